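# Two-wave moral-change analysis: per-word score deltas between time
# slices, group contrasts, and precision-at-K retrieval of shifted words.

#' Per-word moral-association change between two waves
#'
#' Scores each word against the lexicon in both association datasets and
#' records the difference (after minus before). Words missing from either
#' wave are returned in the \code{"missing"} attribute rather than silently
#' dropped.
#'
#' @param before,after \code{assoc_data} objects for the two time slices.
#' @param lexicon a \code{moral_lexicon}.
#' @param words character vector of words to track (must overlap both waves'
#'   cue sets).
#' @param groups optional character vector of group labels parallel to
#'   \code{words} (e.g. pandemic / emotion / routine / control); defaults to
#'   \code{"other"}.
#' @return a data frame of class \code{mag_change}: \code{word},
#'   \code{group}, \code{before}, \code{after}, \code{delta}, sorted by
#'   word; attribute \code{"missing"} lists excluded words and which wave
#'   lacked them.
#' @export
delta_scores <- function(before, after, lexicon, words, groups = NULL) {
  stopifnot(inherits(before, "assoc_data"), inherits(after, "assoc_data"))
  words <- as.character(words)
  if (is.null(groups)) groups <- rep("other", length(words))
  stopifnot(length(groups) == length(words))
  in_b <- words %in% before$cues
  in_a <- words %in% after$cues
  ok <- in_b & in_a
  if (!any(ok))
    stop_empty("no word is a cue in both waves")
  missing <- data.frame(
    word = words[!ok],
    absent_from = ifelse(!in_b[!ok] & !in_a[!ok], "both",
                         ifelse(!in_b[!ok], "before", "after")),
    stringsAsFactors = FALSE
  )
  if (nrow(missing))
    message(sprintf("%d word(s) missing from at least one wave; see attr(x, 'missing')",
                    nrow(missing)))
  w <- sort(words[ok])
  g <- groups[ok][order(words[ok])]
  sb <- .score_cues(before, lexicon, w)
  sa <- .score_cues(after, lexicon, w)
  out <- data.frame(word = w, group = g, before = sb$score, after = sa$score,
                    delta = sa$score - sb$score, stringsAsFactors = FALSE)
  attr(out, "missing") <- missing
  class(out) <- c("mag_change", "data.frame")
  out
}

#' Words whose moral association increased
#'
#' Restricts a change table to records with strictly positive delta — the
#' words that acquired new moral associations between waves.
#'
#' @param records a \code{mag_change} data frame.
#' @return the positive-delta subset, same class and columns.
#' @export
positive_subset <- function(records) {
  out <- records[records$delta > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum contrast between two word groups
#'
#' Tests whether the moral-association deltas of one group are
#' stochastically larger than another's, using the rank-sum test with
#' normal approximation and tie correction. The default alternative is
#' one-sided (\code{group_a} greater), matching a directional hypothesis
#' about which group changed most.
#'
#' @param records a \code{mag_change} data frame.
#' @param group_a,group_b group labels to contrast (each needs >= 2 records).
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return a list of class \code{mag_change_test}: \code{statistic} (the
#'   rank-sum W), \code{p_value}, \code{n_per_group}, \code{method},
#'   \code{alternative}.
#' @export
wilcoxon_contrast <- function(records, group_a, group_b,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  da <- records$delta[records$group == group_a]
  db <- records$delta[records$group == group_b]
  if (length(da) < 2L || length(db) < 2L)
    stop_moralassoc("each group needs at least 2 records",
                    "moralassoc_group_size_error")
  wt <- suppressWarnings(
    stats::wilcox.test(da, db, alternative = alternative,
                       exact = FALSE, correct = TRUE))
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_per_group = stats::setNames(c(length(da), length(db)),
                                       c(group_a, group_b)),
         method = "wilcoxon", alternative = alternative),
    class = "mag_change_test"
  )
}

#' Permutation contrast of one group against all others
#'
#' Tests whether the mean delta of \code{group_a} exceeds the mean delta of
#' all other words by shuffling group labels. The statistic is
#' mean(delta of group_a) - mean(delta of the rest); the p-value is
#' \code{(1 + #permuted >= observed) / (1 + n_perm)}. By default the test is
#' run on the positive-delta subset — the words that became more morally
#' associated — mirroring the focus of the change analysis;
#' \code{positive_only = FALSE} uses all records.
#'
#' @param records a \code{mag_change} data frame.
#' @param group_a target group label.
#' @param n_perm number of label shuffles (>= 1000).
#' @param seed integer seed for reproducible shuffles.
#' @param positive_only logical; restrict to delta > 0 first.
#' @return a \code{mag_change_test} list (statistic = observed mean
#'   difference), with \code{n_perm} recorded.
#' @export
permutation_contrast <- function(records, group_a, n_perm = 1000L, seed = NULL,
                                 positive_only = TRUE) {
  if (n_perm < 1000L)
    stop_moralassoc("n_perm must be at least 1000", "moralassoc_format_error")
  if (positive_only) records <- positive_subset(records)
  is_a <- records$group == group_a
  n_a <- sum(is_a)
  n <- nrow(records)
  if (n_a == 0L || n_a == n)
    stop_moralassoc("permutation contrast needs records both in and out of the target group",
                    "moralassoc_single_group_error")
  delta <- records$delta
  obs <- mean(delta[is_a]) - mean(delta[!is_a])
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  tot <- sum(delta)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n_a)
    s <- sum(delta[idx])
    s / n_a - (tot - s) / (n - n_a)
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  structure(
    list(statistic = obs, p_value = p,
         n_per_group = stats::setNames(c(n_a, n - n_a), c(group_a, "rest")),
         method = "permutation", n_perm = as.integer(n_perm),
         positive_only = positive_only),
    class = "mag_change_test"
  )
}

#' @export
print.mag_change_test <- function(x, ...) {
  cat(sprintf("%s contrast: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(sprintf("%s:%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  invisible(x)
}

#' Precision at K in retrieving a word group by change magnitude
#'
#' Ranks the change records by delta, descending (ties broken
#' lexicographically by word), and reports for each K the fraction of the
#' top K words that belong to the target group, together with the chance
#' level (the group's share of all records).
#'
#' @param records a \code{mag_change} data frame.
#' @param target_group group label to retrieve.
#' @param k_values integer vector of cutoffs; values above the number of
#'   records are truncated with a warning.
#' @return a data frame: \code{k}, \code{precision}, \code{chance}.
#' @export
precision_at_k <- function(records, target_group, k_values = c(5L, 10L, 25L, 50L)) {
  if (!nrow(records)) stop_empty("no change records")
  n <- nrow(records)
  if (any(k_values > n)) {
    warning(sprintf("k truncated to n = %d records", n))
    k_values <- pmin(k_values, n)
  }
  k_values <- sort(unique(as.integer(k_values)))
  ord <- order(-records$delta, records$word)
  in_target <- records$group[ord] == target_group
  hits <- cumsum(in_target)
  data.frame(k = k_values,
             precision = hits[k_values] / k_values,
             chance = mean(records$group == target_group))
}
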