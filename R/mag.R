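# The moral association graph model: lexicon-proportion scores over a
# word-association dataset, fit once per (dataset, lexicon) pair.

# Vectorized scorer over the count table; returns one row per requested cue.
.score_cues <- function(d, lex, cues) {
  counts <- d$counts[d$counts$cue %in% cues, , drop = FALSE]
  matched <- lex_match(counts$response, lex)
  tot <- rowsum(counts$n, counts$cue)
  hit <- rowsum(counts$n * matched, counts$cue)
  out <- data.frame(
    cue = cues,
    score = 0, n_matched = 0L, n_total = 0L,
    stringsAsFactors = FALSE
  )
  i <- match(out$cue, rownames(tot))
  out$n_total <- as.integer(tot[i, 1L])
  out$n_matched <- as.integer(hit[i, 1L])
  out$score <- out$n_matched / out$n_total
  rownames(out) <- NULL
  out
}

#' Fit a moral association graph model
#'
#' The MAG score of a cue word is the proportion of its association
#' responses, weighted by how many participants gave each response, that
#' fall inside a moral lexicon:
#' \deqn{MAG(c) = \frac{\sum_{t \in T(c) \cap M} A_{c,t}}{\sum_{t \in T(c)} A_{c,t}}}
#' where \eqn{A_{c,t}} counts participants responding \eqn{t} to cue
#' \eqn{c}, \eqn{T(c)} is the cue's response set and \eqn{M} the lexicon.
#' The model is parameter-free: fitting means evaluating this ratio for
#' every cue. Supplying an emotion lexicon instead of a moral one yields the
#' emotion association graph (EAG) variant — the formula is identical.
#'
#' @param data an \code{assoc_data} object from
#'   \code{\link{read_associations}} or \code{\link{simulate_associations}}.
#' @param lexicon a \code{moral_lexicon}.
#' @param cues optional character vector restricting which cues are scored;
#'   default all cues, in lexicographic order. Unknown cues raise a
#'   missing-cue error.
#' @return an object of class \code{mag} with components \code{scores} (a
#'   data frame with columns \code{cue}, \code{score}, \code{n_matched},
#'   \code{n_total}), \code{data}, \code{lexicon} and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict} (document
#'   scoring), \code{plot}, \code{simulate}.
#' @seealso \code{\link{mag_score}} for a single cue,
#'   \code{\link{mag_foundations}} for per-foundation profiles,
#'   \code{\link{mag_explain}} for the random-walk interpretation.
#' @examples
#' sim <- simulate_associations(n_cues = 5, n_participants = 30, seed = 1)
#' fit <- mag(sim$data, sim$lexicon)
#' coef(fit)
#' @export
mag <- function(data, lexicon, cues = NULL) {
  stopifnot(inherits(data, "assoc_data"), inherits(lexicon, "moral_lexicon"))
  if (is.null(cues)) {
    cues <- data$cues
  } else {
    bad <- setdiff(cues, data$cues)
    if (length(bad)) stop_missing_cue(bad[1L])
    cues <- sort(unique(cues))
  }
  structure(
    list(scores = .score_cues(data, lexicon, cues),
         data = data, lexicon = lexicon, call = match.call()),
    class = "mag"
  )
}

#' Score a single cue
#'
#' Evaluates the MAG ratio for one cue, reporting the integer numerator and
#' denominator alongside the score. An unknown cue is an error, distinct
#' from a score of 0.
#'
#' @inheritParams mag
#' @param cue a cue present in the data.
#' @return a one-row data frame: \code{cue}, \code{score}, \code{n_matched},
#'   \code{n_total}.
#' @export
mag_score <- function(data, lexicon, cue) {
  stopifnot(inherits(data, "assoc_data"), length(cue) == 1L)
  if (!cue %in% data$cues) stop_missing_cue(cue)
  .score_cues(data, lexicon, cue)
}

#' Per-foundation moral association profile
#'
#' Replaces the overall lexicon with its foundation-specific sub-lexicons
#' and scores each cue against each foundation separately, giving a profile
#' of association strengths across care, fairness, loyalty, authority and
#' sanctity. When the sub-lexicons partition the lexicon, the foundation
#' scores of a cue sum exactly to its overall MAG score.
#'
#' @inheritParams mag
#' @param foundations which foundation labels to profile; defaults to the
#'   labels present in the lexicon, in canonical foundation order.
#' @return a data frame with one row per cue: \code{cue}, one score column
#'   per foundation, and \code{score} (the overall MAG score).
#' @export
mag_foundations <- function(data, lexicon, cues = NULL, foundations = NULL) {
  stopifnot(inherits(lexicon, "moral_lexicon"))
  if (!lexicon$labeled)
    stop_moralassoc("lexicon carries no foundation labels",
                    "moralassoc_unlabeled_error")
  present <- unique(stats::na.omit(lexicon$entries$foundation))
  if (is.null(foundations))
    foundations <- c(intersect(moral_foundations, present),
                     sort(setdiff(present, moral_foundations)))
  overall <- mag(data, lexicon, cues = cues)$scores
  out <- overall[, "cue", drop = FALSE]
  for (f in foundations) {
    sub <- foundation_sublexicon(lexicon, f)
    out[[f]] <- .score_cues(data, sub, out$cue)$score
  }
  out$score <- overall$score
  out
}

#' Score a document by lemma averaging
#'
#' Tokenizes and lemmatizes free text, looks each token lemma up among the
#' dataset's cues, and averages the MAG scores of the covered occurrences
#' (a lemma occurring twice contributes twice). Tokens that are not cues are
#' skipped by default rather than scored zero, so the result reflects moral
#' association rather than vocabulary coverage; \code{zero_fill = TRUE}
#' scores them 0 instead, and \code{type_weighted = TRUE} averages over
#' distinct covered lemmas rather than occurrences.
#'
#' @inheritParams mag
#' @param text a single character string.
#' @param lemmatize logical; lemmatize document tokens.
#' @param zero_fill logical; count uncovered tokens as score 0.
#' @param type_weighted logical; average over lemma types, not occurrences.
#' @return a one-row data frame: \code{score} (\code{NA} when no token is
#'   covered — an undefined score, not zero), \code{covered_tokens},
#'   \code{total_tokens}.
#' @export
document_score <- function(data, lexicon, text, lemmatize = TRUE,
                           zero_fill = FALSE, type_weighted = FALSE) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  toks <- tokenize_text(text, lemmatize = lemmatize)
  covered <- toks[toks %in% data$cues]
  if (type_weighted) covered <- unique(covered)
  n_tot <- if (type_weighted) length(unique(toks)) else length(toks)
  if (!length(covered) && !zero_fill) {
    return(data.frame(score = NA_real_, covered_tokens = 0L, total_tokens = n_tot))
  }
  sc <- if (length(covered)) {
    tab <- .score_cues(data, lexicon, sort(unique(covered)))
    tab$score[match(covered, tab$cue)]
  } else numeric(0)
  denom <- if (zero_fill) n_tot else length(covered)
  data.frame(score = sum(sc) / denom,
             covered_tokens = length(covered), total_tokens = n_tot)
}

#' @export
print.mag <- function(x, ...) {
  cat(sprintf("Moral association graph model (lexicon '%s')\n", x$lexicon$name))
  cat(sprintf("  %d cues scored; mean score %.4f, range [%.4f, %.4f]\n",
              nrow(x$scores), mean(x$scores$score),
              min(x$scores$score), max(x$scores$score)))
  invisible(x)
}

#' @export
summary.mag <- function(object, n_top = 5L, ...) {
  s <- object$scores
  structure(
    list(lexicon = object$lexicon$name, n_cues = nrow(s),
         quantiles = stats::quantile(s$score, c(0, .25, .5, .75, 1)),
         top = utils::head(s[order(-s$score, s$cue), ], n_top)),
    class = "summary.mag"
  )
}

#' @export
print.summary.mag <- function(x, ...) {
  cat(sprintf("MAG model over %d cues (lexicon '%s')\n", x$n_cues, x$lexicon))
  cat("Score quantiles:\n")
  print(round(x$quantiles, 4))
  cat("Most morally associated cues:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mag <- function(object, ...) {
  stats::setNames(object$scores$score, object$scores$cue)
}

#' Predict document-level moral scores from a fitted model
#'
#' Applies \code{\link{document_score}} to each element of \code{newdata}.
#'
#' @param object a fitted \code{mag} model.
#' @param newdata character vector of document texts (optionally named with
#'   document ids).
#' @param ... passed to \code{\link{document_score}} (\code{lemmatize},
#'   \code{zero_fill}, \code{type_weighted}).
#' @return a data frame: \code{doc_id}, \code{score}, \code{covered_tokens},
#'   \code{total_tokens}; \code{score} is \code{NA} for uncovered documents.
#' @export
predict.mag <- function(object, newdata, ...) {
  stopifnot(is.character(newdata), length(newdata) >= 1L)
  ids <- if (!is.null(names(newdata))) names(newdata)
         else sprintf("doc%d", seq_along(newdata))
  rows <- lapply(newdata, function(txt)
    document_score(object$data, object$lexicon, txt, ...))
  cbind(data.frame(doc_id = ids, stringsAsFactors = FALSE), do.call(rbind, rows))
}

#' @export
plot.mag <- function(x, breaks = 20, ...) {
  graphics::hist(x$scores$score, breaks = breaks,
                 main = sprintf("MAG scores (%d cues)", nrow(x$scores)),
                 xlab = "moral association score", col = "grey80", ...)
  invisible(x)
}

#' Simulate association datasets from a fitted model
#'
#' Draws new synthetic word-association datasets whose planted per-cue moral
#' probabilities equal the fitted MAG scores, using the same generator as
#' \code{\link{simulate_associations}}. Useful for parametric-bootstrap
#' checks of score variability.
#'
#' @param object a fitted \code{mag} model.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n_participants,responses_per_participant generator settings.
#' @param ... ignored.
#' @return a list of \code{nsim} \code{assoc_data} objects.
#' @export
simulate.mag <- function(object, nsim = 1, seed = NULL, n_participants = 100,
                         responses_per_participant = 3, ...) {
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::setNames(object$scores$score, object$scores$cue)
  lapply(seq_len(nsim), function(i)
    simulate_associations(
      n_cues = length(theta), theta = unname(theta), cue_names = names(theta),
      n_participants = n_participants,
      responses_per_participant = responses_per_participant,
      seed = NULL)$data)
}
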