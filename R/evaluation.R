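# Evaluation harnesses: rank correlation against gold ratings and
# precision/recall/F1 of retrieved keywords against a reference list.

#' Spearman rank correlation between predicted and gold scores
#'
#' Tie-corrected Spearman correlation with a two-sided p-value (via
#' \code{stats::cor.test} with the asymptotic approximation, which handles
#' ties). Constant inputs make the correlation undefined and raise an
#' error rather than returning \code{NA}.
#'
#' @param predicted numeric vector of model scores.
#' @param gold numeric vector of reference ratings, same length.
#' @return a list: \code{rho}, \code{p}, \code{n}.
#' @export
rank_correlation <- function(predicted, gold) {
  stopifnot(length(predicted) == length(gold))
  ok <- is.finite(predicted) & is.finite(gold)
  predicted <- predicted[ok]; gold <- gold[ok]
  if (length(predicted) < 3L)
    stop_moralassoc("need at least 3 complete pairs", "moralassoc_empty_error")
  if (stats::sd(predicted) == 0 || stats::sd(gold) == 0)
    stop_moralassoc("correlation undefined for constant input",
                    "moralassoc_degenerate_correlation_error")
  ct <- suppressWarnings(
    stats::cor.test(predicted, gold, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(predicted))
}

#' Rescale a bipolar rating to absolute moral relevance
#'
#' Maps a rating on a bipolar scale \code{[lo, hi]} linearly onto
#' \code{[-1, 1]} and takes the absolute value, so the scale midpoint (a
#' nonmoral stance) maps to 0 and either extreme (a strongly moralized
#' stance) maps to 1. This is the standard preprocessing for survey scales
#' such as justifiability ratings before correlating with association
#' scores.
#'
#' @param x numeric ratings.
#' @param lo,hi scale endpoints.
#' @return numeric vector in [0, 1].
#' @export
abs_normalize <- function(x, lo, hi) {
  stopifnot(hi > lo)
  abs(2 * (x - lo) / (hi - lo) - 1)
}

#' Precision, recall and F1 of retrieved keywords
#'
#' Compares a retrieved keyword list against a reference list on unique
#' terms: precision = overlap / retrieved, recall = overlap / reference, F1
#' their harmonic mean (0 when both are 0). With \code{normalize = TRUE}
#' both sides are normalized (lowercase, lemma) before comparison. By
#' default multi-word reference terms must match as whole phrases;
#' \code{split_phrases = TRUE} lets a reference phrase count as retrieved if
#' any of its constituent tokens was retrieved (and a retrieved token count
#' as correct if it occurs inside any reference phrase).
#'
#' @param retrieved character vector of retrieved keywords (non-empty).
#' @param reference character vector of reference keywords (non-empty).
#' @param normalize logical; normalize tokens before matching.
#' @param split_phrases logical; constituent-token matching for phrases.
#' @return a list: \code{precision}, \code{recall}, \code{f1},
#'   \code{n_retrieved}, \code{n_reference}, \code{n_overlap} (matched
#'   reference terms).
#' @export
keyword_prf <- function(retrieved, reference, normalize = FALSE,
                        split_phrases = FALSE) {
  if (!length(retrieved)) stop_empty("retrieved keyword list is empty")
  if (!length(reference)) stop_empty("reference keyword list is empty")
  if (normalize) {
    retrieved <- normalize_token(retrieved)
    reference <- normalize_token(reference)
  }
  retrieved <- unique(retrieved[nzchar(retrieved)])
  reference <- unique(reference[nzchar(reference)])
  if (split_phrases) {
    ref_tokens <- strsplit(reference, " ", fixed = TRUE)
    ref_hit <- vapply(seq_along(reference), function(i)
      reference[i] %in% retrieved || any(ref_tokens[[i]] %in% retrieved),
      logical(1))
    all_ref_tokens <- unique(c(reference, unlist(ref_tokens)))
    ret_hit <- retrieved %in% all_ref_tokens
    n_overlap <- sum(ref_hit)
    precision <- sum(ret_hit) / length(retrieved)
    recall <- n_overlap / length(reference)
  } else {
    n_overlap <- length(intersect(retrieved, reference))
    precision <- n_overlap / length(retrieved)
    recall <- n_overlap / length(reference)
  }
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_retrieved = length(retrieved), n_reference = length(reference),
       n_overlap = n_overlap)
}
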