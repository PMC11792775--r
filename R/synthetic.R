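# Seeded generator of word-association fixtures with planted
# moral-association probabilities, emulating the statistical structure of
# large association norms (about 100 annotations per cue, three response
# slots per participant).

# One wave of records for fixed cues/vocab/theta. Each response slot draws
# from the moral vocabulary with probability theta[cue], else from the
# neutral vocabulary. If cooccurrence_blocks are given, a participant's
# whole response set is drawn from one randomly chosen block with
# probability block_prob, planting co-occurrence clusters.
.gen_records <- function(cues, theta, moral_vocab, neutral_vocab,
                         n_participants, k, blocks = NULL, block_prob = 0.5) {
  pids <- sprintf("p%04d", seq_len(n_participants))
  out <- vector("list", length(cues))
  for (ci in seq_along(cues)) {
    resp <- character(n_participants * k)
    if (!is.null(blocks)) {
      use_block <- stats::runif(n_participants) < block_prob
      bidx <- sample.int(length(blocks), n_participants, replace = TRUE)
    } else {
      use_block <- rep(FALSE, n_participants)
    }
    pos <- 0L
    for (p in seq_len(n_participants)) {
      if (use_block[p]) {
        r <- sample(blocks[[bidx[p]]], k, replace = TRUE)
      } else {
        moral <- stats::runif(k) < theta[ci]
        r <- character(k)
        r[moral] <- sample(moral_vocab, sum(moral), replace = TRUE)
        r[!moral] <- sample(neutral_vocab, sum(!moral), replace = TRUE)
      }
      resp[pos + seq_len(k)] <- r
      pos <- pos + k
    }
    out[[ci]] <- data.frame(
      participant = rep(pids, each = k),
      cue = cues[ci],
      response = resp,
      position = rep(seq_len(k), n_participants),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Moral vocabulary tokens carry foundation and polarity labels cycling
# through the five foundations and virtue/vice.
.make_vocab <- function(vocab_size, lexicon_fraction) {
  n_moral <- max(1L, round(vocab_size * lexicon_fraction))
  n_neutral <- max(1L, vocab_size - n_moral)
  list(moral = sprintf("moralterm%03d", seq_len(n_moral)),
       neutral = sprintf("neutralterm%03d", seq_len(n_neutral)))
}

#' Generate a synthetic word-association dataset
#'
#' Simulates participant-level cue/response records with a planted
#' moral-association probability theta per cue: each response slot draws a
#' word from the moral sub-vocabulary with probability \code{theta[cue]},
#' otherwise from the neutral sub-vocabulary. The returned lexicon contains
#' exactly the moral sub-vocabulary (with foundation and polarity labels
#' cycling over the five foundations), so the planted theta is recoverable
#' by the MAG score up to binomial sampling error. Fully reproducible from
#' the seed.
#'
#' Defaults emulate large word-association norms: 100 participants per cue,
#' three response slots each, theta drawn uniformly on [0, 0.6].
#'
#' @param n_cues number of cue words.
#' @param n_participants participants per cue (default 100).
#' @param responses_per_participant response slots per participant (1 to 3).
#' @param vocab_size total response vocabulary size.
#' @param lexicon_fraction share of the vocabulary that is moral.
#' @param theta per-cue moral-association probabilities in [0, 1]; a scalar
#'   is recycled; \code{NULL} draws Uniform(0, 0.6).
#' @param cooccurrence_blocks optional list of token vectors (subsets of the
#'   vocabulary) that co-occur within participants, giving the response
#'   graphs non-trivial cluster structure.
#' @param block_prob probability a participant responds from a single block.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param cue_names optional explicit cue names (length \code{n_cues}).
#' @return a list: \code{data} (an \code{assoc_data}), \code{lexicon} (a
#'   labeled \code{moral_lexicon}), \code{theta} (data frame \code{cue},
#'   \code{theta} — the ground truth for recovery tests), and \code{seed}.
#' @examples
#' sim <- simulate_associations(n_cues = 4, n_participants = 20, seed = 7)
#' mag(sim$data, sim$lexicon)
#' @export
simulate_associations <- function(n_cues = 100L, n_participants = 100L,
                                  responses_per_participant = 3L,
                                  vocab_size = 200L, lexicon_fraction = 0.2,
                                  theta = NULL, cooccurrence_blocks = NULL,
                                  block_prob = 0.5, seed = NULL,
                                  cue_names = NULL) {
  stopifnot(n_cues >= 1L, n_participants >= 1L,
            responses_per_participant %in% 1:3)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- stats::runif(n_cues, 0, 0.6)
  theta <- rep_len(theta, n_cues)
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 1))
    stop_moralassoc("theta must lie in [0, 1]", "moralassoc_invalid_theta_error")
  cues <- if (is.null(cue_names)) sprintf("cue%04d", seq_len(n_cues))
          else { stopifnot(length(cue_names) == n_cues); as.character(cue_names) }
  voc <- .make_vocab(vocab_size, lexicon_fraction)
  if (!is.null(cooccurrence_blocks)) {
    all_vocab <- c(voc$moral, voc$neutral)
    if (!all(unlist(cooccurrence_blocks) %in% all_vocab))
      stop_format("cooccurrence_blocks must be subsets of the generated vocabulary")
  }
  rec <- .gen_records(cues, theta, voc$moral, voc$neutral, n_participants,
                      responses_per_participant,
                      blocks = cooccurrence_blocks, block_prob = block_prob)
  nf <- length(moral_foundations)
  lex <- moral_lexicon(
    voc$moral,
    foundation = moral_foundations[(seq_along(voc$moral) - 1L) %% nf + 1L],
    polarity = c("virtue", "vice")[(seq_along(voc$moral) - 1L) %% 2L + 1L],
    name = "synthetic-moral", lemmatize = FALSE)
  list(data = new_assoc_data(rec), lexicon = lex,
       theta = data.frame(cue = cues, theta = theta, stringsAsFactors = FALSE),
       seed = seed)
}

#' Generate a two-wave dataset with a planted moral shift
#'
#' Draws two association datasets over the same cues, vocabulary and
#' lexicon; in the second wave the moral-association probability of the
#' shifted cues is raised by \code{shift} (their group label is
#' \code{"pandemic"}, all others \code{"control"}). Emulates a
#' before/during two-wave design for short-term moral-change analysis.
#'
#' @inheritParams simulate_associations
#' @param n_shifted number of cues receiving the shift (ignored when
#'   \code{shifted_cues} is given).
#' @param shift added to theta in the second wave; the shifted theta must
#'   stay in [0, 1].
#' @param shifted_cues optional explicit cue names to shift.
#' @return a list: \code{before}, \code{after} (both \code{assoc_data}),
#'   \code{groups} (data frame \code{word}, \code{group}), \code{lexicon},
#'   \code{theta} (data frame \code{cue}, \code{theta_before},
#'   \code{theta_after}), and \code{seed}.
#' @export
simulate_two_wave <- function(n_cues = 500L, n_participants = 100L,
                              responses_per_participant = 1L,
                              vocab_size = 200L, lexicon_fraction = 0.2,
                              theta = NULL, n_shifted = 50L, shift = 0.2,
                              shifted_cues = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- stats::runif(n_cues, 0, 0.6)
  theta <- rep_len(theta, n_cues)
  cues <- sprintf("cue%04d", seq_len(n_cues))
  if (is.null(shifted_cues)) {
    stopifnot(n_shifted >= 1L, n_shifted <= n_cues)
    shifted_cues <- sample(cues, n_shifted)
  }
  stopifnot(all(shifted_cues %in% cues))
  theta_after <- theta + shift * (cues %in% shifted_cues)
  if (any(theta_after < 0 | theta_after > 1))
    stop_moralassoc("shift pushes theta outside [0, 1]",
                    "moralassoc_invalid_theta_error")
  voc <- .make_vocab(vocab_size, lexicon_fraction)
  nf <- length(moral_foundations)
  lex <- moral_lexicon(
    voc$moral,
    foundation = moral_foundations[(seq_along(voc$moral) - 1L) %% nf + 1L],
    polarity = c("virtue", "vice")[(seq_along(voc$moral) - 1L) %% 2L + 1L],
    name = "synthetic-moral", lemmatize = FALSE)
  before <- .gen_records(cues, theta, voc$moral, voc$neutral,
                         n_participants, responses_per_participant)
  after <- .gen_records(cues, theta_after, voc$moral, voc$neutral,
                        n_participants, responses_per_participant)
  list(before = new_assoc_data(before), after = new_assoc_data(after),
       groups = data.frame(word = cues,
                           group = ifelse(cues %in% shifted_cues,
                                          "pandemic", "control"),
                           stringsAsFactors = FALSE),
       lexicon = lex,
       theta = data.frame(cue = cues, theta_before = theta,
                          theta_after = theta_after, stringsAsFactors = FALSE),
       seed = seed)
}
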