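# Fixtures are built in code: tiny record tables, random datasets with a
# known vocabulary, random weighted graphs, and independent brute-force
# oracles the implementation is checked against.

# Dataset straight from parallel record vectors (bypasses file loading).
make_assoc <- function(participant, cue, response, position = 1L) {
  moralassoc:::new_assoc_data(data.frame(
    participant = as.character(participant), cue = as.character(cue),
    response = as.character(response),
    position = as.integer(rep_len(position, length(cue))),
    stringsAsFactors = FALSE))
}

# Literal-only lexicon over already-normalized tokens.
make_lex <- function(words, ...) {
  moral_lexicon(words, lemmatize = FALSE, ...)
}

# Random small dataset over a digit-suffixed vocabulary (stable under
# normalization). Returns the dataset plus the moral word set.
random_dataset <- function(n_cues = 5, max_resp = 30, vocab_size = 30,
                           n_moral = 8) {
  vocab <- sprintf("w%02d", seq_len(vocab_size))
  moral <- sample(vocab, n_moral)
  cues <- sprintf("q%02d", seq_len(n_cues))
  rows <- do.call(rbind, lapply(cues, function(cu) {
    n <- sample.int(max_resp, 1)
    data.frame(participant = sprintf("p%03d", sample.int(max(2, n %/% 2), n,
                                                         replace = TRUE)),
               cue = cu, response = sample(vocab, n, replace = TRUE),
               position = 1L, stringsAsFactors = FALSE)
  }))
  list(data = moralassoc:::new_assoc_data(rows), moral = moral,
       lexicon = make_lex(moral))
}

# Independent record-by-record MAG oracle: a plain loop over the raw
# records, counting matches against a literal word set.
brute_mag <- function(d, moral_words, cue) {
  n_matched <- 0L; n_total <- 0L
  for (i in seq_len(nrow(d$records))) {
    if (d$records$cue[i] != cue) next
    n_total <- n_total + 1L
    if (d$records$response[i] %in% moral_words) n_matched <- n_matched + 1L
  }
  c(n_matched = n_matched, n_total = n_total)
}

# Random symmetric integer weight matrix with zero diagonal and at least
# one edge, wrapped as a response_graph.
random_graph <- function(n, edge_prob = 0.2, max_w = 5L, cue = "g") {
  repeat {
    W <- matrix(0L, n, n)
    up <- which(upper.tri(W))
    on <- up[stats::runif(length(up)) < edge_prob]
    W[on] <- sample.int(max_w, length(on), replace = TRUE)
    W <- W + t(W)
    if (any(W > 0)) break
  }
  nodes <- sprintf("n%02d", seq_len(n))
  dimnames(W) <- list(nodes, nodes)
  structure(list(cue = cue, nodes = nodes, W = W, participant_count = 0L,
                 isolated = rowSums(W) == 0),
            class = "response_graph")
}

# Closed-form fixed point of the damped walk, for the iterative solver.
solve_walk <- function(A_norm, m, beta) {
  n <- nrow(A_norm)
  as.numeric(solve(diag(n) - beta * A_norm, (1 - beta) * m))
}

# Write a long-format association TSV for loader tests.
write_long_tsv <- function(participant, cue, response, path) {
  utils::write.table(
    data.frame(participant = participant, cue = cue, response = response),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
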