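test_that("symmetric normalization has the closed form on simple graphs", {
  # two nodes, one edge of weight 4: off-diagonal 4/sqrt(4*4) = 1
  g <- random_graph(2)
  g$W <- matrix(c(0L, 4L, 4L, 0L), 2, dimnames = list(g$nodes, g$nodes))
  A <- normalized_adjacency(g)
  expect_equal(A[1, 2], 1)
  expect_equal(A[2, 1], 1)
  expect_equal(diag(A), c(n01 = 0, n02 = 0))
  # regular graph: every node degree d, A = W / d
  g4 <- random_graph(4)
  g4$W <- matrix(2L, 4, 4, dimnames = list(g4$nodes, g4$nodes))
  diag(g4$W) <- 0L
  expect_equal(normalized_adjacency(g4), g4$W / 6, ignore_attr = TRUE)
})

test_that("normalized adjacency has spectral radius at most one", {
  set.seed(404)
  for (i in 1:20) {
    g <- random_graph(sample(5:20, 1))
    A <- normalized_adjacency(g)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-12)
    expect_equal(A, t(A))
  }
})

test_that("an edgeless graph is degenerate", {
  g <- random_graph(3)
  g$W[] <- 0L
  expect_error(normalized_adjacency(g),
               class = "moralassoc_degenerate_graph_error")
})

test_that("the restart vector is degree-weighted over moral nodes", {
  g <- random_graph(4)
  g$W <- matrix(0L, 4, 4, dimnames = list(g$nodes, g$nodes))
  g$W[1, 2] <- g$W[2, 1] <- 2L   # n01 deg 3, n02 deg 3, n03 deg 2
  g$W[1, 3] <- g$W[3, 1] <- 1L
  g$W[2, 3] <- g$W[3, 2] <- 1L
  # single moral node -> one-hot
  m1 <- restart_vector(g, make_lex("n01"))
  expect_equal(unname(m1), c(1, 0, 0, 0))
  # degrees 3 and 1: masses 0.75 / 0.25
  g2 <- random_graph(4)
  g2$W <- matrix(0L, 4, 4, dimnames = list(g2$nodes, g2$nodes))
  g2$W[1, 2] <- g2$W[2, 1] <- 3L
  g2$W[3, 4] <- g2$W[4, 3] <- 1L
  m2 <- restart_vector(g2, make_lex(c("n01", "n03")))
  expect_equal(unname(m2), c(0.75, 0, 0.25, 0))
  expect_equal(sum(m2), 1)
  expect_error(restart_vector(g, make_lex("absent")),
               class = "moralassoc_no_seed_error")
})

test_that("the initial distribution adds uniform smoothing to cue scores", {
  g <- random_graph(2)
  d <- make_assoc("p1", "other", "thing")  # neither node is a cue
  expect_equal(unname(initial_distribution(g, d, make_lex("thing"))),
               c(0.5, 0.5))
  # one node with MAG = 1, the other not a cue: (0.5+1, 0.5)/2 normalized
  d2 <- make_assoc(c("p1", "p2"), c("n01", "n01"), c("bad", "bad"))
  p0 <- initial_distribution(g, d2, make_lex("bad"))
  expect_equal(unname(p0), c(0.75, 0.25))
  expect_equal(sum(p0), 1)
})

test_that("beta = 0 collapses the recurrence onto the restart vector", {
  g <- random_graph(6)
  A <- normalized_adjacency(g)
  m <- restart_vector(g, make_lex(g$nodes[which(rowSums(g$W) > 0)[1]]))
  res <- propagate(A, rep(1 / 6, 6), m, walk_config(beta = 0))
  expect_equal(unname(res$p), unname(m))
  expect_identical(res$iterations, 1L)
  expect_true(res$converged)
})

test_that("iterative propagation matches the direct linear solve", {
  set.seed(505)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    g <- random_graph(n, edge_prob = 0.25)
    A <- normalized_adjacency(g)
    pos <- g$nodes[rowSums(g$W) > 0]
    m <- restart_vector(g, make_lex(sample(pos, max(1, length(pos) %/% 3))))
    res <- propagate(A, rep(1 / n, n), m, walk_config(beta = 0.5))
    expect_true(res$converged)
    expect_lt(max(abs(res$p - solve_walk(A, m, 0.5))), 1e-8)
  }
})

test_that("the fixed point does not depend on the initialization", {
  set.seed(606)
  cfg <- walk_config()
  for (i in 1:10) {
    n <- 12
    g <- random_graph(n, edge_prob = 0.3)
    A <- normalized_adjacency(g)
    pos <- g$nodes[rowSums(g$W) > 0]
    m <- restart_vector(g, make_lex(sample(pos, 2)))
    p_a <- propagate(A, rep(1 / n, n), m, cfg)$p
    alt <- stats::runif(n); alt <- alt / sum(alt)
    p_b <- propagate(A, alt, m, cfg)$p
    expect_lt(max(abs(p_a - p_b)), 10 * cfg$tol)
  }
})

test_that("a complete graph of moral nodes converges to the uniform walk", {
  g <- random_graph(5)
  g$W <- matrix(1L, 5, 5, dimnames = list(g$nodes, g$nodes))
  diag(g$W) <- 0L
  A <- normalized_adjacency(g)
  m <- restart_vector(g, make_lex(g$nodes))
  res <- propagate(A, rep(1 / 5, 5), m, walk_config())
  expect_equal(unname(res$p), rep(0.2, 5), tolerance = 1e-7)
})

test_that("keyword ranking is by probability with lexicographic tie-break", {
  p <- c(b = 0.3, a = 0.3, c = 0.4)
  kw <- moralassoc:::top_keywords(p, 3)
  expect_identical(kw$keyword, c("c", "a", "b"))
  expect_identical(nrow(moralassoc:::top_keywords(p, 10)), 3L)  # truncation
})

test_that("a dominant moral co-occurrer ranks first in the explanation", {
  # participants repeatedly pair 'wrong' with varying second responses
  d <- make_assoc(rep(sprintf("p%d", 1:6), each = 2), rep("smoking", 12),
                  c(rbind(rep("wrong", 6), c("ash", "ash", "smell", "smell",
                                             "puff", "puff"))))
  lex <- make_lex("wrong")
  w <- mag_explain(d, lex, "smoking")
  expect_identical(w$keywords$keyword[1], "wrong")
  expect_true(w$keywords$is_moral[1])
  # oracle: fixed point by direct solve on the same graph
  g <- response_graph(d, "smoking")
  A <- normalized_adjacency(g)
  m <- restart_vector(g, lex)
  expect_lt(max(abs(w$p[g$nodes] - solve_walk(A, m, 0.5))), 1e-8)
})

test_that("explanations are deterministic and respect relabeling symmetry", {
  rd <- withr::with_seed(77, {
    simulate_associations(n_cues = 2, n_participants = 40, seed = 77)
  })
  w1 <- mag_explain(rd$data, rd$lexicon, "cue0001")
  w2 <- mag_explain(rd$data, rd$lexicon, "cue0001")
  expect_identical(w1$keywords, w2$keywords)
  # relabeled isomorphic graph: same probabilities up to the relabeling
  d <- make_assoc(rep(c("p1", "p2"), each = 2), rep("x", 4),
                  c("aa", "bb", "bb", "cc"))
  relab <- c(aa = "zz", bb = "yy", cc = "xx")
  d2 <- make_assoc(rep(c("p1", "p2"), each = 2), rep("x", 4),
                   unname(relab[c("aa", "bb", "bb", "cc")]))
  wa <- mag_explain(d, make_lex("bb"), "x")
  wb <- mag_explain(d2, make_lex("yy"), "x")
  expect_equal(unname(wa$p[names(relab)]), unname(wb$p[unname(relab)]),
               tolerance = 1e-9)
})

test_that("errors surface the cue and the walk reports non-convergence", {
  d <- make_assoc(c("p1", "p2"), c("x", "x"), c("a", "b"))  # no edges
  expect_error(mag_explain(d, make_lex("a"), "x"),
               class = "moralassoc_degenerate_graph_error")
  g <- random_graph(8, edge_prob = 0.5)
  A <- normalized_adjacency(g)
  m <- restart_vector(g, make_lex(g$nodes[rowSums(g$W) > 0][1]))
  expect_warning(
    res <- propagate(A, rep(1 / 8, 8), m, walk_config(max_iter = 2)),
    "converge")
  expect_false(res$converged)
})
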