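# Damped random walk with restart over a cue's response co-occurrence
# graph: the interpretability procedure that retrieves which associated
# concepts carry a cue's moral relevance.

#' Random-walk configuration
#'
#' @param beta damping parameter in [0, 1): weight of graph diffusion versus
#'   restart toward moral words. Default 0.5.
#' @param K number of keywords retrieved after convergence. Default 25.
#' @param tol convergence tolerance on the L-infinity change between
#'   iterates. Default 1e-8.
#' @param max_iter iteration cap. Default 10000.
#' @return a \code{walk_config} list.
#' @export
walk_config <- function(beta = 0.5, K = 25L, tol = 1e-8, max_iter = 10000L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta < 1,
            K >= 1L, tol > 0, max_iter >= 1L)
  structure(list(beta = beta, K = as.integer(K), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "walk_config")
}

#' Symmetric normalized adjacency matrix
#'
#' Computes \eqn{\tilde A = D^{-1/2} W D^{-1/2}} from a response graph's
#' weight matrix, with \eqn{D} the diagonal of weighted degrees. Isolated
#' nodes keep zero rows and columns. The spectral radius of the result is at
#' most 1, so damped iteration with \eqn{\beta < 1} is a contraction.
#'
#' @param g a \code{response_graph} with at least one edge.
#' @return the normalized adjacency matrix, dimnames = node names.
#' @export
normalized_adjacency <- function(g) {
  stopifnot(inherits(g, "response_graph"))
  deg <- rowSums(g$W)
  if (all(deg == 0))
    stop_moralassoc(
      sprintf("response graph for '%s' has no edges", g$cue),
      "moralassoc_degenerate_graph_error")
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  g$W * outer(dinv, dinv)
}

#' Degree-weighted restart vector
#'
#' The restart distribution m places mass only on nodes matching the
#' lexicon, proportional to their weighted degree in the graph, normalized
#' to sum to 1. It anchors the walk near the moral words. If no node matches
#' the lexicon (or all matching nodes are isolated) the walk is undefined.
#'
#' @param g a \code{response_graph}.
#' @param lex a \code{moral_lexicon}.
#' @return numeric vector named by node, summing to 1.
#' @export
restart_vector <- function(g, lex) {
  stopifnot(inherits(g, "response_graph"))
  deg <- rowSums(g$W)
  m <- deg * lex_match(g$nodes, lex)
  if (sum(m) == 0)
    stop_moralassoc(
      sprintf("no lexicon word with positive degree among responses to '%s'", g$cue),
      "moralassoc_no_seed_error")
  m / sum(m)
}

#' Initial walk distribution
#'
#' Each node starts with mass proportional to its own MAG score as a cue in
#' the association data (0 when it is not a cue) plus a uniform smoothing
#' term 1/|V|, renormalized to sum to 1. Because the damped fixed point does
#' not depend on the initialization, this only shapes early iterates.
#'
#' @param g a \code{response_graph}.
#' @param d the \code{assoc_data} the graph came from.
#' @param lex a \code{moral_lexicon}.
#' @return numeric vector named by node, summing to 1.
#' @export
initial_distribution <- function(g, d, lex) {
  stopifnot(inherits(g, "response_graph"), inherits(d, "assoc_data"))
  n <- length(g$nodes)
  magv <- numeric(n)
  as_cue <- g$nodes[g$nodes %in% d$cues]
  if (length(as_cue)) {
    sc <- .score_cues(d, lex, sort(as_cue))
    magv[match(sc$cue, g$nodes)] <- sc$score
  }
  raw <- 1 / n + magv
  stats::setNames(raw / sum(raw), g$nodes)
}

#' Iterate the damped propagation to its fixed point
#'
#' Runs \eqn{p^{(t+1)} = \beta \tilde A p^{(t)} + (1 - \beta) m} until
#' convergence or \code{cfg$max_iter}. For \eqn{\beta < 1} the iteration
#' contracts (in the spectral norm, at rate at most \eqn{\beta}) to the
#' unique fixed point \eqn{p^* = (1-\beta)(I - \beta\tilde A)^{-1} m}
#' regardless of \code{p0}. \code{cfg$tol} bounds the L-infinity distance of
#' the returned vector from that fixed point: the iteration stops once the
#' successive change falls below \eqn{tol\,(1-\beta)/(\beta\sqrt{|V|})},
#' which certifies the error bound via the contraction inequality. With
#' \eqn{\beta = 0} the first update is already exact.
#'
#' @param A_norm normalized adjacency matrix.
#' @param p0 initial distribution (same length as \code{nrow(A_norm)}).
#' @param m restart vector.
#' @param cfg a \code{\link{walk_config}}.
#' @return an object of class \code{mag_walk}: \code{p} (named converged
#'   vector), \code{iterations}, \code{converged}, and \code{keywords} (the
#'   top-K nodes by probability, ties broken lexicographically).
#' @export
propagate <- function(A_norm, p0, m, cfg = walk_config()) {
  stopifnot(nrow(A_norm) == length(p0), length(p0) == length(m))
  beta <- cfg$beta
  p <- as.numeric(p0)
  converged <- FALSE
  iter <- 0L
  if (beta == 0) {
    # recurrence collapses: p(1) = m exactly
    p <- as.numeric(m)
    converged <- TRUE
    iter <- 1L
  } else {
    # ||p - p*||_inf <= ||p - p*||_2 <= beta/(1-beta) * ||change||_2
    #                <= beta*sqrt(n)/(1-beta) * ||change||_inf
    thresh <- cfg$tol * (1 - beta) / (beta * sqrt(length(p)))
    while (iter < cfg$max_iter) {
      iter <- iter + 1L
      p_new <- beta * as.numeric(A_norm %*% p) + (1 - beta) * m
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < thresh) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning(sprintf("propagation did not converge in %d iterations", cfg$max_iter))
  names(p) <- rownames(A_norm)
  structure(
    list(p = p, iterations = iter, converged = converged,
         keywords = top_keywords(p, cfg$K)),
    class = "mag_walk"
  )
}

# Top-K nodes by probability, descending; ties broken lexicographically.
top_keywords <- function(p, K) {
  ord <- order(-p, names(p))
  idx <- ord[seq_len(min(K, length(p)))]
  data.frame(keyword = names(p)[idx], p = unname(p[idx]),
             stringsAsFactors = FALSE)
}

#' Explain why a cue is morally associated
#'
#' Composes the full interpretability pipeline for one cue: build the
#' response co-occurrence graph, normalize its adjacency, seed a restart
#' vector on the lexicon-matching responses, and iterate the damped walk to
#' convergence. The returned keyword ranking lists the responses — moral
#' words included — whose graph proximity to the moral vocabulary is
#' highest, i.e. the associative contexts in which the cue is moralized.
#'
#' @param data an \code{assoc_data} object.
#' @param lexicon a \code{moral_lexicon}.
#' @param cue a cue present in the data.
#' @param cfg a \code{\link{walk_config}}.
#' @return a \code{mag_walk} (see \code{\link{propagate}}) with extra fields
#'   \code{cue}, \code{graph} and, per keyword, an \code{is_moral} flag.
#' @examples
#' sim <- simulate_associations(n_cues = 3, n_participants = 50, seed = 2)
#' w <- mag_explain(sim$data, sim$lexicon, sim$theta$cue[1])
#' head(w$keywords)
#' @export
mag_explain <- function(data, lexicon, cue, cfg = walk_config()) {
  g <- response_graph(data, cue)
  A_norm <- normalized_adjacency(g)
  m <- restart_vector(g, lexicon)
  p0 <- initial_distribution(g, data, lexicon)
  res <- propagate(A_norm, p0, m, cfg)
  res$cue <- cue
  res$graph <- g
  res$keywords$is_moral <- lex_match(res$keywords$keyword, lexicon)
  res
}

#' @export
print.mag_walk <- function(x, n = 10L, ...) {
  if (!is.null(x$cue))
    cat(sprintf("Random-walk interpretation for cue '%s'\n", x$cue))
  cat(sprintf("  converged: %s after %d iterations\n", x$converged, x$iterations))
  cat(sprintf("  top %d keywords:\n", min(n, nrow(x$keywords))))
  print(utils::head(x$keywords, n), row.names = FALSE, digits = 4)
  invisible(x)
}
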