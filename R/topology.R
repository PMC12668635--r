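#' Local topological similarity of a state graph
#'
#' Unweighted shortest-path lengths are computed on the undirected view of
#' the state graph and turned into similarities by exponential decay,
#' `exp(-d_ij)`. Disconnected pairs receive `exp(-d_big)`, a negligible but
#' finite similarity; `d_big` defaults to the node count, a size-adaptive
#' upper bound on any finite path length. Rows are then normalized to sum to
#' one.
#'
#' @param graph A `tm_state_graph`.
#' @param d_big Large constant standing in for infinite distance.
#' @param normalize Row-normalize the result (default `TRUE`).
#' @return An N x N matrix with gene dimnames.
#' @export
tm_local_similarity <- function(graph, d_big = length(graph$nodes),
                                normalize = TRUE) {
  stopifnot(inherits(graph, "tm_state_graph"))
  g <- state_igraph(graph, directed = FALSE)
  d <- igraph::distances(g)
  d[!is.finite(d)] <- d_big
  s <- exp(-d)
  if (normalize) s <- row_normalize(s) else s
}

# Internal: divide each row by its sum; all-zero rows stay zero (warned).
row_normalize <- function(m) {
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero row(s) left unnormalized", sum(zero)))
    rs[zero] <- 1
  }
  m / rs
}

#' PageRank scores by power iteration
#'
#' Damped PageRank on a directed graph with uniform teleportation; dangling
#' nodes redistribute their mass uniformly. Iterates until the L1 change
#' falls below `tol`.
#'
#' @param graph A `tm_state_graph`.
#' @param damping Damping factor in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum number of power iterations.
#' @return Named numeric vector of PageRank scores summing to 1.
#' @export
tm_pagerank <- function(graph, damping = 0.85, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(graph, "tm_state_graph"))
  check_fraction(damping, "damping", strict_lo = TRUE)
  n <- length(graph$nodes)
  A <- graph$adjacency
  out_deg <- Matrix::rowSums(A)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    dangling <- sum(p[out_deg == 0])
    contrib <- as.numeric(Matrix::crossprod(A, ifelse(out_deg > 0, p / out_deg, 0)))
    p_new <- (1 - damping) / n + damping * (contrib + dangling / n)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- graph$nodes
      return(p / sum(p))
    }
  }
  abort(sprintf("PageRank did not converge in %d iterations (residual %.3g)",
                max_iter, delta))
}

#' Global topological similarity of a state graph
#'
#' The global profile scores each gene pair by the product of their PageRank
#' scores on the directed state graph, so pairs of globally central genes
#' receive large similarity. Rows are then normalized to sum to one.
#'
#' @param graph A `tm_state_graph`.
#' @param damping PageRank damping factor.
#' @param normalize Row-normalize the result (default `TRUE`).
#' @return An N x N matrix with gene dimnames.
#' @export
tm_global_similarity <- function(graph, damping = 0.85, normalize = TRUE) {
  p <- tm_pagerank(graph, damping = damping)
  s <- outer(p, p)
  if (normalize) row_normalize(s) else s
}

#' Fuse local and global similarity into one structural matrix
#'
#' Convex combination `S = alpha * local + (1 - alpha) * global`, entrywise.
#' Each profile is row-normalized before combination, so the result is also
#' row-stochastic. The default `alpha = 0.3` slightly favors the global
#' profile, the setting found best in ablation.
#'
#' @param local,global Same-shape matrices from [tm_local_similarity()] and
#'   [tm_global_similarity()].
#' @param alpha Weight on the local profile, in \[0, 1\].
#' @return A list of class `tm_structure` with `S`, `local`, `global`,
#'   `alpha`.
#' @export
tm_combine_similarity <- function(local, global, alpha = 0.3) {
  if (!identical(dim(local), dim(global))) {
    abort("`local` and `global` must have identical dimensions")
  }
  check_fraction(alpha, "alpha")
  structure(list(S = alpha * local + (1 - alpha) * global,
                 local = local, global = global, alpha = alpha),
            class = "tm_structure")
}

#' Structural similarity matrix of a state graph
#'
#' Convenience wrapper: computes the local and global profiles and fuses
#' them.
#'
#' @inheritParams tm_combine_similarity
#' @inheritParams tm_local_similarity
#' @inheritParams tm_global_similarity
#' @return A `tm_structure`.
#' @export
tm_structural_similarity <- function(graph, alpha = 0.3, damping = 0.85,
                                     d_big = length(graph$nodes)) {
  tm_combine_similarity(tm_local_similarity(graph, d_big = d_big),
                        tm_global_similarity(graph, damping = damping),
                        alpha = alpha)
}
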