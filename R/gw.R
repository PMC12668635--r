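#' Pairwise embedding dissimilarity
#'
#' Euclidean distances between the embedding rows of a state, the input
#' geometry for Gromov-Wasserstein alignment. Optionally rescales the matrix
#' by its median nonzero entry so the entropic regularization strength is
#' comparable across datasets.
#'
#' @param E A `tm_embedding` or a numeric matrix (rows = genes).
#' @param scale_median Divide by the median nonzero distance (default
#'   `FALSE`; the pipeline enables it before solving).
#' @return A symmetric N x N matrix with zero diagonal.
#' @export
tm_embedding_dissimilarity <- function(E, scale_median = FALSE) {
  if (inherits(E, "tm_embedding")) E <- E$E
  stopifnot(is.matrix(E), all(is.finite(E)))
  D <- as.matrix(stats::dist(E))
  if (scale_median) {
    med <- stats::median(D[D > 0])
    if (is.finite(med) && med > 0) D <- D / med
  }
  dimnames(D) <- list(rownames(E), rownames(E))
  D
}

# Internal: log-stabilized Sinkhorn scaling (Schmitzer-style absorption)
# for marginals p, q and cost C with regularization eps. Runs the fast
# multiplicative u/v updates on the kernel exp((f + g - C) / eps) and folds
# the scalings into the dual potentials whenever they threaten overflow.
# Warm-startable via `init` potentials; converges on the row-marginal
# violation.
sinkhorn_log <- function(C, p, q, eps, max_iter = 1000, tol = 1e-9,
                         init = NULL) {
  n <- length(p); m <- length(q)
  f <- init$f %||% rep(0, n)
  g <- init$g %||% rep(0, m)
  u <- rep(1, n); v <- rep(1, m)
  make_kernel <- function(f, g) {
    exp((outer(f, g, "+") - C) / eps)
  }
  # one numerically safe log-domain update, used when the fast scaling
  # under/overflows
  stable_step <- function(f, g) {
    f <- eps * (log(p) - row_logsumexp(sweep(-C, 2L, g, "+") / eps))
    g <- eps * (log(q) - row_logsumexp(t(sweep(-C, 1L, f, "+")) / eps))
    list(f = f, g = g)
  }
  K <- make_kernel(f, g)
  absorb_at <- 1e100
  for (it in seq_len(max_iter)) {
    Kv <- as.numeric(K %*% v)
    u <- p / Kv
    Ktu <- as.numeric(crossprod(K, u))
    v <- q / Ktu
    bad <- !all(is.finite(u)) || !all(is.finite(v))
    if (bad || max(u, v) > absorb_at || it %% 50L == 0L) {
      if (bad) {
        st <- stable_step(f, g)
        f <- st$f; g <- st$g
      } else {
        f <- f + eps * log(u)
        g <- g + eps * log(v)
      }
      u <- rep(1, n); v <- rep(1, m)
      K <- make_kernel(f, g)
    }
    if (it %% 5L == 0L || it == max_iter) {
      row_mass <- u * as.numeric(K %*% v)
      if (all(is.finite(row_mass)) && max(abs(row_mass - p)) < tol) break
    }
  }
  if (all(is.finite(u)) && all(is.finite(v))) {
    f <- f + eps * log(pmax(u, 1e-300))
    g <- g + eps * log(pmax(v, 1e-300))
  }
  G <- make_kernel(f, g)
  list(gamma = G, f = f, g = g)
}

# Internal: GW square-loss tensor pieces (Peyre-Cuturi-Solomon). With
# marginals (p, q), the quadratic objective evaluated at a coupling G is
# <constC - 2 D G D', G>.
gw_const <- function(D, Dprime, p, q) {
  (D^2) %*% p %*% t(rep(1, length(q))) +
    rep(1, length(p)) %*% t(q) %*% t(Dprime^2)
}

gw_cost <- function(D, Dprime, G, constC) {
  sum((constC - 2 * (D %*% G %*% Dprime)) * G)
}

#' Entropic Gromov-Wasserstein alignment of two embedding geometries
#'
#' Minimizes the quadratic Gromov-Wasserstein discrepancy between two
#' pairwise-dissimilarity matrices over couplings with prescribed marginals,
#' with entropic regularization `-eps * H(Gamma)`. Solved by projected
#' gradients with a log-domain Sinkhorn inner loop, starting from the
#' independent coupling `p q^T`. The reported cost is the unregularized
#' quadratic objective at the returned coupling.
#'
#' @param D,Dprime Symmetric dissimilarity matrices for the two states.
#' @param p,q Marginal probability vectors (default uniform).
#' @param epsilon Entropic regularization strength (default 1e-2).
#' @param max_iter Maximum outer (gradient) iterations.
#' @param tol Outer convergence tolerance on the L1 change of the coupling.
#' @param inner_tol,inner_max_iter Sinkhorn inner-loop controls.
#' @return An object of class `tm_transport_plan`: list with `gamma`
#'   (N x N coupling), `p`, `q`, `epsilon`, `cost`, `iterations`,
#'   `converged`.
#' @export
tm_entropic_gw <- function(D, Dprime, p = NULL, q = NULL, epsilon = 1e-2,
                           max_iter = 1000, tol = 1e-8,
                           inner_tol = 1e-9, inner_max_iter = 1000) {
  stopifnot(is.matrix(D), is.matrix(Dprime), nrow(D) == ncol(D),
            nrow(Dprime) == ncol(Dprime), epsilon > 0)
  n <- nrow(D); m <- nrow(Dprime)
  p <- p %||% rep(1 / n, n)
  q <- q %||% rep(1 / m, m)
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8 ||
      any(p < 0) || any(q < 0)) {
    abort("`p` and `q` must be probability vectors summing to 1")
  }

  constC <- gw_const(D, Dprime, p, q)
  G <- outer(p, q)
  converged <- FALSE
  it <- 0L
  pot <- NULL
  for (it in seq_len(max_iter)) {
    grad <- 2 * (constC - 2 * (D %*% G %*% Dprime))
    sk <- sinkhorn_log(grad, p, q, epsilon,
                       max_iter = inner_max_iter, tol = inner_tol,
                       init = pot)
    pot <- sk[c("f", "g")]
    delta <- sum(abs(sk$gamma - G))
    G <- sk$gamma
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("entropic GW did not converge in %d iterations", max_iter))
  }
  # round the approximate coupling onto the feasible polytope: scale rows
  # and columns down where they overshoot, then distribute the remaining
  # deficit as a nonnegative rank-one correction (exact marginals, entries
  # stay nonnegative, and the perturbation is of the order of the residual)
  r_scale <- pmin(p / pmax(rowSums(G), 1e-300), 1)
  G <- G * r_scale
  c_scale <- pmin(q / pmax(colSums(G), 1e-300), 1)
  G <- sweep(G, 2L, c_scale, "*")
  err_r <- p - rowSums(G)
  err_c <- q - colSums(G)
  if (sum(err_r) > 0) G <- G + outer(err_r, err_c) / sum(err_r)
  dimnames(G) <- dimnames(D) %||% NULL
  structure(list(gamma = G, p = p, q = q, epsilon = epsilon,
                 cost = gw_cost(D, Dprime, G, constC),
                 iterations = it, converged = converged),
            class = "tm_transport_plan")
}

#' @exportS3Method base::print
print.tm_transport_plan <- function(x, ...) {
  cat(sprintf(
    "<tm_transport_plan> %d x %d coupling; eps %.3g; cost %.6g; %s after %d iteration(s)\n",
    nrow(x$gamma), ncol(x$gamma), x$epsilon, x$cost,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Per-gene structural-shift score of one transition
#'
#' The population standard deviation of each gene's transport-plan row. A
#' gene whose relational context is preserved across the transition
#' concentrates its mass (high row variability relative to the uniform row),
#' while diffuse rows indicate positional ambiguity; summarizing rows by
#' their spread captures how sharply the gene's structural role maps across
#' states.
#'
#' @param plan A `tm_transport_plan`.
#' @return Named numeric vector of per-gene scores.
#' @export
tm_transition_score <- function(plan) {
  stopifnot(inherits(plan, "tm_transport_plan"))
  scores <- apply(plan$gamma, 1L, pop_sd)
  names(scores) <- rownames(plan$gamma)
  scores
}

#' Cumulative alignment scores across all transitions
#'
#' Sums per-transition structural-shift scores over the consecutive-state
#' transport plans, giving each gene a single cumulative score R; the
#' per-transition columns are retained for the downstream instability index.
#'
#' @param plans List of `tm_transport_plan`, one per consecutive-state
#'   transition, all with the same gene set.
#' @param genes Optional gene names (taken from the first plan's rownames
#'   when absent).
#' @return An object of class `tm_alignment_scores`: a tibble with columns
#'   `gene`, one `R_t<k>` column per transition, and the cumulative `R`.
#' @export
tm_alignment_scores <- function(plans, genes = NULL) {
  stopifnot(length(plans) >= 1)
  ns <- vapply(plans, function(p) nrow(p$gamma), integer(1))
  if (length(unique(ns)) != 1L) abort("plans have inconsistent sizes")
  per <- vapply(plans, tm_transition_score, numeric(ns[1]))
  if (is.null(dim(per))) per <- matrix(per, nrow = 1)
  genes <- genes %||% rownames(plans[[1]]$gamma) %||%
    sprintf("g%d", seq_len(ns[1]))
  colnames(per) <- sprintf("R_t%d", seq_along(plans))
  out <- tibble::as_tibble(per)
  out <- dplyr::mutate(out, gene = genes, R = rowSums(per),
                       .before = 1)
  class(out) <- c("tm_alignment_scores", class(out))
  out
}
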