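#' Generate a ground-truth gene regulatory network
#'
#' Draws a random directed acyclic regulator-to-target network. Genes are
#' ordered and the first `n_tfs` act as transcription factors; edges always
#' point from a TF to a downstream gene (in gene order), which guarantees
#' acyclicity and lets steady-state kinetics be solved in a single topological
#' pass. Each edge carries a signed regulatory strength: positive for
#' activation, negative for repression.
#'
#' @param n_genes Total number of genes.
#' @param n_tfs Number of transcription factors (must be < `n_genes`).
#' @param edge_density Fraction of the `n_tfs * (n_genes - 1)` possible
#'   regulator-target pairs to realize; the drawn edge count is
#'   `round(edge_density * n_tfs * (n_genes - 1))`, capped at the number of
#'   legal acyclic pairs.
#' @param seed Integer seed; identical arguments and seed give identical
#'   networks.
#' @param activator_prob Probability that a drawn edge is activating.
#' @return An object of class `tm_grn`: a list with `genes`, `regulators`,
#'   `edges` (a tibble with columns `source`, `target`, `strength`), `basal`
#'   (named per-gene basal production rates), `states` (list of per-state edge
#'   tibbles; a single entry until [tm_rewire_states()] is applied) and
#'   `switchers` (character vector of rewired genes).
#' @seealso [tm_rewire_states()], [tm_simulate_expression()]
#' @export
tm_generate_grn <- function(n_genes, n_tfs, edge_density, seed = 1L,
                            activator_prob = 0.7) {
  if (n_tfs < 1L || n_tfs >= n_genes) {
    abort("`n_tfs` must satisfy 1 <= n_tfs < n_genes")
  }
  check_fraction(edge_density, "edge_density", strict_lo = TRUE)
  n_edges <- round(edge_density * n_tfs * (n_genes - 1))
  if (n_edges < 1L) {
    abort("`edge_density` too small: it yields zero edges")
  }
  genes <- sprintf("G%03d", seq_len(n_genes))
  regulators <- genes[seq_len(n_tfs)]

  # legal pairs: TF i -> any gene with a larger index (forward DAG edges)
  pairs <- do.call(rbind, lapply(seq_len(n_tfs), function(i) {
    if (i < n_genes) cbind(i, seq.int(i + 1L, n_genes)) else NULL
  }))
  n_edges <- min(n_edges, nrow(pairs))

  withr::with_seed(as.integer(seed), {
    take <- sample.int(nrow(pairs), n_edges)
    strengths <- runif(n_edges, 2, 5) *
      ifelse(runif(n_edges) < activator_prob, 1, -1)
    basal <- c(runif(n_tfs, 1, 3), rep(0.2, n_genes - n_tfs))
  })
  names(basal) <- genes

  edges <- tibble::tibble(
    source = genes[pairs[take, 1L]],
    target = genes[pairs[take, 2L]],
    strength = strengths
  ) |> dplyr::arrange(.data$source, .data$target)

  structure(
    list(genes = genes, regulators = regulators, edges = edges,
         basal = basal, states = list(edges), switchers = character(0)),
    class = "tm_grn"
  )
}

#' Generate a regulon-structured (modular) ground-truth network
#'
#' Builds a layered regulatory network with explicit co-regulation
#' redundancy, the hallmark of curated GRNs and of kinetic expression
#' simulators: a small TF cascade (each non-master TF regulated by one
#' earlier TF) and target genes organized into regulons -- groups of
#' `module_size` targets sharing the same small set of TFs, with coherent
#' edge signs within a regulon. Regulon members therefore have
#' near-identical regulatory neighborhoods and correlated expression, which
#' is what makes stable genes mutually interchangeable (and rewired genes
#' structurally distinctive) for the downstream alignment analysis.
#'
#' @param n_genes Total number of genes.
#' @param n_tfs Number of TFs (default: 20% of genes).
#' @param module_size Target genes per regulon.
#' @param tfs_per_module Number of TFs regulating each regulon.
#' @param seed Integer seed.
#' @param activator_prob Probability that a regulon's input from a given TF
#'   is activating.
#' @return A `tm_grn` whose `modules` field maps each target gene to its
#'   regulon id (TFs carry `NA`).
#' @export
tm_generate_modular_grn <- function(n_genes,
                                    n_tfs = max(3L, round(0.2 * n_genes)),
                                    module_size = 4, tfs_per_module = 3,
                                    seed = 1L, activator_prob = 0.7) {
  if (n_tfs < 2L || n_tfs >= n_genes) {
    abort("`n_tfs` must satisfy 2 <= n_tfs < n_genes")
  }
  genes <- sprintf("G%03d", seq_len(n_genes))
  regulators <- genes[seq_len(n_tfs)]
  targets <- genes[(n_tfs + 1L):n_genes]

  withr::with_seed(as.integer(seed), {
    # TF cascade: each non-master TF gets one earlier TF as parent
    tf_edges <- purrr::map_dfr(seq(2L, n_tfs), function(i) {
      tibble::tibble(
        source = genes[sample.int(i - 1L, 1L)],
        target = genes[i],
        strength = runif(1, 2, 5) * ifelse(runif(1) < activator_prob, 1, -1)
      )
    })
    # regulons: shuffled targets chunked into modules sharing a TF set.
    # Module sizes and TF counts vary so regulons are structurally
    # heterogeneous -- no two stable genes should be graph-isomorphic by
    # construction alone.
    shuffled <- sample(targets)
    sizes <- integer(0)
    while (sum(sizes) < length(shuffled)) {
      sizes <- c(sizes, sample(max(2, module_size - 2):(module_size + 2), 1))
    }
    module_of <- rep(seq_along(sizes), sizes)[seq_along(shuffled)]
    regulon_edges <- purrr::map_dfr(unique(module_of), function(m) {
      members <- shuffled[module_of == m]
      n_tf_m <- sample(seq_len(min(tfs_per_module + 1, n_tfs)), 1)
      tf_set <- sample(regulators, n_tf_m)
      purrr::map_dfr(tf_set, function(tf) {
        base <- runif(1, 2, 5) * ifelse(runif(1) < activator_prob, 1, -1)
        tibble::tibble(source = tf, target = members,
                       strength = base * runif(length(members), 0.9, 1.1))
      })
    })
    basal <- c(runif(n_tfs, 1, 3), rep(0.2, n_genes - n_tfs))
    modules <- stats::setNames(rep(NA_integer_, n_genes), genes)
    modules[shuffled] <- module_of
  })
  names(basal) <- genes
  edges <- dplyr::arrange(dplyr::bind_rows(tf_edges, regulon_edges),
                          .data$source, .data$target)

  structure(
    list(genes = genes, regulators = regulators, edges = edges,
         basal = basal, modules = modules, states = list(edges),
         switchers = character(0)),
    class = "tm_grn"
  )
}

#' Rewire a ground-truth network across disease states
#'
#' Produces one edge set per disease state by edge swapping: state `t + 1`
#' starts from state `t`, removes `round(rewire_fraction * |E|)` edges and
#' adds the same number of new legal regulator-target edges absent from state
#' `t`. Swapping preserves the edge count per state so that downstream
#' instability scores respond to structural change, not to network size.
#'
#' Rewiring is driver-localized: a fixed random subset of genes (the driver
#' module, of size `driver_fraction * n_genes`, always containing at least
#' one TF) is chosen once, and swapped edges are drawn among edges incident
#' to a driver gene. This mirrors disease progression, where regulatory
#' rewiring concentrates on a pathway rather than scattering uniformly, and
#' gives the simulation a recoverable connected module of rewired genes.
#' `driver_fraction = 1` makes rewiring uniform over all edges.
#'
#' Genes incident to any edge that is present in some states but not all are
#' recorded as switcher genes -- the ground truth the pipeline is expected to
#' recover.
#'
#' @param grn A `tm_grn` from [tm_generate_grn()].
#' @param n_states Number of ordered disease states (>= 2).
#' @param rewire_fraction Fraction of edges swapped at each state transition.
#' @param seed Integer seed.
#' @param driver_fraction Fraction of genes forming the rewiring-prone driver
#'   module, in (0, 1]. Ignored when `drivers` is given.
#' @param drivers Optional explicit character vector of driver genes.
#' @return The input `tm_grn` with `states` holding `n_states` edge tibbles,
#'   `drivers` (the driver module) and `switchers` filled in.
#' @export
tm_rewire_states <- function(grn, n_states, rewire_fraction, seed = 1L,
                             driver_fraction = 0.5, drivers = NULL) {
  stopifnot(inherits(grn, "tm_grn"))
  if (n_states < 2L) abort("`n_states` must be >= 2")
  check_fraction(rewire_fraction, "rewire_fraction")
  check_fraction(driver_fraction, "driver_fraction", strict_lo = TRUE)
  if (!is.null(drivers) && !all(drivers %in% grn$genes)) {
    abort("`drivers` must be a subset of the network's genes")
  }

  genes <- grn$genes
  n_tfs <- length(grn$regulators)
  all_pairs <- do.call(rbind, lapply(seq_len(n_tfs), function(i) {
    if (i < length(genes)) cbind(i, seq.int(i + 1L, length(genes))) else NULL
  }))
  pair_key <- function(s, t) paste(s, t, sep = "\r")
  all_keys <- pair_key(genes[all_pairs[, 1L]], genes[all_pairs[, 2L]])

  states <- vector("list", n_states)
  states[[1L]] <- grn$edges
  k <- round(rewire_fraction * nrow(grn$edges))

  withr::with_seed(as.integer(seed), {
    if (is.null(drivers)) {
      n_driver <- max(2L, round(driver_fraction * length(genes)))
      drivers <- sample(genes, n_driver)
      if (!any(drivers %in% grn$regulators)) {
        drivers[1L] <- sample(grn$regulators, 1L)
      }
    }
    src_drv <- genes[all_pairs[, 1L]] %in% drivers
    dst_drv <- genes[all_pairs[, 2L]] %in% drivers
    # tiered preference: both endpoints in the driver module, then one, then any
    pair_tier <- ifelse(src_drv & dst_drv, 1L, ifelse(src_drv | dst_drv, 2L, 3L))
    take_tiered <- function(pool_idx, tiers, k) {
      out <- integer(0)
      for (tier in sort(unique(tiers))) {
        cand <- pool_idx[tiers == tier]
        need <- k - length(out)
        if (need <= 0L) break
        out <- c(out, cand[sample.int(length(cand), min(need, length(cand)))])
      }
      out
    }
    for (t in seq_len(n_states - 1L)) {
      cur <- states[[t]]
      if (k == 0L) {
        states[[t + 1L]] <- cur
        next
      }
      cur_keys <- pair_key(cur$source, cur$target)
      edge_tier <- ifelse(cur$source %in% drivers & cur$target %in% drivers, 1L,
                          ifelse(cur$source %in% drivers |
                                 cur$target %in% drivers, 2L, 3L))
      absent <- which(!(all_keys %in% cur_keys))
      if (length(absent) < k) {
        abort("rewire count exceeds the number of legal replacement edges")
      }
      drop_i <- take_tiered(seq_len(nrow(cur)), edge_tier, k)
      add_i <- take_tiered(absent, pair_tier[absent], k)
      added <- tibble::tibble(
        source = genes[all_pairs[add_i, 1L]],
        target = genes[all_pairs[add_i, 2L]],
        strength = runif(k, 2, 5) * ifelse(runif(k) < 0.7, 1, -1)
      )
      states[[t + 1L]] <- dplyr::bind_rows(cur[-drop_i, ], added) |>
        dplyr::arrange(.data$source, .data$target)
    }
  })

  keys_by_state <- lapply(states, function(e) pair_key(e$source, e$target))
  union_keys <- unique(unlist(keys_by_state))
  in_all <- union_keys[vapply(union_keys, function(kk) {
    all(vapply(keys_by_state, function(ks) kk %in% ks, logical(1)))
  }, logical(1))]
  variable <- setdiff(union_keys, in_all)
  switchers <- unique(unlist(strsplit(variable, "\r", fixed = TRUE)))

  grn$states <- states
  grn$drivers <- sort(drivers)
  grn$switchers <- sort(switchers)
  grn
}

#' @exportS3Method base::print
print.tm_grn <- function(x, ...) {
  cat(sprintf(
    "<tm_grn> %d genes (%d TFs), %d base edges, %d state(s), %d switcher gene(s)\n",
    length(x$genes), length(x$regulators), nrow(x$edges),
    length(x$states), length(x$switchers)
  ))
  invisible(x)
}

#' Union edge list of a multi-state network
#'
#' Collapses the per-state edge tibbles of a `tm_grn` into one directed edge
#' list tagged with the states each edge occurs in. This union is what the
#' analysis pipeline uses as its prior regulatory network when run on
#' simulated data.
#'
#' @param grn A `tm_grn`.
#' @return A tibble with columns `source`, `target`, `n_states`.
#' @export
tm_grn_union_edges <- function(grn) {
  stopifnot(inherits(grn, "tm_grn"))
  dplyr::bind_rows(grn$states) |>
    dplyr::count(.data$source, .data$target, name = "n_states")
}
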