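#' Select structurally variable genes by knee-point detection
#'
#' Sorts cumulative alignment scores in descending order and locates the
#' knee of the ranked curve with the kneedle criterion (convex, decreasing
#' mode): the curve is min-max normalized, flipped to a concave increasing
#' curve, and the knee is the index maximizing the difference from the
#' diagonal. Genes ranked strictly above the knee are returned. When no knee
#' exists (flat or concave curve, all-equal scores) or the knee keeps fewer
#' than 3 or more than half of the genes, the fallback selects the top
#' `fallback_fraction` of genes (rounding up), mirroring the empirically
#' best-performing top-15% rule.
#'
#' @param scores A `tm_alignment_scores` tibble (or any data frame with
#'   `gene` and `R` columns).
#' @param fallback_fraction Fraction of genes kept by the fallback rule.
#' @param sensitivity Minimum normalized prominence of the knee.
#' @return Character vector of selected genes, in descending score order.
#' @export
tm_elbow_select <- function(scores, fallback_fraction = 0.15,
                            sensitivity = 0) {
  stopifnot(is.data.frame(scores), all(c("gene", "R") %in% names(scores)))
  check_fraction(fallback_fraction, "fallback_fraction", strict_lo = TRUE)
  ord <- order(-scores$R, scores$gene)
  genes <- scores$gene[ord]
  y <- scores$R[ord]
  n <- length(y)
  fallback <- function() genes[seq_len(min(n, ceiling(fallback_fraction * n)))]
  if (n < 3L || diff(range(y)) == 0) return(fallback())

  xn <- (seq_len(n) - 1) / (n - 1)
  yn <- (y - min(y)) / diff(range(y))
  diff_curve <- (1 - yn) - xn # concave-increasing flip minus diagonal
  delta <- which.max(diff_curve)
  if (diff_curve[delta] <= sensitivity || delta == 1L || delta == n) {
    return(fallback())
  }
  k <- delta - 1L # genes ranked strictly above the knee index
  if (k < 3L || k > n / 2) return(fallback())
  genes[seq_len(k)]
}

#' Connected components of the union network over selected genes
#'
#' Builds the union of all state-specific edge sets restricted to the
#' selected genes and extracts the connected components of its undirected
#' view. Singleton components are retained but flagged.
#'
#' @param selected Character vector of selected genes (subset of the shared
#'   node list).
#' @param graphs List of `tm_state_graph`, one per state.
#' @return A tibble with columns `component`, `gene`, `singleton`.
#' @export
tm_union_components <- function(selected, graphs) {
  stopifnot(length(graphs) >= 1)
  nodes <- graphs[[1]]$nodes
  if (!all(selected %in% nodes)) abort("`selected` must be a subset of the node list")
  union_edges <- dplyr::distinct(
    dplyr::bind_rows(lapply(graphs, `[[`, "edges"))
  )
  union_edges <- dplyr::filter(union_edges, .data$source %in% selected,
                               .data$target %in% selected)
  g <- igraph::graph_from_data_frame(union_edges, directed = FALSE,
                                     vertices = selected)
  comp <- igraph::components(g)
  out <- tibble::tibble(
    component = unname(comp$membership[selected]),
    gene = selected
  )
  sizes <- table(out$component)
  dplyr::mutate(out, singleton = sizes[as.character(.data$component)] == 1L)
}

#' Score the dynamic instability of one gene component
#'
#' For each state t the component's cohesion density
#' `rho = 2 m_t / (n_t (n_t - 1))` (undirected edge count; defined as 1 for
#' singletons), summed member alignment score `Psi`, graph cohesion score
#' `GCS = (1 - rho) * (-Psi)` and dynamic score `D = exp(-GCS)` are
#' computed; the Dynamic Network Instability (DNI) is the population
#' standard deviation of the D series across states. The final state, which
#' has no outgoing transition, reuses the incoming transition's per-gene
#' scores.
#'
#' @param genes Character vector: the component's gene set.
#' @param graphs List of `tm_state_graph`, one per state.
#' @param scores A `tm_alignment_scores` with per-transition columns.
#' @return A one-row tibble of class `tm_component_report` with `genes`
#'   (list-column), `n_genes`, `dni`, and a `per_state` list-column holding
#'   the per-state `n_t`, `m_t`, `rho`, `psi`, `gcs`, `d` table.
#' @export
tm_score_component <- function(genes, graphs, scores) {
  stopifnot(length(genes) >= 1, inherits(scores, "data.frame"))
  n_states <- length(graphs)
  r_cols <- grep("^R_t", names(scores), value = TRUE)
  stopifnot(length(r_cols) == n_states - 1L)
  idx <- match(genes, scores$gene)
  if (anyNA(idx)) abort("per-transition scores must cover all component genes")

  per_state <- purrr::map_dfr(seq_len(n_states), function(t) {
    e <- graphs[[t]]$edges
    e <- e[e$source %in% genes & e$target %in% genes, , drop = FALSE]
    # reciprocal directed pairs count once (undirected density)
    und <- unique(ifelse(e$source < e$target,
                         paste(e$source, e$target),
                         paste(e$target, e$source)))
    n_t <- length(genes)
    m_t <- length(und)
    rho <- if (n_t == 1L) 1 else 2 * m_t / (n_t * (n_t - 1))
    r_col <- r_cols[min(t, n_states - 1L)] # last state reuses incoming transition
    psi <- sum(scores[[r_col]][idx])
    gcs <- (1 - rho) * (-psi)
    tibble::tibble(state = t, n_t = n_t, m_t = m_t, rho = rho,
                   psi = psi, gcs = gcs, d = exp(-gcs))
  })

  out <- tibble::tibble(
    genes = list(sort(genes)),
    n_genes = length(genes),
    dni = pop_sd(per_state$d),
    per_state = list(per_state)
  )
  class(out) <- c("tm_component_report", class(out))
  out
}

#' Rank components and select the dynamic network biomarker module
#'
#' Scores every connected component of the union network and returns all
#' reports ranked by DNI, with the top-ranked component flagged as the DNB
#' module C*. Ties are broken by larger gene count, then by lexicographically
#' smallest gene set.
#'
#' @param components Tibble from [tm_union_components()].
#' @param graphs List of `tm_state_graph`.
#' @param scores A `tm_alignment_scores`.
#' @return A tibble of component reports with `component`, `rank`, and
#'   `is_dnb` columns; row 1 (rank 1) is C*.
#' @export
tm_select_dnb <- function(components, graphs, scores) {
  stopifnot(nrow(components) > 0)
  reports <- purrr::map_dfr(split(components$gene, components$component),
                            tm_score_component,
                            graphs = graphs, scores = scores,
                            .id = "component")
  key <- vapply(reports$genes, function(g) paste(g, collapse = " "),
                character(1))
  ord <- order(-reports$dni, -reports$n_genes, key)
  reports <- reports[ord, ]
  reports$rank <- seq_len(nrow(reports))
  reports$is_dnb <- reports$rank == 1L
  class(reports) <- c("tm_component_report", class(tibble::tibble()))
  reports
}
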