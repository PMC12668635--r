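#' Identify differentially expressed genes between a state and a reference
#'
#' Screens genes by absolute log2 fold change of mean expression (with a
#' pseudocount) and a two-sided Wilcoxon rank-sum test on log-normalized
#' values. Genes with missing or constant expression in either condition are
#' excluded before testing. Both thresholds are strict inequalities: a gene
#' with log2 fold change exactly equal to `lfc_min` is not called.
#'
#' @param state_counts,normal_counts Genes x cells count matrices sharing the
#'   same row (gene) index.
#' @param lfc_min Minimum absolute log2 fold change (default 1.0).
#' @param p_max Maximum rank-sum p-value (default 0.05, unadjusted).
#' @param pseudocount Added to both means before the fold-change ratio.
#' @return A tibble with one row per tested gene: `gene`, `log2fc`, `p`,
#'   `selected`. Excluded (constant/missing) genes are absent.
#' @export
tm_identify_degs <- function(state_counts, normal_counts, lfc_min = 1.0,
                             p_max = 0.05, pseudocount = 1) {
  if (!identical(rownames(state_counts), rownames(normal_counts))) {
    abort("`state_counts` and `normal_counts` must share the same gene index")
  }
  if (ncol(state_counts) < 2L || ncol(normal_counts) < 2L) {
    abort("each condition needs at least 2 cells")
  }
  stopifnot(lfc_min > 0, p_max > 0, p_max < 1)

  norm_s <- tm_normalize_counts(state_counts)
  norm_n <- tm_normalize_counts(normal_counts)
  keep <- vapply(seq_len(nrow(state_counts)), function(i) {
    vs <- state_counts[i, ]; vn <- normal_counts[i, ]
    !anyNA(c(vs, vn)) && length(unique(vs)) > 1L && length(unique(vn)) > 1L
  }, logical(1))

  res <- purrr::map_dfr(which(keep), function(i) {
    lfc <- log2((mean(state_counts[i, ]) + pseudocount) /
                (mean(normal_counts[i, ]) + pseudocount))
    p <- suppressWarnings(
      wilcox.test(norm_s[i, ], norm_n[i, ], exact = FALSE)$p.value
    )
    tibble::tibble(gene = rownames(state_counts)[i], log2fc = lfc, p = p)
  })
  if (nrow(res) == 0L) {
    return(tibble::tibble(gene = character(), log2fc = numeric(),
                          p = numeric(), selected = logical()))
  }
  dplyr::mutate(res, selected = abs(.data$log2fc) > lfc_min & .data$p < p_max)
}

#' Assemble the background regulatory network
#'
#' Maps a gene set (typically the union of per-state DEGs plus an optional
#' pathway gene list) onto a prior directed regulatory network and returns
#' the induced subgraph. Mapped genes without any retained edge are kept as
#' isolated nodes.
#'
#' @param genes Character vector of genes to map (DEG union and/or pathway
#'   genes).
#' @param prior A data frame with columns `source` and `target` (directed
#'   prior regulatory edges); duplicate directed edges are collapsed.
#' @param pathway_genes Optional additional gene symbols to include.
#' @return A list of class `tm_background` with `nodes` (character) and
#'   `edges` (tibble `source`, `target`).
#' @export
tm_assemble_background <- function(genes, prior, pathway_genes = NULL) {
  stopifnot(is.data.frame(prior), all(c("source", "target") %in% names(prior)))
  if (nrow(prior) == 0L) abort("`prior` network is empty")
  gene_set <- unique(c(genes, pathway_genes))
  prior <- dplyr::distinct(tibble::as_tibble(prior[c("source", "target")]))
  edges <- dplyr::filter(prior, .data$source %in% gene_set,
                         .data$target %in% gene_set,
                         .data$source != .data$target)
  nodes <- intersect(gene_set, unique(c(prior$source, prior$target)))
  if (length(nodes) == 0L) {
    warn("gene set has no overlap with the prior network; background is empty")
  }
  structure(list(nodes = nodes, edges = edges), class = "tm_background")
}

#' @exportS3Method base::print
print.tm_background <- function(x, ...) {
  cat(sprintf("<tm_background> %d genes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Internal: Gaussian mutual information from a correlation coefficient.
gauss_mi <- function(r) {
  r2 <- min(r^2, 1 - 1e-12)
  -0.5 * log(1 - r2)
}

# Internal: Gaussian conditional mutual information CMI(X, Y | Z) from
# covariance determinants of the log-normalized expression.
gauss_cmi <- function(dat, xi, yi, zi) {
  det_of <- function(cols) det(as.matrix(cov(dat[, cols, drop = FALSE])))
  d_xz <- det_of(c(xi, zi)); d_yz <- det_of(c(yi, zi))
  d_z <- det_of(zi); d_xyz <- det_of(c(xi, yi, zi))
  denom <- d_z * d_xyz
  if (!is.finite(denom) || denom <= 0 || !is.finite(d_xz * d_yz)) {
    return(NA_real_) # singular covariance: non-informative test
  }
  0.5 * log((d_xz * d_yz) / denom)
}

#' Prune a background network into a state-specific regulatory graph
#'
#' Path-consistency pruning with (conditional) mutual information under a
#' Gaussian estimator on log-normalized expression. The order-0 pass removes
#' edges whose marginal mutual information
#' `MI(X, Y) = -1/2 log(1 - cor(X, Y)^2)` falls at or below the threshold;
#' the order-1 pass removes a surviving edge (u, v) when the minimum over
#' common neighbors z of `CMI(u, v | z)` falls at or below the threshold.
#' Edge direction is inherited from the background network; a singular
#' covariance makes the conditional test non-informative and the edge is
#' retained.
#'
#' @param background A `tm_background`.
#' @param state_counts Genes x cells count matrix for the state; all
#'   background nodes must be present among its rownames.
#' @param max_order 0 or 1; highest conditioning order applied.
#' @param cmi_threshold Positive CMI threshold (default 0.03).
#' @param state Integer state index stored on the result.
#' @return An object of class `tm_state_graph`: list with `state`, `nodes`,
#'   `edges` (tibble `source`, `target`) and `adjacency` (binary sparse
#'   directed matrix).
#' @export
tm_pc_cmi_prune <- function(background, state_counts, max_order = 1,
                            cmi_threshold = 0.03, state = 1L) {
  stopifnot(inherits(background, "tm_background"))
  if (!max_order %in% c(0, 1)) abort("`max_order` must be 0 or 1")
  if (cmi_threshold <= 0) abort("`cmi_threshold` must be > 0")
  missing <- setdiff(background$nodes, rownames(state_counts))
  if (length(missing) > 0L) {
    abort(sprintf("background nodes absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  nodes <- background$nodes
  # normalize against the full library before subsetting, so cell totals are
  # not dominated by the analysis genes themselves
  dat <- t(tm_normalize_counts(state_counts)[nodes, , drop = FALSE])
  edges <- background$edges

  if (nrow(edges) > 0L) {
    # order 0: marginal mutual information
    mi <- vapply(seq_len(nrow(edges)), function(e) {
      r <- suppressWarnings(cor(dat[, edges$source[e]], dat[, edges$target[e]]))
      if (is.na(r)) 0 else gauss_mi(r)
    }, numeric(1))
    edges <- edges[mi > cmi_threshold, , drop = FALSE]
  }

  if (max_order >= 1 && nrow(edges) > 0L) {
    # order 1: condition on common neighbors in the surviving skeleton
    nbrs <- lapply(nodes, function(g) {
      unique(c(edges$target[edges$source == g], edges$source[edges$target == g]))
    })
    names(nbrs) <- nodes
    keep <- vapply(seq_len(nrow(edges)), function(e) {
      u <- edges$source[e]; v <- edges$target[e]
      common <- setdiff(intersect(nbrs[[u]], nbrs[[v]]), c(u, v))
      if (length(common) == 0L) return(TRUE)
      cmis <- vapply(common, function(z) gauss_cmi(dat, u, v, z), numeric(1))
      cmis <- cmis[!is.na(cmis)]
      length(cmis) == 0L || min(cmis) > cmi_threshold
    }, logical(1))
    edges <- edges[keep, , drop = FALSE]
  }

  tm_state_graph(nodes, edges, state = state)
}

#' Construct a state-specific graph from a node list and edge list
#'
#' @param nodes Character vector of gene symbols (shared across states).
#' @param edges Data frame with `source`, `target` columns, a subset of
#'   `nodes`.
#' @param state Integer state index.
#' @return A `tm_state_graph`.
#' @export
tm_state_graph <- function(nodes, edges, state = 1L) {
  edges <- tibble::as_tibble(edges[, c("source", "target")])
  stopifnot(all(edges$source %in% nodes), all(edges$target %in% nodes))
  n <- length(nodes)
  adj <- Matrix::sparseMatrix(
    i = match(edges$source, nodes), j = match(edges$target, nodes),
    x = 1, dims = c(n, n), dimnames = list(nodes, nodes)
  )
  structure(list(state = as.integer(state), nodes = nodes, edges = edges,
                 adjacency = adj),
            class = "tm_state_graph")
}

#' @exportS3Method base::print
print.tm_state_graph <- function(x, ...) {
  cat(sprintf("<tm_state_graph> state %d: %d genes, %d directed edges\n",
              x$state, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Internal: igraph view of a state graph (directed or undirected).
state_igraph <- function(graph, directed = TRUE) {
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = graph$nodes)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  g
}
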