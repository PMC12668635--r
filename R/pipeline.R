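#' Pipeline configuration
#'
#' Gathers all tunable parameters of the end-to-end analysis. Defaults are
#' the package defaults used throughout: `alpha = 0.3` (local/global fusion
#' weight), `epsilon = 1e-2` (entropic regularization), `cmi_threshold =
#' 0.03` with conditioning orders 0-1 (network pruning), top-15% fallback
#' for gene selection, and the GAT/MLP configurations documented in
#' [tm_gat_config()] and [tm_mlp_config()].
#'
#' @param alpha Weight on the local topological profile, in \[0, 1\].
#' @param epsilon Entropic regularization of the GW alignment.
#' @param cmi_threshold,max_order PC-CMI pruning controls.
#' @param damping PageRank damping for the global profile.
#' @param fallback_fraction Top fraction of genes kept when knee detection
#'   fails.
#' @param lfc_min,p_max Differential-expression thresholds (used only when a
#'   reference/normal state is supplied).
#' @param gat A [tm_gat_config()].
#' @param gat_restarts Number of independently initialized embedding
#'   trainings per state; their (median-scaled) dissimilarity matrices are
#'   averaged before alignment, reducing initialization variance in the
#'   geometry.
#' @param mlp A [tm_mlp_config()].
#' @param classify Run the classification stage (default `TRUE`).
#' @param features Classifier input: `"dnb_plus_initial"` (default) feeds
#'   the biomarker genes together with the initial feature matrix (all
#'   analysis genes); `"dnb_only"` restricts the classifier to the DNB
#'   module's genes.
#' @param seed Global seed; all stage seeds are derived from it.
#' @return A list of class `tm_config`.
#' @export
tm_config <- function(alpha = 0.3, epsilon = 1e-2, cmi_threshold = 0.03,
                      max_order = 1, damping = 0.85,
                      fallback_fraction = 0.15, lfc_min = 1.0, p_max = 0.05,
                      gat = tm_gat_config(), gat_restarts = 3,
                      mlp = tm_mlp_config(), classify = TRUE,
                      features = c("dnb_plus_initial", "dnb_only"),
                      seed = 1L) {
  check_fraction(alpha, "alpha")
  check_fraction(fallback_fraction, "fallback_fraction", strict_lo = TRUE)
  check_fraction(damping, "damping", strict_lo = TRUE)
  stopifnot(epsilon > 0, cmi_threshold > 0, max_order %in% c(0, 1),
            inherits(gat, "tm_gat_config"), inherits(mlp, "tm_mlp_config"))
  stopifnot(gat_restarts >= 1)
  structure(list(alpha = alpha, epsilon = epsilon,
                 cmi_threshold = cmi_threshold, max_order = max_order,
                 damping = damping, fallback_fraction = fallback_fraction,
                 lfc_min = lfc_min, p_max = p_max, gat = gat,
                 gat_restarts = as.integer(gat_restarts), mlp = mlp,
                 classify = classify, features = match.arg(features),
                 seed = as.integer(seed)),
            class = "tm_config")
}

#' Run the full dynamic-network-biomarker pipeline
#'
#' Executes the complete analysis on a multi-state expression dataset:
#' state-specific network construction (PC-CMI pruning of the prior
#' network), topological similarity fusion, per-state GAT embedding,
#' entropic Gromov-Wasserstein alignment of consecutive states, cumulative
#' alignment scoring, knee-point gene selection, union-component extraction
#' and DNI ranking, and (optionally) multiclass state classification on the
#' selected biomarker genes.
#'
#' @param dataset A `tm_dataset` from the simulator, or a named list of
#'   genes x cells count matrices in state order.
#' @param prior Directed prior regulatory edge list (data frame with
#'   `source`, `target`). Defaults to the ground-truth union network when
#'   `dataset` is a simulated `tm_dataset`.
#' @param config A [tm_config()].
#' @param normal_counts Optional reference-state count matrix; when given,
#'   genes are first filtered to the DEG union (plus `pathway_genes`) before
#'   mapping onto the prior.
#' @param pathway_genes Optional extra gene symbols added to the DEG union.
#' @param out_dir Optional directory; when given, per-stage TSV outputs and
#'   a reproducibility manifest are written there.
#' @return An object of class `tm_run`: list with `graphs`, `structures`,
#'   `embeddings`, `plans`, `scores`, `selected`, `reports`, `dnb_genes`,
#'   `metrics` (NULL unless classification ran), `config`, `timings`.
#' @export
tm_run_pipeline <- function(dataset, prior = NULL, config = tm_config(),
                            normal_counts = NULL, pathway_genes = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(config, "tm_config"))
  counts <- if (inherits(dataset, "tm_dataset")) dataset$counts else dataset
  stopifnot(is.list(counts), length(counts) >= 2)
  if (is.null(prior)) {
    if (!inherits(dataset, "tm_dataset")) {
      abort("`prior` is required unless `dataset` is a simulated tm_dataset")
    }
    prior <- tm_grn_union_edges(dataset$grn)
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # stage 1: gene universe and state-specific rewired networks
  genes <- rownames(counts[[1]])
  if (!is.null(normal_counts)) {
    degs <- purrr::map_dfr(seq_along(counts), function(t) {
      dplyr::mutate(
        tm_identify_degs(counts[[t]], normal_counts,
                         lfc_min = config$lfc_min, p_max = config$p_max),
        state = t)
    })
    genes <- union(unique(degs$gene[degs$selected]), pathway_genes)
  }
  background <- tm_assemble_background(genes, prior, pathway_genes)
  if (nrow(background$edges) == 0L) {
    abort("background network is empty; cannot continue")
  }
  graphs <- lapply(seq_along(counts), function(t) {
    g <- tm_pc_cmi_prune(background, counts[[t]], max_order = config$max_order,
                         cmi_threshold = config$cmi_threshold, state = t)
    if (nrow(g$edges) == 0L) {
      # degenerate state: pruning removed everything, keep the prior edges
      # so downstream stages have a network to work with
      warn(sprintf("state %d: all edges pruned; falling back to the background network", t))
      g <- tm_state_graph(background$nodes, background$edges, state = t)
    }
    g
  })
  timings["networks"] <- tic() - t0; t0 <- tic()

  # stage 2: fused local/global structural similarity
  structures <- lapply(graphs, tm_structural_similarity,
                       alpha = config$alpha, damping = config$damping)
  timings["topology"] <- tic() - t0; t0 <- tic()

  # stage 3: per-state GAT embeddings (restart-averaged geometry)
  nodes <- graphs[[1]]$nodes
  fits <- lapply(seq_along(graphs), function(t) {
    feats <- tm_normalize_counts(counts[[t]][nodes, , drop = FALSE])
    lapply(seq_len(config$gat_restarts), function(r) {
      cfg <- config$gat
      cfg$seed <- derive_seed(config$seed, sprintf("gat%d.%d", t, r))
      tm_train_embedding(feats, structures[[t]], graphs[[t]], cfg)
    })
  })
  embeddings <- lapply(fits, `[[`, 1L)
  timings["embedding"] <- tic() - t0; t0 <- tic()

  # stage 4: consecutive-state GW alignment on the averaged geometry
  dmats <- lapply(fits, function(fs) {
    Reduce(`+`, lapply(fs, tm_embedding_dissimilarity, scale_median = TRUE)) /
      length(fs)
  })
  plans <- lapply(seq_len(length(dmats) - 1L), function(t) {
    tm_entropic_gw(dmats[[t]], dmats[[t + 1L]], epsilon = config$epsilon)
  })
  scores <- tm_alignment_scores(plans)
  timings["alignment"] <- tic() - t0; t0 <- tic()

  # stage 5: biomarker module selection
  selected <- tm_elbow_select(scores,
                              fallback_fraction = config$fallback_fraction)
  components <- tm_union_components(selected, graphs)
  reports <- tm_select_dnb(components, graphs, scores)
  dnb_genes <- reports$genes[[1]]
  timings["selection"] <- tic() - t0; t0 <- tic()

  # stage 6: multiclass state classification. By default the classifier
  # receives the biomarker genes together with the initial feature matrix
  # (all analysis genes); "dnb_only" restricts it to the module itself.
  metrics <- NULL
  if (config$classify) {
    panel <- if (config$features == "dnb_plus_initial") {
      union(dnb_genes, nodes)
    } else {
      dnb_genes
    }
    ds <- tm_assemble_dataset(counts, panel)
    mlp_cfg <- config$mlp
    mlp_cfg$seed <- derive_seed(config$seed, "mlp")
    metrics <- tm_train_and_evaluate(ds$x, ds$y, mlp_cfg)
  }
  timings["classification"] <- tic() - t0

  run <- structure(
    list(graphs = graphs, structures = structures, embeddings = embeddings,
         plans = plans, scores = scores, selected = selected,
         components = components, reports = reports, dnb_genes = dnb_genes,
         metrics = metrics, config = config, timings = timings),
    class = "tm_run"
  )
  if (!is.null(out_dir)) tm_write_run(run, out_dir)
  run
}

#' @exportS3Method base::print
print.tm_run <- function(x, ...) {
  cat(sprintf(
    "<tm_run> %d states, %d genes; %d selected, DNB module of %d gene(s) (DNI %.4f)\n",
    length(x$graphs), length(x$graphs[[1]]$nodes), length(x$selected),
    length(x$dnb_genes), x$reports$dni[1]
  ))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Write pipeline outputs and a reproducibility manifest
#'
#' @param run A `tm_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
tm_write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(run$scores, file.path(dir, "alignment_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(run$dnb_genes, file.path(dir, "dnb_genes.txt"))
  dnb_tbl <- tidyr::unnest(
    dplyr::select(run$reports, "component", "rank", "dni", "genes"),
    "genes")
  write.table(dnb_tbl, file.path(dir, "components.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (t in seq_along(run$graphs)) {
    write.table(run$graphs[[t]]$edges,
                file.path(dir, sprintf("state_%d_edges.tsv", t)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$metrics)) {
    write.table(run$metrics$summary, file.path(dir, "metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    seed = run$config$seed,
    alpha = run$config$alpha, epsilon = run$config$epsilon,
    cmi_threshold = run$config$cmi_threshold,
    fallback_fraction = run$config$fallback_fraction,
    n_states = length(run$graphs),
    n_genes = length(run$graphs[[1]]$nodes),
    dnb_genes = run$dnb_genes,
    timings = as.list(run$timings),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a directory of per-state expression matrices
#'
#' Reads one matrix per declared state, either `<state>.csv`/`<state>.tsv`
#' (genes x cells with a header of cell barcodes and gene symbols in the
#' first column) or a MatrixMarket triplet `<state>.mtx` +
#' `<state>.genes.tsv` + `<state>.barcodes.tsv`. Matrices are aligned to the
#' intersection of their gene indices in declared state order; dropped genes
#' are reported.
#'
#' @param path Directory containing the matrices.
#' @param states Character vector of state file stems, in disease order.
#' @return Named list of genes x cells integer matrices.
#' @export
tm_load_expression_dir <- function(path, states) {
  if (!dir.exists(path)) abort(sprintf("directory not found: %s", path))
  stopifnot(length(states) >= 2)
  read_one <- function(s) {
    mtx <- file.path(path, paste0(s, ".mtx"))
    csv <- file.path(path, paste0(s, ".csv"))
    tsv <- file.path(path, paste0(s, ".tsv"))
    if (file.exists(mtx)) {
      m <- as.matrix(Matrix::readMM(mtx))
      rownames(m) <- readLines(file.path(path, paste0(s, ".genes.tsv")))
      colnames(m) <- readLines(file.path(path, paste0(s, ".barcodes.tsv")))
    } else if (file.exists(csv) || file.exists(tsv)) {
      f <- if (file.exists(csv)) csv else tsv
      d <- read.delim(f, sep = if (file.exists(csv)) "," else "\t",
                      row.names = 1, check.names = FALSE)
      m <- as.matrix(d)
    } else {
      abort(sprintf("no matrix found for state '%s' in %s", s, path))
    }
    if (anyDuplicated(rownames(m))) {
      abort(sprintf("duplicate gene symbols in state '%s'", s))
    }
    m
  }
  mats <- lapply(states, read_one)
  names(mats) <- states
  shared <- Reduce(intersect, lapply(mats, rownames))
  dropped <- length(unique(unlist(lapply(mats, rownames)))) - length(shared)
  if (dropped > 0) {
    message(sprintf("dropped %d gene(s) absent from some states", dropped))
  }
  lapply(mats, function(m) m[shared, , drop = FALSE])
}
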