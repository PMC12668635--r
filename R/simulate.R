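#' Noise configuration for the expression simulator
#'
#' Collects the stochastic layers applied on top of the deterministic
#' steady-state kinetics, in the order they act on a cell:
#' cell-to-cell extrinsic variability, multiplicative technical noise,
#' expression-dependent dropout, and Poisson UMI sampling under a per-cell
#' library size.
#'
#' @param cell_sd Log-normal sd of per-cell, per-gene basal-rate variability
#'   (extrinsic noise). 0 disables it.
#' @param technical_sd Log-normal sd of multiplicative technical noise on the
#'   steady-state abundance. 0 disables it.
#' @param dropout_max Maximum dropout probability, attained as expression
#'   tends to zero.
#' @param dropout_scale Expression scale of the dropout decay: a molecule
#'   level `y` is dropped with probability `dropout_max * exp(-y / dropout_scale)`.
#'   `Inf` makes dropout expression-independent at `dropout_max`.
#' @param lib_scale Mean library-size multiplier mapping steady-state
#'   abundance to expected UMI counts.
#' @param lib_sd Log-normal sd of the per-cell library size. 0 disables it.
#' @return A list of class `tm_noise_config`.
#' @export
tm_noise_config <- function(cell_sd = 0.9, technical_sd = 0.3,
                            dropout_max = 0.35, dropout_scale = 1.5,
                            lib_scale = 10, lib_sd = 0.15) {
  check_fraction(dropout_max, "dropout_max")
  stopifnot(cell_sd >= 0, technical_sd >= 0, dropout_scale > 0,
            lib_scale > 0, lib_sd >= 0)
  structure(list(cell_sd = cell_sd, technical_sd = technical_sd,
                 dropout_max = dropout_max, dropout_scale = dropout_scale,
                 lib_scale = lib_scale, lib_sd = lib_sd),
            class = "tm_noise_config")
}

# Internal: steady-state abundances for one state's edge set, vectorized over
# cells. `basal_mat` is genes x cells. Regulation is Hill-type: an activator
# contributes strength * x^h / (x^h + K^h), a repressor |strength| * K^h /
# (x^h + K^h); with first-order degradation the steady state equals the
# production rate, evaluated gene-by-gene in topological (index) order.
steady_state_expression <- function(genes, edges, basal_mat,
                                    hill_coef = 2, hill_k = 2) {
  x <- basal_mat
  parents <- split(seq_len(nrow(edges)), edges$target)
  for (g in genes) {
    pe <- parents[[g]]
    if (is.null(pe)) next
    gi <- match(g, genes)
    for (e in pe) {
      r <- match(edges$source[e], genes)
      s <- edges$strength[e]
      hx <- x[r, ]^hill_coef
      hill <- hx / (hx + hill_k^hill_coef)
      x[gi, ] <- x[gi, ] + if (s > 0) s * hill else -s * (1 - hill)
    }
    if (any(!is.finite(x[gi, ]))) {
      abort(sprintf("non-finite steady state for gene %s", g))
    }
  }
  x
}

#' Simulate multi-state single-cell UMI counts from a ground-truth network
#'
#' For every disease state of a rewired `tm_grn`, solves per-gene
#' steady-state production/degradation kinetics with Hill-type regulation,
#' samples per-cell basal rates, then applies multiplicative log-normal
#' technical noise, Bernoulli dropout with expression-dependent probability,
#' and Poisson UMI sampling scaled by a per-cell library size. State
#' differences in the counts arise solely from the state-specific edge sets,
#' so rewired (switcher) genes are the ones whose expression shifts across
#' states.
#'
#' @param grn A `tm_grn`, normally after [tm_rewire_states()].
#' @param n_cells_per_state Number of cells simulated per state.
#' @param noise A [tm_noise_config()].
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param hill_coef,hill_k Hill coefficient and half-saturation constant of
#'   the regulation function.
#' @return An object of class `tm_dataset`: list with `counts` (named list of
#'   integer genes x cells matrices, one per state), `states` (state names in
#'   order), `grn`, and `seed`.
#' @export
tm_simulate_expression <- function(grn, n_cells_per_state = 100,
                                   noise = tm_noise_config(), seed = 1L,
                                   hill_coef = 2, hill_k = 2) {
  stopifnot(inherits(grn, "tm_grn"), inherits(noise, "tm_noise_config"))
  if (n_cells_per_state < 1L) abort("`n_cells_per_state` must be >= 1")
  genes <- grn$genes
  n_states <- length(grn$states)
  state_names <- sprintf("state_%d", seq_len(n_states))

  counts <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_states), function(t) {
      n <- length(genes) * n_cells_per_state
      basal <- matrix(grn$basal, nrow = length(genes),
                      ncol = n_cells_per_state)
      if (noise$cell_sd > 0) {
        basal <- basal * matrix(rlnorm(n, 0, noise$cell_sd), nrow = length(genes))
      }
      x <- steady_state_expression(genes, grn$states[[t]], basal,
                                   hill_coef, hill_k)
      y <- x
      if (noise$technical_sd > 0) {
        y <- y * matrix(rlnorm(n, 0, noise$technical_sd), nrow = length(genes))
      }
      keep <- 1
      if (noise$dropout_max > 0) {
        p_drop <- noise$dropout_max *
          if (is.finite(noise$dropout_scale)) exp(-y / noise$dropout_scale) else 1
        keep <- matrix(rbinom(n, 1L, 1 - p_drop), nrow = length(genes))
      }
      lib <- noise$lib_scale *
        (if (noise$lib_sd > 0) rlnorm(n_cells_per_state, 0, noise$lib_sd) else 1)
      lambda <- sweep(y * keep, 2L, lib, "*")
      m <- matrix(rpois(n, lambda), nrow = length(genes),
                  dimnames = list(genes, sprintf("cell_%04d", seq_len(n_cells_per_state))))
      storage.mode(m) <- "integer"
      m
    })
  })
  names(counts) <- state_names
  structure(list(counts = counts, states = state_names, grn = grn, seed = seed),
            class = "tm_dataset")
}

#' @exportS3Method base::print
print.tm_dataset <- function(x, ...) {
  cat(sprintf("<tm_dataset> %d genes x %d cells in %d state(s); seed %d\n",
              nrow(x$counts[[1]]), ncol(x$counts[[1]]), length(x$counts),
              x$seed))
  invisible(x)
}

#' Simulation preset mirroring the benchmark study design
#'
#' One call that generates, rewires and simulates a dataset under the
#' benchmark conditions: four disease states, 100 cells per state, and a
#' regulon-structured network (see [tm_generate_modular_grn()]) in which a
#' driver compartment -- whole regulons plus their TFs, covering roughly a
#' third of the genes -- has 20% of the network's edges swapped at each
#' state transition, while the remaining regulons stay intact. Rewiring
#' concentrated on a coherent subnetwork is what disease-progression
#' rewiring looks like, and it gives the simulation a ground-truth dynamic
#' module for the pipeline to recover.
#'
#' @param n_genes Network size (the study uses 30, 50 and 100).
#' @param n_states Number of disease states.
#' @param n_cells_per_state Cells per state.
#' @param rewire_fraction Fraction of edges swapped per transition.
#' @param noise A [tm_noise_config()].
#' @param seed Integer seed.
#' @return A `tm_dataset`.
#' @export
tm_simulate_benchmark <- function(n_genes, n_states = 4,
                                  n_cells_per_state = 100,
                                  rewire_fraction = 0.2,
                                  noise = tm_noise_config(), seed = 1L) {
  grn <- tm_generate_modular_grn(n_genes, seed = derive_seed(seed, "grn"))
  # driver compartment: whole regulons (plus their TFs) covering ~30% of genes
  drivers <- withr::with_seed(derive_seed(seed, "drivers"), {
    mods <- grn$modules[!is.na(grn$modules)]
    picked <- character(0)
    for (m in sample(unique(mods))) {
      members <- names(mods)[mods == m]
      tfs <- unique(grn$edges$source[grn$edges$target %in% members])
      picked <- unique(c(picked, members, tfs))
      if (length(picked) >= 0.3 * n_genes) break
    }
    picked
  })
  grn <- tm_rewire_states(grn, n_states, rewire_fraction,
                          seed = derive_seed(seed, "rewire"),
                          drivers = drivers)
  tm_simulate_expression(grn, n_cells_per_state, noise,
                         seed = derive_seed(seed, "expr"))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes one MatrixMarket triplet (`state_k.mtx`, `state_k.genes.tsv`,
#' `state_k.barcodes.tsv`) per state, the multi-state GRN as a TSV edge list
#' with columns `source`, `target`, `strength`, `state`, and the ground-truth
#' switcher genes as a one-column text file.
#'
#' @param dataset A `tm_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
tm_write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tm_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(dataset$counts)) {
    m <- dataset$counts[[s]]
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                    file.path(dir, paste0(s, ".mtx")))
    writeLines(rownames(m), file.path(dir, paste0(s, ".genes.tsv")))
    writeLines(colnames(m), file.path(dir, paste0(s, ".barcodes.tsv")))
  }
  grn_tbl <- purrr::imap_dfr(dataset$grn$states, function(e, t) {
    dplyr::mutate(e, state = t)
  })
  write.table(grn_tbl, file.path(dir, "grn_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(dataset$grn$switchers, file.path(dir, "switchers.txt"))
  invisible(dir)
}
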