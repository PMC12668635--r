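#' Assemble a classification dataset from multi-state expression
#'
#' Stacks the cells of all states into one feature matrix restricted to the
#' selected biomarker genes (log-normalized), with the state index as label.
#'
#' @param dataset A `tm_dataset`, or a named list of genes x cells count
#'   matrices in state order.
#' @param dnb_genes Nonempty character vector of biomarker genes, all present
#'   in the shared gene index.
#' @return A list with `x` (cells x genes matrix) and `y` (integer state
#'   labels, 1-based).
#' @export
tm_assemble_dataset <- function(dataset, dnb_genes) {
  counts <- if (inherits(dataset, "tm_dataset")) dataset$counts else dataset
  stopifnot(is.list(counts), length(counts) >= 1)
  if (length(counts) < 2L) abort("multiclass classification needs >= 2 states")
  if (length(dnb_genes) == 0L) abort("`dnb_genes` is empty")
  missing <- setdiff(dnb_genes, rownames(counts[[1]]))
  if (length(missing) > 0L) {
    abort(sprintf("biomarker genes absent from the expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  xs <- lapply(seq_along(counts), function(t) {
    norm <- tm_normalize_counts(counts[[t]])
    t(norm[dnb_genes, , drop = FALSE])
  })
  list(x = do.call(rbind, xs),
       y = rep(seq_along(counts), vapply(xs, nrow, integer(1))))
}

#' Configuration of the state classifier
#'
#' A multilayer perceptron with three ReLU hidden layers of 128, 64 and 32
#' units, a softmax output, categorical cross-entropy weighted by inverse
#' class frequency `n_total / (k * n_c)`, Adam optimization, and early
#' stopping on validation macro AUROC.
#'
#' @param hidden Hidden layer widths.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation AUROC
#'   improvement).
#' @param n_runs Number of repeated train/evaluate runs to aggregate.
#' @param seed Integer seed; per-run seeds are derived from it.
#' @return A list of class `tm_mlp_config`.
#' @export
tm_mlp_config <- function(hidden = c(128, 64, 32), learning_rate = 0.001,
                          batch_size = 32, max_epochs = 500, patience = 50,
                          n_runs = 10, seed = 1L) {
  stopifnot(all(hidden >= 1), learning_rate > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1, n_runs >= 1)
  structure(list(hidden = hidden, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, n_runs = n_runs,
                 seed = as.integer(seed)),
            class = "tm_mlp_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = n_total / (k * n_c)` for each of the `k` classes.
#'
#' @param y Integer class labels (1-based).
#' @param k Number of classes.
#' @return Numeric vector of length `k`.
#' @export
tm_class_weights <- function(y, k = max(y)) {
  counts <- tabulate(y, nbins = k)
  length(y) / (k * counts)
}

# Internal: stratified 70/10/20 split preserving class proportions within
# one sample. Returns index vectors.
stratified_split <- function(y, train = 0.7, val = 0.1) {
  idx <- split(seq_along(y), y)
  parts <- lapply(idx, function(ii) {
    ii <- sample(ii)
    n <- length(ii)
    n_tr <- round(train * n)
    n_va <- round(val * n)
    if (n_tr < 1 || n_va < 1 || n - n_tr - n_va < 1) {
      abort("a class is too small for a stratified 70/10/20 split")
    }
    list(train = ii[seq_len(n_tr)],
         val = ii[n_tr + seq_len(n_va)],
         test = ii[(n_tr + n_va + 1):n])
  })
  list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
       val = unlist(lapply(parts, `[[`, "val"), use.names = FALSE),
       test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
}

# Internal: forward pass of the MLP. Returns per-layer activations.
mlp_forward <- function(X, params) {
  acts <- list(X)
  n_layers <- length(params$W)
  for (l in seq_len(n_layers)) {
    Z <- acts[[l]] %*% params$W[[l]] + matrix(params$b[[l]], nrow(X),
                                              length(params$b[[l]]),
                                              byrow = TRUE)
    acts[[l + 1]] <- if (l < n_layers) pmax(Z, 0) else Z
  }
  logits <- acts[[n_layers + 1]]
  mx <- apply(logits, 1L, max)
  ez <- exp(logits - mx)
  probs <- ez / rowSums(ez)
  list(acts = acts, probs = probs)
}

# Internal: train one MLP. X scaled features, y integer labels (1..k).
mlp_train <- function(X_tr, y_tr, X_va, y_va, k, cfg) {
  dims <- c(ncol(X_tr), cfg$hidden, k)
  params <- list(W = list(), b = list())
  for (l in seq_len(length(dims) - 1)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))
    params$W[[l]] <- matrix(runif(dims[l] * dims[l + 1], -lim, lim),
                            dims[l], dims[l + 1])
    params$b[[l]] <- rep(0, dims[l + 1])
  }
  zero_like <- function(p) list(W = lapply(p$W, function(x) x * 0),
                                b = lapply(p$b, function(x) x * 0))
  m_st <- zero_like(params); v_st <- zero_like(params)
  w_class <- tm_class_weights(y_tr, k)
  n_tr <- nrow(X_tr)
  best <- list(auroc = -Inf, params = params)
  wait <- 0L; step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n_tr)
    for (start in seq(1, n_tr, by = cfg$batch_size)) {
      bi <- perm[start:min(start + cfg$batch_size - 1, n_tr)]
      Xb <- X_tr[bi, , drop = FALSE]
      yb <- y_tr[bi]
      fw <- mlp_forward(Xb, params)
      wb <- w_class[yb]
      # weighted softmax CE gradient wrt logits
      G <- fw$probs
      G[cbind(seq_along(yb), yb)] <- G[cbind(seq_along(yb), yb)] - 1
      G <- G * wb / sum(wb)
      step <- step + 1L
      n_layers <- length(params$W)
      for (l in rev(seq_len(n_layers))) {
        A_prev <- fw$acts[[l]]
        gW <- t(A_prev) %*% G
        gb <- colSums(G)
        if (l > 1) {
          G <- (G %*% t(params$W[[l]])) * (fw$acts[[l]] > 0)
        }
        m_st$W[[l]] <- beta1 * m_st$W[[l]] + (1 - beta1) * gW
        v_st$W[[l]] <- beta2 * v_st$W[[l]] + (1 - beta2) * gW^2
        m_st$b[[l]] <- beta1 * m_st$b[[l]] + (1 - beta1) * gb
        v_st$b[[l]] <- beta2 * v_st$b[[l]] + (1 - beta2) * gb^2
        params$W[[l]] <- params$W[[l]] - cfg$learning_rate *
          (m_st$W[[l]] / (1 - beta1^step)) /
          (sqrt(v_st$W[[l]] / (1 - beta2^step)) + eps)
        params$b[[l]] <- params$b[[l]] - cfg$learning_rate *
          (m_st$b[[l]] / (1 - beta1^step)) /
          (sqrt(v_st$b[[l]] / (1 - beta2^step)) + eps)
      }
    }
    # early stopping on validation macro AUROC; ties (e.g. AUROC pinned at
    # 1 on separable data) break toward the lower validation loss so the
    # restored weights are the best-calibrated ones
    probs_va <- mlp_forward(X_va, params)$probs
    aucs <- vapply(seq_len(k), function(c) tm_auroc(y_va == c, probs_va[, c]),
                   numeric(1))
    val_auroc <- mean(aucs, na.rm = TRUE)
    val_loss <- -mean(w_class[y_va] *
                        log(pmax(probs_va[cbind(seq_along(y_va), y_va)],
                                 1e-12)))
    if (val_auroc > best$auroc + 1e-12) {
      best <- list(auroc = val_auroc, loss = val_loss, params = params)
      wait <- 0L
    } else {
      if (abs(val_auroc - best$auroc) <= 1e-12 &&
          (is.null(best$loss) || val_loss < best$loss)) {
        best$loss <- val_loss
        best$params <- params
      }
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  best$params
}

#' Train and evaluate the state classifier over repeated runs
#'
#' For each run: a stratified 70/10/20 train/validation/test split, feature
#' standardization fitted on the training set, MLP training with
#' class-weighted cross-entropy and early stopping on validation macro
#' AUROC (best weights restored), then the seven metrics on the held-out
#' test set. Results are aggregated as mean and standard deviation over
#' runs.
#'
#' @param x Cells x genes feature matrix (e.g. from
#'   [tm_assemble_dataset()]).
#' @param y Integer state labels (1-based).
#' @param cfg A [tm_mlp_config()].
#' @return An object of class `tm_metrics`: list with `summary` (tibble of
#'   metric, mean, sd), `runs` (per-run tibble), `n_runs`, `seed`.
#' @export
tm_train_and_evaluate <- function(x, y, cfg = tm_mlp_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(as.factor(y))
  k <- max(y)
  if (k < 2L) abort("need at least 2 classes")
  if (min(tabulate(y)) < 10L) abort("need at least 10 samples per class")

  runs <- purrr::map_dfr(seq_len(cfg$n_runs), function(r) {
    withr::with_seed(derive_seed(cfg$seed, paste0("run", r)), {
      sp <- stratified_split(y)
      mu <- colMeans(x[sp$train, , drop = FALSE])
      sg <- apply(x[sp$train, , drop = FALSE], 2L, sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      scale_x <- function(m) sweep(sweep(m, 2L, mu), 2L, sg, "/")
      params <- mlp_train(scale_x(x[sp$train, , drop = FALSE]), y[sp$train],
                          scale_x(x[sp$val, , drop = FALSE]), y[sp$val],
                          k, cfg)
      probs <- mlp_forward(scale_x(x[sp$test, , drop = FALSE]), params)$probs
      dplyr::mutate(tm_compute_metrics(y[sp$test], probs), run = r)
    })
  })

  metric_cols <- setdiff(names(runs), "run")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(runs[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) sd(runs[[m]]), numeric(1))
  )
  structure(list(summary = summary, runs = runs, n_runs = cfg$n_runs,
                 seed = cfg$seed),
            class = "tm_metrics")
}

#' @exportS3Method base::print
print.tm_metrics <- function(x, ...) {
  cat(sprintf("<tm_metrics> %d run(s)\n", x$n_runs))
  with(x$summary, for (i in seq_along(metric)) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", metric[i], mean[i], sd[i]))
  })
  invisible(x)
}
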