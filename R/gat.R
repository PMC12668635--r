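#' Configuration of the graph attention embedder
#'
#' Defaults follow the embedding module design: a first layer with 64 hidden
#' units split over 2 attention heads, a single-head 62-dimensional output
#' layer, dropout 0.6, Adam with learning rate 0.001 and weight decay 5e-4,
#' and early stopping when the reconstruction loss fails to improve for 50
#' consecutive epochs.
#'
#' @param hidden_units Width of the first layer (total over heads; must be
#'   divisible by `heads`).
#' @param heads Number of attention heads in the first layer.
#' @param output_dim Embedding dimension of the single-head second layer.
#' @param dropout Dropout rate on layer inputs during training, in \[0, 1).
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Maximum training epochs.
#' @param leaky_slope Negative slope of the LeakyReLU used on attention
#'   logits.
#' @param loss_mode `"full"` scores all N^2 adjacency entries in the
#'   reconstruction loss; `"sampled"` scores all positives plus an equal
#'   number of uniformly sampled negatives per epoch; `"auto"` (default)
#'   uses `"full"` for graphs with at most 500 nodes.
#' @param seed Integer seed for initialization, dropout and negative
#'   sampling.
#' @return A list of class `tm_gat_config`.
#' @export
tm_gat_config <- function(hidden_units = 64, heads = 2, output_dim = 62,
                          dropout = 0.6, learning_rate = 0.001,
                          weight_decay = 5e-4, patience = 50,
                          max_epochs = 1000, leaky_slope = 0.2,
                          loss_mode = c("auto", "full", "sampled"),
                          seed = 1L) {
  stopifnot(hidden_units >= 1, heads >= 1, hidden_units %% heads == 0,
            output_dim >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, weight_decay >= 0, patience >= 1,
            max_epochs >= 1)
  structure(list(hidden_units = hidden_units, heads = heads,
                 output_dim = output_dim, dropout = dropout,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 patience = patience, max_epochs = max_epochs,
                 leaky_slope = leaky_slope,
                 loss_mode = match.arg(loss_mode), seed = as.integer(seed)),
            class = "tm_gat_config")
}

# Internal activation helpers (ELU with alpha = 1).
elu <- function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
elu_grad <- function(z) ifelse(z > 0, 1, exp(pmin(z, 0)))
lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
lrelu_grad <- function(z, slope) ifelse(z > 0, 1, slope)

# Internal: Glorot-uniform parameter initialization for one attention head.
init_head <- function(m_in, f_out) {
  lim <- sqrt(6 / (m_in + f_out))
  list(W = matrix(runif(m_in * f_out, -lim, lim), m_in, f_out),
       a_src = runif(f_out, -lim, lim),
       a_dst = runif(f_out, -lim, lim))
}

# Internal: forward pass of one attention head.
# H: N x M input; mask: logical N x N neighborhoods; logS: log structure
# weights (masked entries finite, off-mask -Inf). Returns intermediates
# needed by the backward pass.
head_forward <- function(H, par, mask, logS, slope) {
  U <- H %*% par$W
  s <- as.numeric(U %*% par$a_src)
  t_ <- as.numeric(U %*% par$a_dst)
  Z0 <- outer(s, t_, "+")
  L <- lrelu(Z0, slope)
  logits <- ifelse(mask, L + logS, -Inf)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  ex[!mask] <- 0
  P <- ex / rowSums(ex)
  Z <- P %*% U
  list(U = U, Z0 = Z0, P = P, Z = Z, out = elu(Z))
}

# Internal: backward pass of one attention head. G_out is the gradient of
# the loss wrt the head's activated output. Returns parameter gradients and
# the gradient wrt the head input H.
head_backward <- function(G_out, fw, H, par, mask, slope) {
  G_Z <- G_out * elu_grad(fw$Z)
  G_P <- G_Z %*% t(fw$U)
  G_P[!mask] <- 0
  G_U <- t(fw$P) %*% G_Z
  # softmax rows: dlogit = P * (G_P - rowSums(P * G_P))
  row_dot <- rowSums(fw$P * G_P)
  G_logit <- fw$P * (G_P - row_dot)
  G_Z0 <- G_logit * lrelu_grad(fw$Z0, slope)
  G_Z0[!mask] <- 0
  g_s <- rowSums(G_Z0)
  g_t <- colSums(G_Z0)
  G_U <- G_U + outer(g_s, par$a_src) + outer(g_t, par$a_dst)
  list(W = t(H) %*% G_U,
       a_src = as.numeric(t(fw$U) %*% g_s),
       a_dst = as.numeric(t(fw$U) %*% g_t),
       H = G_U %*% t(par$W))
}

# Internal: flatten/apply Adam updates over a nested parameter list.
adam_step <- function(params, grads, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (pn in names(params[[nm]])) {
      g <- grads[[nm]][[pn]] + wd * params[[nm]][[pn]]
      state$m[[nm]][[pn]] <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g
      state$v[[nm]][[pn]] <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[pn]] / (1 - beta1^t)
      vhat <- state$v[[nm]][[pn]] / (1 - beta2^t)
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# Internal: full two-layer forward pass. drop_masks NULL for evaluation.
gat_forward <- function(H, params, mask, logS, cfg, drop_masks = NULL) {
  H1_in <- if (is.null(drop_masks)) H else H * drop_masks$l1
  heads <- lapply(params$layer1, function(p) {
    head_forward(H1_in, p, mask, logS, cfg$leaky_slope)
  })
  H1 <- do.call(cbind, lapply(heads, `[[`, "out"))
  H2_in <- if (is.null(drop_masks)) H1 else H1 * drop_masks$l2
  top <- head_forward(H2_in, params$layer2[[1]], mask, logS, cfg$leaky_slope)
  list(heads = heads, H1 = H1, H1_in = H1_in, H2_in = H2_in, top = top,
       E = top$out)
}

#' Reconstruct an adjacency matrix from embeddings
#'
#' Edge likelihood between genes i and j is the logistic sigmoid of the dot
#' product of their embedding rows, giving a symmetric matrix with entries in
#' (0, 1).
#'
#' @param E An embedding matrix (rows = genes) or a `tm_embedding`.
#' @return An N x N numeric matrix.
#' @export
tm_reconstruct_adjacency <- function(E) {
  if (inherits(E, "tm_embedding")) E <- E$E
  stopifnot(is.matrix(E), all(is.finite(E)))
  1 / (1 + exp(-tcrossprod(E)))
}

#' Adjacency reconstruction loss (binary cross-entropy)
#'
#' Sum over the scored entry set of
#' `-[A log(Ahat) + (1 - A) log(1 - Ahat)]`. Predicted probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` so the loss stays finite.
#'
#' @param A Binary target adjacency matrix.
#' @param A_hat Predicted edge probabilities, same shape.
#' @param weights Optional 0/1 matrix selecting the scored entries (default:
#'   all).
#' @return A nonnegative scalar.
#' @export
tm_reconstruction_loss <- function(A, A_hat, weights = NULL) {
  if (!identical(dim(A), dim(A_hat))) abort("shape mismatch")
  A_hat <- pmin(pmax(A_hat, 1e-7), 1 - 1e-7)
  ll <- -(A * log(A_hat) + (1 - A) * log(1 - A_hat))
  if (!is.null(weights)) ll <- ll * weights
  sum(ll)
}

#' Train an unsupervised graph attention embedding for one state
#'
#' Two GAT layers are trained to reconstruct the state adjacency from
#' embedding dot products. Attention neighborhoods are the state's regulatory
#' edges (symmetrized, plus self-loops); the fused structural similarity
#' S(t) enters as a multiplicative weight on the attention logits, biasing
#' attention toward topologically proximal neighbors. Training minimizes the
#' binary cross-entropy between `sigmoid(E E^T)` and the symmetrized
#' adjacency using Adam, with early stopping on the (dropout-free) epoch
#' loss; the returned embedding comes from the best-loss epoch.
#'
#' @param features N x M numeric matrix of node features, row-aligned with
#'   the graph's node list (typically log-normalized expression).
#' @param structure A `tm_structure` (or an N x N similarity matrix).
#' @param graph A `tm_state_graph` with at least one edge.
#' @param cfg A [tm_gat_config()].
#' @return An object of class `tm_embedding`: list with `E` (N x d matrix,
#'   gene rownames), `loss` (best loss), `epochs_run`, `loss_curve`, and
#'   `state`.
#' @export
tm_train_embedding <- function(features, structure, graph,
                               cfg = tm_gat_config()) {
  stopifnot(inherits(graph, "tm_state_graph"), is.matrix(features))
  n <- length(graph$nodes)
  if (nrow(features) != n) abort("`features` must be row-aligned with nodes")
  if (nrow(graph$edges) == 0L) abort("graph has no edges; no neighborhoods to attend over")
  S <- if (inherits(structure, "tm_structure")) structure$S else structure
  stopifnot(identical(dim(S), c(n, n)))

  # per-gene standardization keeps initial activations O(1); without it the
  # reconstruction logits start deeply saturated and training stalls
  features <- t(scale(t(features)))
  features[!is.finite(features)] <- 0

  A_dir <- as.matrix(graph$adjacency)
  A_sym <- pmin(A_dir + t(A_dir), 1)
  diag(A_sym) <- 1
  mask <- A_sym > 0
  logS <- suppressWarnings(log(pmax(S, 1e-300)))
  target <- A_sym

  m_in <- ncol(features)
  f1 <- cfg$hidden_units %/% cfg$heads
  # sampled negatives are the default: scoring every non-edge over-penalizes
  # structurally equivalent (co-regulated) genes, which must stay
  # interchangeable in the embedding geometry; full scoring is kept for
  # exactness checks on small graphs
  full_mode <- cfg$loss_mode == "full"

  withr::with_seed(cfg$seed, {
    params <- list(
      layer1 = lapply(seq_len(cfg$heads), function(k) init_head(m_in, f1)),
      layer2 = list(init_head(cfg$hidden_units, cfg$output_dim))
    )
    # flatten layer lists into named entries for the optimizer
    flat <- function(p) {
      out <- list()
      for (k in seq_along(p$layer1)) out[[paste0("l1h", k)]] <- p$layer1[[k]]
      out[["l2"]] <- p$layer2[[1]]
      out
    }
    unflat <- function(f, heads) {
      list(layer1 = lapply(seq_len(heads), function(k) f[[paste0("l1h", k)]]),
           layer2 = list(f[["l2"]]))
    }
    fp <- flat(params)
    opt <- list(m = lapply(fp, function(h) lapply(h, function(x) x * 0)),
                v = lapply(fp, function(h) lapply(h, function(x) x * 0)))

    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    curve <- numeric(0)
    pos_idx <- which(target > 0)
    neg_pool <- which(target == 0)
    # fixed evaluation entry set: all positives plus negatives drawn once,
    # so early stopping tracks a stable objective
    eval_w <- NULL
    if (!full_mode) {
      eval_w <- matrix(0, n, n)
      eval_w[pos_idx] <- 1
      eval_w[neg_pool[sample.int(length(neg_pool),
                                 min(length(pos_idx), length(neg_pool)))]] <- 1
    }

    for (epoch in seq_len(cfg$max_epochs)) {
      drop_masks <- NULL
      if (cfg$dropout > 0) {
        drop_masks <- list(
          l1 = matrix(rbinom(n * m_in, 1L, 1 - cfg$dropout), n) / (1 - cfg$dropout),
          l2 = matrix(rbinom(n * cfg$hidden_units, 1L, 1 - cfg$dropout), n) /
            (1 - cfg$dropout)
        )
      }
      fw <- gat_forward(features, params, mask, logS, cfg, drop_masks)
      E <- fw$E

      w <- NULL
      if (!full_mode) {
        w <- matrix(0, n, n)
        w[pos_idx] <- 1
        w[neg_pool[sample.int(length(neg_pool),
                              min(length(pos_idx), length(neg_pool)))]] <- 1
      }
      Z_dot <- tcrossprod(E)
      A_hat <- 1 / (1 + exp(-Z_dot))
      # gradient of BCE wrt logits is (A_hat - target) on scored entries
      Dm <- (A_hat - target)
      if (!is.null(w)) Dm <- Dm * w
      G_E <- (Dm + t(Dm)) %*% E

      # backward through layer 2
      bk2 <- head_backward(G_E, fw$top, fw$H2_in, params$layer2[[1]], mask,
                           cfg$leaky_slope)
      G_H1 <- bk2$H
      if (!is.null(drop_masks)) G_H1 <- G_H1 * drop_masks$l2
      grads <- list()
      for (k in seq_len(cfg$heads)) {
        cols <- ((k - 1) * f1 + 1):(k * f1)
        bk1 <- head_backward(G_H1[, cols, drop = FALSE], fw$heads[[k]],
                             fw$H1_in, params$layer1[[k]], mask,
                             cfg$leaky_slope)
        grads[[paste0("l1h", k)]] <- bk1[c("W", "a_src", "a_dst")]
      }
      grads[["l2"]] <- bk2[c("W", "a_src", "a_dst")]

      fp <- flat(params)
      upd <- adam_step(fp, grads, opt, cfg$learning_rate, cfg$weight_decay,
                       epoch)
      params <- unflat(upd$params, cfg$heads)
      opt <- upd$state

      # dropout-free loss drives early stopping and best-epoch selection
      fw_eval <- gat_forward(features, params, mask, logS, cfg, NULL)
      eval_loss <- tm_reconstruction_loss(
        target, tm_reconstruct_adjacency(fw_eval$E), weights = eval_w
      )
      if (!is.finite(eval_loss)) {
        abort(sprintf("non-finite training loss at epoch %d", epoch))
      }
      curve <- c(curve, eval_loss)
      if (eval_loss < best$loss) {
        best <- list(loss = eval_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }

    E_best <- gat_forward(features, best$params, mask, logS, cfg, NULL)$E
    rownames(E_best) <- graph$nodes
    structure(list(E = E_best, loss = best$loss, epochs_run = length(curve),
                   best_epoch = best$epoch, loss_curve = curve,
                   state = graph$state),
              class = "tm_embedding")
  })
}

#' @exportS3Method base::print
print.tm_embedding <- function(x, ...) {
  cat(sprintf(
    "<tm_embedding> state %d: %d genes x %d dims; loss %.4f after %d epoch(s)\n",
    x$state, nrow(x$E), ncol(x$E), x$loss, x$epochs_run
  ))
  invisible(x)
}
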