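make_toy_graph <- function(n = 8, seed = 3) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- tibble::tibble(source = nodes[c(1, 2, 3, 4)],
                          target = nodes[c(2, 3, 4, 5)])
  list(graph = tm_state_graph(nodes, edges),
       feats = matrix(rnorm(n * 5), n, 5),
       S = matrix(1 / n, n, n))
}

test_that("analytic GAT gradients match finite differences", {
  toy <- make_toy_graph()
  tmn <- asNamespace("transmarker")
  cfg <- tm_gat_config(hidden_units = 4, heads = 2, output_dim = 3,
                       dropout = 0, loss_mode = "full", seed = 5)
  A <- as.matrix(toy$graph$adjacency)
  As <- pmin(A + t(A), 1); diag(As) <- 1
  mask <- As > 0
  logS <- log(pmax(toy$S, 1e-300))
  withr::with_seed(5, {
    params <- list(layer1 = lapply(1:2, function(k) tmn$init_head(5, 2)),
                   layer2 = list(tmn$init_head(4, 3)))
  })
  loss_of <- function(p) {
    fw <- tmn$gat_forward(toy$feats, p, mask, logS, cfg, NULL)
    tm_reconstruction_loss(As, tm_reconstruct_adjacency(fw$E))
  }
  fw <- tmn$gat_forward(toy$feats, params, mask, logS, cfg, NULL)
  Ah <- 1 / (1 + exp(-tcrossprod(fw$E)))
  G_E <- ((Ah - As) + t(Ah - As)) %*% fw$E
  bk2 <- tmn$head_backward(G_E, fw$top, fw$H2_in, params$layer2[[1]], mask,
                           cfg$leaky_slope)
  G_H1 <- bk2$H
  bk1 <- tmn$head_backward(G_H1[, 1:2, drop = FALSE], fw$heads[[1]],
                           fw$H1_in, params$layer1[[1]], mask,
                           cfg$leaky_slope)
  eps <- 1e-6
  fd <- function(set_fun) {
    (loss_of(set_fun(+eps)) - loss_of(set_fun(-eps))) / (2 * eps)
  }
  # spot-check every parameter family
  for (idx in list(c(1, 1), c(3, 2))) {
    num <- fd(function(d) {
      p <- params; p$layer2[[1]]$W[idx[1], idx[2]] <-
        p$layer2[[1]]$W[idx[1], idx[2]] + d; p
    })
    expect_equal(bk2$W[idx[1], idx[2]], num, tolerance = 1e-5)
  }
  num <- fd(function(d) {
    p <- params; p$layer1[[1]]$W[2, 1] <- p$layer1[[1]]$W[2, 1] + d; p
  })
  expect_equal(bk1$W[2, 1], num, tolerance = 1e-5)
  num <- fd(function(d) {
    p <- params; p$layer1[[1]]$a_src[1] <- p$layer1[[1]]$a_src[1] + d; p
  })
  expect_equal(bk1$a_src[1], num, tolerance = 1e-5)
  num <- fd(function(d) {
    p <- params; p$layer2[[1]]$a_dst[2] <- p$layer2[[1]]$a_dst[2] + d; p
  })
  expect_equal(bk2$a_dst[2], num, tolerance = 1e-5)
})

test_that("adjacency reconstruction follows the logistic closed forms", {
  E <- rbind(rep(0, 4), c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  Ah <- tm_reconstruct_adjacency(E)
  expect_equal(Ah[1, 2], 0.5)            # zero vector -> sigma(0)
  expect_equal(Ah[2, 3], 1 / (1 + exp(-1))) # unit dot -> sigma(1) ~ 0.73106
  expect_equal(Ah[2, 4], 0.5)            # orthogonal -> sigma(0)
  expect_equal(Ah, t(Ah))                # symmetric by construction
})

test_that("reconstruction loss matches closed forms and a loop oracle", {
  A <- matrix(c(1, 0, 0, 1), 2, 2)
  flat <- matrix(0.5, 2, 2)
  expect_equal(tm_reconstruction_loss(A, flat), 4 * log(2))

  # near-perfect reconstruction gives a near-zero loss
  perfect <- ifelse(A == 1, 1 - 1e-7, 1e-7)
  expect_lt(tm_reconstruction_loss(A, perfect), 1e-5)

  set.seed(6)
  A <- matrix(rbinom(25, 1, 0.3), 5, 5)
  Ah <- matrix(runif(25, 0.05, 0.95), 5, 5)
  oracle <- 0
  for (i in 1:5) for (j in 1:5) {
    oracle <- oracle - (A[i, j] * log(Ah[i, j]) +
                        (1 - A[i, j]) * log(1 - Ah[i, j]))
  }
  expect_equal(tm_reconstruction_loss(A, Ah), oracle, tolerance = 1e-10)
  expect_error(tm_reconstruction_loss(A, Ah[1:2, 1:2]), "shape")
})

test_that("training is seeded, improves the loss, and reconstructs structure", {
  # 30-node two-community graph
  set.seed(7)
  nodes <- sprintf("n%02d", 1:30)
  within <- function(block) {
    pairs <- t(combn(block, 2))
    keep <- runif(nrow(pairs)) < 0.4
    tibble::tibble(source = pairs[keep, 1], target = pairs[keep, 2])
  }
  edges <- dplyr::bind_rows(within(nodes[1:15]), within(nodes[16:30]),
                            tibble::tibble(source = "n01", target = "n16"))
  g <- tm_state_graph(nodes, edges)
  st <- tm_structural_similarity(g)
  feats <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(nodes, NULL))
  cfg <- tm_gat_config(hidden_units = 16, heads = 2, output_dim = 8,
                       max_epochs = 300, patience = 40, seed = 11)
  emb <- tm_train_embedding(feats, st, g, cfg)
  emb2 <- tm_train_embedding(feats, st, g, cfg)
  expect_identical(emb$E, emb2$E) # seeded determinism
  expect_true(all(is.finite(emb$E)))
  expect_lt(emb$loss, emb$loss_curve[1]) # beats the first epoch

  A <- as.matrix(g$adjacency); As <- pmin(A + t(A), 1); diag(As) <- 1
  Ah <- tm_reconstruct_adjacency(emb)
  off <- upper.tri(As)
  expect_gt(tm_auroc(As[off] == 1, Ah[off]), 0.8)

  empty <- tm_state_graph(nodes, edges[0, ])
  expect_error(tm_train_embedding(feats, st, empty, cfg), "no edges")
})

test_that("embeddings are permutation-equivariant", {
  toy <- make_toy_graph(n = 10, seed = 9)
  nodes <- toy$graph$nodes
  feats <- toy$feats
  rownames(feats) <- nodes
  st <- tm_structural_similarity(toy$graph)
  cfg <- tm_gat_config(hidden_units = 8, heads = 2, output_dim = 4,
                       dropout = 0, loss_mode = "full", max_epochs = 40,
                       patience = 40, seed = 13)
  emb <- tm_train_embedding(feats, st, toy$graph, cfg)

  perm <- sample(seq_along(nodes))
  g_perm <- tm_state_graph(nodes[perm], toy$graph$edges)
  st_perm <- tm_structural_similarity(g_perm)
  emb_perm <- tm_train_embedding(feats[nodes[perm], , drop = FALSE], st_perm,
                                 g_perm, cfg)
  expect_equal(emb_perm$E[nodes, ], emb$E[nodes, ], tolerance = 1e-8)
})
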