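random_space <- function(n, d = 3, seed = 1) {
  set.seed(seed)
  tm_embedding_dissimilarity(matrix(rnorm(n * d), n, d))
}

test_that("embedding dissimilarity is Euclidean and matches a loop oracle", {
  E <- rbind(c(0, 0), c(3, 4), c(0, 0))
  D <- tm_embedding_dissimilarity(E)
  expect_equal(D[1, 2], 5) # 3-4-5 triangle
  expect_equal(D[1, 3], 0) # identical rows
  expect_equal(diag(D), rep(0, 3))

  set.seed(2)
  E <- matrix(rnorm(24), 6, 4)
  D <- tm_embedding_dissimilarity(E)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    oracle[i, j] <- sqrt(sum((E[i, ] - E[j, ])^2))
  }
  expect_equal(unname(D), oracle, tolerance = 1e-10)

  Ds <- tm_embedding_dissimilarity(E, scale_median = TRUE)
  expect_equal(stats::median(Ds[Ds > 0]), 1)
})

test_that("transport plans satisfy marginal and mass invariants", {
  for (seed in 1:3) {
    D <- random_space(8, seed = seed)
    Dp <- random_space(8, seed = seed + 100)
    plan <- tm_entropic_gw(D, Dp)
    expect_true(all(plan$gamma >= 0))
    expect_equal(rowSums(plan$gamma), plan$p, tolerance = 1e-6)
    expect_equal(colSums(plan$gamma), plan$q, tolerance = 1e-6)
    expect_equal(sum(plan$gamma), 1, tolerance = 1e-8)
  }
  expect_error(tm_entropic_gw(random_space(4), random_space(4),
                              p = c(1, 1, 1, 1), q = rep(0.25, 4)),
               "probability")
})

test_that("the entropy-dominated limit returns the independent coupling", {
  D <- random_space(6, seed = 4)
  Dp <- random_space(6, seed = 5)
  eps_big <- 1e3 * mean(D^2)
  plan <- tm_entropic_gw(D, Dp, epsilon = eps_big)
  expect_equal(unname(plan$gamma), outer(plan$p, plan$q), tolerance = 1e-3)
})

test_that("self-alignment costs no more than the independent coupling", {
  for (seed in 1:10) {
    D <- random_space(10, seed = seed)
    plan <- tm_entropic_gw(D, D, epsilon = 1e-2)
    constC <- transmarker:::gw_const(D, D, plan$p, plan$q)
    ind_cost <- transmarker:::gw_cost(D, D, outer(plan$p, plan$q), constC)
    expect_lte(plan$cost, ind_cost + 1e-8)
  }
})

test_that("3-point spaces respect the exhaustive permutation bound", {
  set.seed(6)
  for (rep in 1:3) {
    D <- random_space(3, seed = rep * 7)
    Dp <- random_space(3, seed = rep * 7 + 50)
    eps <- 1e-3
    plan <- tm_entropic_gw(D, Dp, epsilon = eps)
    p <- rep(1 / 3, 3)
    constC <- transmarker:::gw_const(D, Dp, p, p)
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                  c(3, 2, 1))
    perm_costs <- vapply(perms, function(pi) {
      G <- matrix(0, 3, 3)
      G[cbind(1:3, pi)] <- 1 / 3
      transmarker:::gw_cost(D, Dp, G, constC)
    }, numeric(1))
    # entropic slack: eps times the maximal entropy gap log(n^2)
    expect_lte(plan$cost, min(perm_costs) + eps * log(9) + 1e-6)
  }
})

test_that("transition scores are population row standard deviations", {
  # uniform coupling: every row constant -> score 0
  g_unif <- structure(list(gamma = matrix(1 / 16, 4, 4), p = rep(0.25, 4),
                           q = rep(0.25, 4), epsilon = 1, cost = 0,
                           iterations = 1, converged = TRUE),
                      class = "tm_transport_plan")
  expect_equal(unname(tm_transition_score(g_unif)), rep(0, 4))

  # N = 2, row (0.5, 0): population std = 0.25
  g2 <- g_unif
  g2$gamma <- rbind(c(0.5, 0), c(0, 0.5))
  g2$p <- g2$q <- c(0.5, 0.5)
  expect_equal(unname(tm_transition_score(g2)), c(0.25, 0.25))

  # permutation-like rows maximize the row std at fixed marginals
  set.seed(8)
  n <- 5
  perm_plan <- g_unif
  perm_plan$gamma <- diag(1 / n, n)
  perm_plan$p <- perm_plan$q <- rep(1 / n, n)
  perm_score <- tm_transition_score(perm_plan)[1]
  for (i in 1:20) {
    w <- matrix(rexp(n * n), n, n)
    feasible <- perm_plan
    feasible$gamma <- w / sum(w)
    # rescale rows to the same marginals
    feasible$gamma <- feasible$gamma / rowSums(feasible$gamma) / n
    expect_lte(max(tm_transition_score(feasible)), perm_score + 1e-12)
  }
})

test_that("cumulative scores add per-transition scores exactly", {
  plans <- lapply(1:3, function(s) {
    D <- random_space(6, seed = s)
    Dp <- random_space(6, seed = s + 10)
    tm_entropic_gw(D, Dp)
  })
  sc <- tm_alignment_scores(plans)
  per <- vapply(plans, tm_transition_score, numeric(6))
  expect_equal(sc$R, unname(rowSums(per)))
  expect_equal(sc$R_t2, unname(per[, 2]))

  one <- tm_alignment_scores(plans[1])
  expect_equal(one$R, unname(per[, 1])) # single transition

  triple <- tm_alignment_scores(list(plans[[1]], plans[[1]], plans[[1]]))
  expect_equal(triple$R, 3 * unname(per[, 1])) # additivity
})

test_that("self-cost does not exceed the cost against perturbed geometry", {
  set.seed(9)
  D <- random_space(8, seed = 30)
  self_cost <- tm_entropic_gw(D, D)$cost
  worse <- 0
  for (i in 1:20) {
    noise <- matrix(rnorm(64, sd = 0.3), 8, 8)
    noise <- abs(noise + t(noise)) / 2
    diag(noise) <- 0
    pert <- tm_entropic_gw(D, D + noise)$cost
    worse <- worse + (pert >= self_cost)
  }
  expect_gt(worse / 20, 0.5) # perturbation raises the cost on average
})
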