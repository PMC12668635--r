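test_that("DEG screening applies exclusion and strict thresholds", {
  set.seed(1)
  n <- 40
  state <- rbind(
    const = rep(5L, n),
    up9 = rpois(n, 90),
    boundary = rep(NA_integer_, n), # filled below
    null = rpois(n, 20)
  )
  normal <- rbind(
    const = rep(5L, n),
    up9 = rpois(n, 10),
    boundary = rep(NA_integer_, n),
    null = rpois(n, 20)
  )
  # boundary gene engineered to a fold change of exactly 2 after pseudocount
  # (non-constant so it passes the exclusion filter)
  state["boundary", ] <- rep(c(6L, 8L), n / 2)   # mean 7, (7+1)/(3+1) = 2
  normal["boundary", ] <- rep(c(2L, 4L), n / 2)  # -> log2FC = 1 exactly
  res <- tm_identify_degs(state, normal)

  expect_false("const" %in% res$gene) # constant in both conditions
  up9 <- res[res$gene == "up9", ]
  expect_gt(abs(up9$log2fc), 1) # ~log2(91/11) = 3.05
  # rank-sum oracle on the same normalized values
  p_oracle <- wilcox.test(tm_normalize_counts(state)["up9", ],
                          tm_normalize_counts(normal)["up9", ],
                          exact = FALSE)$p.value
  expect_equal(up9$p, p_oracle)
  expect_true(up9$selected)
  expect_false(res$selected[res$gene == "boundary"]) # strict > 1.0
  expect_false(res$selected[res$gene == "null"])

  expect_error(tm_identify_degs(state[1:2, ], normal), "gene index")
  expect_error(tm_identify_degs(state[, 1, drop = FALSE], normal), "2 cells")
})

test_that("background assembly induces the prior subgraph and keeps isolates", {
  prior <- tibble::tibble(source = c("A", "B", "C"), target = c("B", "C", "D"))
  bg <- tm_assemble_background(c("A", "B", "C"), prior)
  expect_setequal(paste(bg$edges$source, bg$edges$target), c("A B", "B C"))
  expect_setequal(bg$nodes, c("A", "B", "C"))

  expect_warning(empty <- tm_assemble_background(c("X", "Y"), prior),
                 "no overlap")
  expect_equal(nrow(empty$edges), 0L)
  expect_error(tm_assemble_background("A", prior[0, ]), "empty")
})

test_that("order-0 pruning removes independent pairs and keeps dependent ones", {
  set.seed(2)
  n <- 500
  x <- rnorm(n)
  counts <- rbind(
    X = as.integer(round(50 * exp(0.3 * x))),
    Yind = as.integer(rpois(n, 40)),
    Ydep = as.integer(round(50 * exp(0.3 * x + rnorm(n, sd = 0.05)))),
    ballast = rep(5000L, n) # stabilizes library sizes
  )
  colnames(counts) <- sprintf("c%d", 1:n)
  bg <- tm_assemble_background(
    rownames(counts),
    tibble::tibble(source = c("X", "X"), target = c("Yind", "Ydep"))
  )
  g <- tm_pc_cmi_prune(bg, counts, max_order = 0)
  expect_false(any(g$edges$target == "Yind")) # MI ~ 0 for independent pair
  expect_true(any(g$edges$target == "Ydep"))  # near-copy retained

  # MI closed form: -0.5 log(1 - r^2) on the normalized data
  dat <- t(tm_normalize_counts(counts))
  r <- cor(dat[, "X"], dat[, "Ydep"])
  expect_gt(-0.5 * log(1 - r^2), 0.03)
})

test_that("order-1 pruning removes the indirect edge of a chain", {
  set.seed(3)
  n <- 600
  a <- rnorm(n)
  b <- 0.9 * a + rnorm(n, sd = 0.2)
  c_ <- 0.9 * b + rnorm(n, sd = 0.2)
  counts <- rbind(A = as.integer(round(60 * exp(0.2 * a))),
                  B = as.integer(round(60 * exp(0.2 * b))),
                  C = as.integer(round(60 * exp(0.2 * c_))),
                  ballast = rep(5000L, n))
  colnames(counts) <- sprintf("c%d", 1:n)
  bg <- tm_assemble_background(
    rownames(counts),
    tibble::tibble(source = c("A", "B", "A"), target = c("B", "C", "C"))
  )
  g <- tm_pc_cmi_prune(bg, counts, max_order = 1)
  keys <- paste(g$edges$source, g$edges$target)
  expect_true(all(c("A B", "B C") %in% keys))
  expect_false("A C" %in% keys) # conditionally independent given B
})

test_that("pruning is a monotone subset operation", {
  ds <- small_dataset()
  bg <- tm_assemble_background(rownames(ds$counts[[1]]),
                               tm_grn_union_edges(ds$grn))
  g_lo <- tm_pc_cmi_prune(bg, ds$counts[[1]], cmi_threshold = 0.03)
  g_hi <- tm_pc_cmi_prune(bg, ds$counts[[1]], cmi_threshold = 0.3)
  key <- function(g) paste(g$edges$source, g$edges$target)
  expect_true(all(key(g_lo) %in% paste(bg$edges$source, bg$edges$target)))
  expect_true(all(key(g_hi) %in% key(g_lo))) # raising threshold never adds
})

test_that("pruning beats the unpruned background on linear-Gaussian data", {
  # 30-gene ground truth; expression linear in the regulators plus noise
  set.seed(4)
  grn <- tm_generate_grn(30, 8, 0.25, seed = 9)
  n <- 300
  expr <- matrix(0, 30, n, dimnames = list(grn$genes, sprintf("c%d", 1:n)))
  for (g in grn$genes) {
    parents <- grn$edges[grn$edges$target == g, ]
    base <- rnorm(n)
    if (nrow(parents) > 0) {
      for (i in seq_len(nrow(parents))) {
        base <- base + 0.8 * sign(parents$strength[i]) * expr[parents$source[i], ]
      }
    }
    expr[g, ] <- base
  }
  counts <- matrix(as.integer(round(30 * exp(0.2 * scale(t(expr))))), n, 30,
                   dimnames = list(colnames(expr), rownames(expr)))
  counts <- t(counts)
  # background = truth plus an equal number of decoy edges
  truth <- paste(grn$edges$source, grn$edges$target)
  all_pairs <- expand.grid(s = grn$regulators, t = grn$genes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$s != all_pairs$t, ]
  decoy_pool <- all_pairs[!paste(all_pairs$s, all_pairs$t) %in% truth, ]
  decoys <- decoy_pool[sample.int(nrow(decoy_pool), nrow(grn$edges)), ]
  bg <- tm_assemble_background(
    grn$genes,
    tibble::tibble(source = c(grn$edges$source, decoys$s),
                   target = c(grn$edges$target, decoys$t))
  )
  g <- tm_pc_cmi_prune(bg, counts)
  prec_bg <- mean(paste(bg$edges$source, bg$edges$target) %in% truth)
  prec_pruned <- mean(paste(g$edges$source, g$edges$target) %in% truth)
  expect_gt(prec_pruned, prec_bg)
})
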