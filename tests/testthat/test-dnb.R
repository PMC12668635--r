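scores_tbl <- function(genes, R) tibble::tibble(gene = genes, R = R)

test_that("knee detection finds a sharp elbow and falls back gracefully", {
  sc <- scores_tbl(sprintf("g%d", 1:6), c(10, 9.5, 9, 1, 0.9, 0.8))
  expect_identical(tm_elbow_select(sc), c("g1", "g2", "g3")) # knee at rank 4

  # all-equal scores: fallback keeps the top 15% by the gene-name tie-break
  sc_eq <- scores_tbl(sprintf("g%03d", 1:100), rep(1, 100))
  sel <- tm_elbow_select(sc_eq, fallback_fraction = 0.15)
  expect_length(sel, 15)
  expect_identical(sel, sprintf("g%03d", 1:15))

  # single gene: fallback returns it
  expect_identical(tm_elbow_select(scores_tbl("only", 3)), "only")
})

test_that("union components follow union semantics and a union-find oracle", {
  g1 <- tm_state_graph(c("A", "B", "C"),
                       tibble::tibble(source = "A", target = "B"), 1)
  g2 <- tm_state_graph(c("A", "B", "C"),
                       tibble::tibble(source = "B", target = "C"), 2)
  comp <- tm_union_components(c("A", "B", "C"), list(g1, g2))
  expect_equal(length(unique(comp$component)), 1L) # one merged component

  # no induced edges -> all singletons, flagged
  comp0 <- tm_union_components(c("A", "C"), list(g1, g2))
  expect_true(all(comp0$singleton))

  # random graphs vs an independent union-find implementation
  set.seed(10)
  nodes <- sprintf("n%02d", 1:15)
  graphs <- lapply(1:3, function(t) {
    e <- tibble::tibble(source = sample(nodes, 8, replace = TRUE),
                        target = sample(nodes, 8, replace = TRUE))
    e <- e[e$source != e$target, ]
    tm_state_graph(nodes, e, t)
  })
  selected <- sample(nodes, 10)
  comp <- tm_union_components(selected, graphs)

  parent <- stats::setNames(selected, selected)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (g in graphs) {
    e <- g$edges[g$edges$source %in% selected & g$edges$target %in% selected, ]
    for (i in seq_len(nrow(e))) {
      parent[[find(e$source[i])]] <- find(e$target[i])
    }
  }
  roots <- vapply(selected, find, character(1))
  oracle_sizes <- sort(as.integer(table(roots)))
  got_sizes <- sort(as.integer(table(comp$component)))
  expect_equal(got_sizes, oracle_sizes)
})

test_that("component scoring reproduces the hand-worked DNI arithmetic", {
  tri_edges <- tibble::tibble(source = c("a", "b", "c"),
                              target = c("b", "c", "a"))
  graphs <- lapply(1:4, function(t) tm_state_graph(c("a", "b", "c"),
                                                   tri_edges, t))
  sc <- tibble::tibble(gene = c("a", "b", "c"),
                       R_t1 = c(0.1, 0.2, 0.3), R_t2 = c(0.3, 0.2, 0.1),
                       R_t3 = c(0.2, 0.2, 0.2),
                       R = c(0.6, 0.6, 0.6))
  # fully cohesive triangle in every state: rho = 1, GCS = 0, D = 1, DNI = 0
  rep_tri <- tm_score_component(c("a", "b", "c"), graphs, sc)
  expect_equal(rep_tri$per_state[[1]]$rho, rep(1, 4))
  expect_equal(rep_tri$per_state[[1]]$d[1], 1)
  expect_equal(rep_tri$dni, 0)

  # n = 3, m = 2, psi = 0.6: rho = 2/3, GCS = -0.2, D = exp(0.2)
  two_edges <- tibble::tibble(source = c("a", "b"), target = c("b", "c"))
  graphs2 <- lapply(1:2, function(t) tm_state_graph(c("a", "b", "c"),
                                                    two_edges, t))
  sc2 <- tibble::tibble(gene = c("a", "b", "c"), R_t1 = c(0.1, 0.2, 0.3),
                        R = c(0.1, 0.2, 0.3))
  rep2 <- tm_score_component(c("a", "b", "c"), graphs2, sc2)
  ps <- rep2$per_state[[1]]
  expect_equal(ps$rho[1], 2 / 3)
  expect_equal(ps$gcs[1], (1 / 3) * (-0.6))
  expect_equal(ps$d[1], exp(0.2), tolerance = 1e-6)

  # population std of the series (1, 1, 1.2214, 1)
  d_series <- c(1, 1, exp(0.2), 1)
  expect_equal(transmarker:::pop_sd(d_series), 0.09587, tolerance = 1e-4)

  # reciprocal directed edges count once in the undirected density
  recip <- tm_state_graph(c("a", "b"),
                          tibble::tibble(source = c("a", "b"),
                                         target = c("b", "a")))
  sc_r <- tibble::tibble(gene = c("a", "b"), R_t1 = c(0, 0), R = c(0, 0))
  rep_r <- tm_score_component(c("a", "b"), list(recip, recip), sc_r)
  expect_equal(rep_r$per_state[[1]]$m_t[1], 1L, ignore_attr = TRUE)
})

test_that("DNB selection takes the argmax with documented tie-breaks", {
  nodes <- c("a", "b", "c", "d", "e", "f")
  e1 <- tibble::tibble(source = c("a", "d"), target = c("b", "e"))
  e2 <- tibble::tibble(source = c("a", "d", "e"), target = c("b", "e", "f"))
  graphs <- list(tm_state_graph(nodes, e1, 1), tm_state_graph(nodes, e2, 2))
  sc <- tibble::tibble(gene = nodes, R_t1 = c(1, 2, 0, 3, 1, 2),
                       R = c(1, 2, 0, 3, 1, 2))
  comp <- tm_union_components(nodes, graphs)
  reports <- tm_select_dnb(comp, graphs, sc)
  expect_equal(reports$rank, seq_len(nrow(reports)))
  expect_true(reports$is_dnb[1])
  # the {d,e,f} component changes density across states -> positive DNI
  expect_setequal(reports$genes[[1]], c("d", "e", "f"))
  expect_gt(reports$dni[1], 0)
  expect_error(tm_select_dnb(comp[0, ], graphs, sc))
})

test_that("DNI is invariant to gene relabeling", {
  nodes <- c("a", "b", "c")
  e1 <- tibble::tibble(source = "a", target = "b")
  e2 <- tibble::tibble(source = c("a", "b"), target = c("b", "c"))
  graphs <- list(tm_state_graph(nodes, e1, 1), tm_state_graph(nodes, e2, 2))
  sc <- tibble::tibble(gene = nodes, R_t1 = c(0.3, 0.1, 0.2),
                       R = c(0.3, 0.1, 0.2))
  dni <- tm_score_component(nodes, graphs, sc)$dni

  relabel <- c(a = "x", b = "y", c = "z")
  graphs_r <- lapply(graphs, function(g) {
    tm_state_graph(unname(relabel[g$nodes]),
                   tibble::tibble(source = unname(relabel[g$edges$source]),
                                  target = unname(relabel[g$edges$target])),
                   g$state)
  })
  sc_r <- sc; sc_r$gene <- unname(relabel[sc$gene])
  expect_equal(tm_score_component(unname(relabel[nodes]), graphs_r, sc_r)$dni,
               dni)
})
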