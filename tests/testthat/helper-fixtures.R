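# Shared fixtures, built once per test run.

# tiny deterministic state graph: path a - b - c plus isolated d
tiny_path_graph <- function() {
  tm_state_graph(c("a", "b", "c", "d"),
                 tibble::tibble(source = c("a", "b"), target = c("b", "c")))
}

# a small rewired simulated dataset shared across tests
fixture_env <- new.env()
small_dataset <- function() {
  if (is.null(fixture_env$ds)) {
    fixture_env$ds <- tm_simulate_benchmark(20, n_cells_per_state = 60,
                                            seed = 42)
  }
  fixture_env$ds
}

# noise-free configuration: deterministic kinetics, fixed library size
noiseless <- function(lib_scale = 10) {
  tm_noise_config(cell_sd = 0, technical_sd = 0, dropout_max = 0,
                  lib_scale = lib_scale, lib_sd = 0)
}

# a hand-built GRN with a chosen edge table (bypasses the random generators)
manual_grn <- function(genes, regulators, edges, basal) {
  structure(list(genes = genes, regulators = regulators, edges = edges,
                 basal = basal, states = list(edges),
                 switchers = character(0)),
            class = "tm_grn")
}
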