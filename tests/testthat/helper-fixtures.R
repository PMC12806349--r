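## Shared fixtures, computed once per test run and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

## small Poisson chromosome for cheap end-to-end checks
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_chromosome(n_bins = 120, n_segments = 4, min_len = 8,
                        max_len = 15, seed = 3, noise_model = "poisson")
  })
}

## noise-free medium chromosome for the linear-model properties
clean_sim_500 <- function() {
  fixture("clean_sim_500", function() {
    simulate_chromosome(n_bins = 500, seed = 1, noise_model = "none")
  })
}

## the standard 1,000-bin Poisson fixture
poisson_sim_1000 <- function(seed = 1) {
  fixture(paste0("poisson_sim_1000_", seed), function() {
    simulate_chromosome(n_bins = 1000, seed = seed, noise_model = "poisson")
  })
}

## small deterministic weighted graph: a 5-node path plus one chord
toy_graph <- function() {
  fixture("toy_graph", function() {
    m <- matrix(0, 5, 5)
    m[1, 2] <- 2; m[2, 3] <- 1; m[3, 4] <- 3; m[4, 5] <- 1; m[2, 4] <- 0.5
    build_graph(m + t(m))
  })
}
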