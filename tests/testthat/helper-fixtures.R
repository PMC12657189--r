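# Shared fixtures, built in code.

# deterministic 8x8 test image with non-trivial structure
fixture_image <- function(seed = 42, n = 8) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# the worked 2x2 pattern tiled to a legal 8x8 image (mean 100)
fixture_tiled <- function() {
  matrix(rep(c(0, 100, 100, 200), 16), 8, 8)
}

# small in-memory dataset for training smoke tests
fixture_dataset <- function(n_total = 60, size = 32, seed = 99, ...) {
  generate_dataset(phantom_spec(n_total = n_total, size = size,
                                seed = seed, ...))
}
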