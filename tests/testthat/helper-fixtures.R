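# Shared small fixtures, all built in code.

# 8x8 deterministic grid on [0, 1] with mixed values
toy_grid <- function() {
  set.seed(11)
  matrix(round(runif(64), 3), 8, 8)
}

# 64x64 disc fixture: zeros except a filled disc of the given value
disc_image <- function(n = 64, value = 0.8, radius = 20) {
  cy <- (n + 1) / 2
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cy)^2, "+")
  img <- matrix(0, n, n)
  img[d2 <= radius^2] <- value
  img
}

small_phantom <- function(seed = 1, n = 64) {
  phantom_generate(phantom_spec(height = n, width = n, seed = seed))
}
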