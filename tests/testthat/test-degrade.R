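test_that("blur kernels are normalized and shaped as specified", {
  for (r in c(1, 3, 5, 15)) {
    k <- pillbox_kernel(r)
    expect_equal(sum(k), 1)
    expect_equal(dim(k), c(2 * r + 1, 2 * r + 1))
    # constant inside the disc, zero outside
    expect_equal(length(unique(k[k > 0])), 1L)
    idx <- -r:r
    inside <- outer(idx^2, idx^2, "+") <= r^2
    expect_identical(unname(k > 0), inside)
  }
  for (L in 2:15) {
    k <- motion_kernel(L, angle = 37)
    expect_equal(sum(k), 1)
    expect_true(nrow(k) %% 2 == 1 && ncol(k) %% 2 == 1)
  }
  expect_identical(motion_kernel(1), matrix(1, 1, 1))
  # angle-0 kernel is a 1-row anti-aliased box: equal interior weights,
  # half-weight endpoints, symmetric
  k0 <- motion_kernel(9, 0)
  expect_equal(nrow(k0), 1)
  expect_equal(ncol(k0), 9)
  expect_equal(as.vector(k0), rev(as.vector(k0)))
  expect_equal(length(unique(round(k0[2:8], 12))), 1L)
  expect_lt(k0[1, 1], k0[1, 2])  # tapered endpoints
})

test_that("blurring preserves constants and reproduces the impulse response", {
  const <- matrix(0.7, 32, 32)
  expect_equal(degrade_circular_blur(const, 4), const, tolerance = 1e-10)
  expect_equal(degrade_motion_blur(const, 7), const, tolerance = 1e-10)

  delta <- matrix(0, 33, 33); delta[17, 17] <- 1
  out <- degrade_circular_blur(delta, 3)
  k <- pillbox_kernel(3)
  expect_equal(out[14:20, 14:20], unname(k), tolerance = 1e-10)
  expect_lt(max(abs(out[1:10, ])), 1e-10)

  expect_error(degrade_circular_blur(matrix(1:256 / 256, 16, 16), 8),
               "half the image")
  expect_error(degrade_circular_blur(const, 0), "level")
  expect_error(degrade_circular_blur(const, 16), "level")
})

test_that("FFT convolution agrees with direct summation on small cases", {
  set.seed(41)
  x <- matrix(runif(23 * 19), 23, 19)
  for (k in list(pillbox_kernel(2), motion_kernel(5, 30),
                 matrix(runif(9), 3, 3))) {
    expect_equal(briq:::conv2_same_symmetric(x, k / sum(k)),
                 oracle_conv2(x, k / sum(k)), tolerance = 1e-10)
  }
})

test_that("Rician noise has the documented magnitude construction", {
  x <- matrix(5, 64, 64)
  expect_identical(degrade_rician(x, 0), x)                 # sigma = 0
  y1 <- degrade_rician(x, 10, seed = 7)
  y2 <- degrade_rician(x, 10, seed = 7)
  expect_identical(y1, y2)                                  # seeded determinism
  expect_true(all(y1 >= 0))
  expect_warning(degrade_rician(x, 5), "seed")

  # zero signal: Rayleigh with mean sigma*sqrt(pi/2), checked at 1e5 pixels
  z <- matrix(0, 317, 317)
  sigma <- 0.10
  out <- degrade_rician(z, 10, seed = 123, ref_max = 1)
  n <- length(out)
  mean_expected <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt((2 - pi / 2) / n)
  expect_lt(abs(mean(out) - mean_expected), 3 * se)

  # channel variance matches sigma^2 within 5% at 1e5 samples
  g <- withr::with_seed(99, rnorm(1e5, 0, sigma))
  expect_lt(abs(var(g) - sigma^2) / sigma^2, 0.05)
})

test_that("bias fields are smooth, strictly positive and scale with level", {
  x <- phantom_generate(phantom_spec(height = 64, width = 64, seed = 2))$slice
  expect_equal(degrade_bias_field(x, 0), x, ignore_attr = TRUE)

  for (prof in c("gaussian", "ramp")) {
    y <- degrade_bias_field(x, 15, profile = prof)
    f <- attr(y, "field")
    expect_true(all(f > 0))
    expect_equal(unname(y[, ]), unname(x * f))
    expect_lt(max(abs(f - 1)), 0.46)
  }
  # ramp field is the element-wise product with a linear ramp
  y <- degrade_bias_field(x, 10, profile = "ramp")
  f <- attr(y, "field")
  expect_equal(f[1, ], f[64, ])                  # constant down columns
  expect_true(all(diff(f[1, ]) > 0))             # increasing across rows
})

test_that("a strong bias field shifts the moment balance of the phantom", {
  ph <- phantom_generate(phantom_spec(seed = 17))
  clean <- score_slice(ph$slice, fg = ph$mask)
  biased <- score_slice(degrade_bias_field(ph$slice, 15), fg = ph$mask)
  # the multiplicative field spreads the grayscale histogram: the grayscale
  # moment moves and the attribute scores respond, while all stay in [0, 1]
  expect_false(isTRUE(all.equal(biased$mu_d, clean$mu_d, tolerance = 1e-3)))
  expect_false(isTRUE(all.equal(biased$Q, clean$Q, tolerance = 1e-3)))
  q <- unlist(biased[c("q1", "q2", "q3", "q4", "Q")])
  expect_true(all(q >= 0 & q <= 1))
})
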