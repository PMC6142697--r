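# helper: build the four binary images for a slice
feature_set <- function(x, fg, window = 3) {
  gray <- rescale_intensity(x)
  con <- local_contrast(gray, window)
  binary_features(gray, con, fg)
}

test_that("edge-matching scores agree with the exhaustive counting oracle", {
  for (sd in c(1, 2, 3)) {
    ph <- small_phantom(seed = sd)
    bf <- feature_set(ph$slice, ph$mask)
    expect_equal(luminance_contrast(bf$FGMG, bf$FCMG),
                 oracle_edge_score(unclass(bf$FGMG), unclass(bf$FCMG)))
    expect_equal(texture(bf$FGMC, bf$FCMC),
                 oracle_edge_score(unclass(bf$FGMC), unclass(bf$FCMC)))
  }
})

test_that("edge-matching handles empty and mismatched inputs", {
  g <- toy_grid(); fg <- matrix(TRUE, 8, 8)
  a <- threshold_feature(g, fg, 0.5, "FGMG")
  empty <- threshold_feature(g, fg, 1, "FCMG")
  expect_warning(q <- luminance_contrast(empty, empty), "empty")
  expect_equal(q, 0)
  # one empty set: intersection empty, denominator positive
  expect_equal(suppressWarnings(luminance_contrast(a, empty)), 0)
  # source-kind mismatch
  c1 <- threshold_feature(g, fg, 0.5, "FCMC")
  expect_error(luminance_contrast(a, c1), "grayscale")
  expect_error(texture(a, c1), "contrast")
})

test_that("agreement scores are 1 for identical pairs and 0 for complements", {
  ph <- small_phantom(seed = 8)
  bf <- feature_set(ph$slice, ph$mask)
  n_t <- sum(ph$mask)
  expect_equal(texture_contrast(bf$FCMC, bf$FCMC, ph$mask, n_t), 1)
  expect_equal(lightness(bf$FGMG, bf$FGMG, ph$mask, n_t), 1)

  # complementary bright sets on the foreground disagree everywhere
  g <- toy_grid(); fg <- matrix(TRUE, 8, 8)
  a <- threshold_feature(g, fg, 0.5, "FCMC")
  b <- threshold_feature(1 - g, fg, 1 - 0.5 - 1e-9, "FGMC")
  expect_equal(texture_contrast(b, a, fg, 64), 0)

  # and against the oracle on phantoms
  expect_equal(texture_contrast(bf$FGMC, bf$FCMC, ph$mask, n_t),
               oracle_agreement_score(unclass(bf$FGMC), unclass(bf$FCMC), ph$mask))
  expect_equal(lightness(bf$FGMG, bf$FCMG, ph$mask, n_t),
               oracle_agreement_score(unclass(bf$FGMG), unclass(bf$FCMG), ph$mask))
})

test_that("the total score is the enforced-convex weighted sum", {
  expect_equal(total_score(1, 1, 1, 1), 1)
  expect_equal(total_score(0, 0, 0, 0), 0)
  expect_equal(total_score(0.5, 0.5, 0.5, 0.5), 0.5)
  expect_equal(total_score(1, 0, 0, 0), 0.1)
  expect_equal(total_score(0, 0, 1, 0), 0.7)
  w <- quality_weights(0.25, 0.25, 0.25, 0.25)
  expect_equal(total_score(0.2, 0.4, 0.6, 0.8, w), 0.5)
  expect_error(quality_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(quality_weights(-0.1, 0.4, 0.4, 0.3), "non-negative")
})

test_that("score_slice reproduces the step-by-step oracle path end to end", {
  ph <- small_phantom(seed = 9)
  fg <- extract_foreground(ph$slice)
  got <- score_slice(ph$slice)
  want <- oracle_score_slice(ph$slice, fg, window = 3)
  for (f in c("mu_d", "mu_c", "q1", "q2", "q3", "q4", "Q")) {
    expect_equal(got[[f]], want[[f]], tolerance = 1e-12, info = f)
  }
  # deterministic: identical rerun
  expect_identical(score_slice(ph$slice), got)
})

test_that("ideal two-valued phantoms give perfect agreement scores", {
  spec <- phantom_spec(rim_intensity = 1, interior_intensity = 0,
                       n_interior_blobs = 0, psf_sigma = 0, seed = 12)
  ph <- phantom_generate(spec)
  expect_setequal(unique(as.vector(ph$slice)), c(0, 1))
  s <- score_slice(ph$slice)
  expect_equal(s$q3, 1)
  expect_equal(s$q4, 1)
})

test_that("a heavily degraded phantom scores strictly below the clean slice", {
  ph <- phantom_generate(phantom_spec(seed = 10))
  clean <- score_slice(ph$slice, fg = ph$mask)$Q
  noisy <- score_slice(degrade_rician(ph$slice, 15, seed = 99), fg = ph$mask)$Q
  expect_lt(noisy, clean)
})

test_that("volume aggregation averages slices and applies sequence cut-offs", {
  ph <- small_phantom(seed = 13)
  slices <- list(ph$slice, ph$slice, ph$slice)
  rep3 <- score_volume(slices, sequence_tag = "T2")
  one <- score_slice(ph$slice)
  expect_equal(unname(rep3$means["Q"]), one$Q)
  expect_equal(rep3$cutoff, 0.45)
  expect_equal(nrow(tidy(rep3)), 3)

  repT1 <- score_volume(slices, sequence_tag = "T1")
  expect_equal(repT1$cutoff, 0.40)

  vol <- phantom_volume(phantom_spec(height = 64, width = 64, seed = 14), 5)
  vr <- score_volume(vol)
  expect_equal(unname(vr$means["Q"]), mean(vr$per_slice$Q))
  expect_equal(unname(vr$means["q2"]), mean(vr$per_slice$q2))
  expect_error(score_volume(list()), "non-empty")
})
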