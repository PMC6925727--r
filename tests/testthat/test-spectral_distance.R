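# spectral_distance: Euclidean distance, curvature histograms, weights, SSD

test_that("euclidean spectral distance excludes the zero mode", {
  expect_equal(euclidean_spectral_distance(c(0, 1, 2, 3), c(0, 1, 2, 3), 3), 0)
  expect_equal(euclidean_spectral_distance(c(0, 1, 2, 3), c(0, 1, 2, 4), 3), 1)
  set.seed(21)
  for (k in 1:5) {
    a <- c(0, sort(stats::runif(12, 0, 5)))
    b <- c(0, sort(stats::runif(12, 0, 5)))
    oracle <- 0
    for (i in 2:11) oracle <- oracle + (a[i] - b[i])^2  # direct summation
    expect_equal(euclidean_spectral_distance(a, b, 10), sqrt(oracle),
                 tolerance = 1e-14)
  }
  expect_error(euclidean_spectral_distance(c(0, 1), c(0, 1), 5), "l \\+ 1")
})

test_that("curvature histogram is a unit-mass area histogram sensitive to detail", {
  ico <- fx_ico(3)
  h <- curvature_histogram(gaussian_curvature(ico), l = 10)
  expect_equal(sum(h$fractions), 1, tolerance = 1e-12)
  expect_gte(max(h$fractions), 0.99)      # constant curvature: one bin

  smooth <- make_synthetic_canal(fx_canal_params(bump_amplitude = 0))
  bumpy <- make_synthetic_canal(fx_canal_params(bump_amplitude = 0.25))
  l <- 12
  hs <- curvature_histogram(gaussian_curvature(smooth), l = l)
  hb <- curvature_histogram(gaussian_curvature(bumpy), l = l)
  expect_equal(sum(hs$fractions), 1, tolerance = 1e-12)
  expect_gt(hb$k_max, hs$k_max)           # heavier curvature tail
  upper <- (l %/% 2 + 1):l
  expect_gt(sum(hb$fractions[upper]), sum(hs$fractions[upper]))
  expect_error(curvature_histogram(gaussian_curvature(ico), l = 1), ">= 2")
})

test_that("weight schemes: uniform, kac, curvature; normalization and floor", {
  wu <- eigenvalue_weights(l = 4, scheme = "uniform")
  expect_equal(wu$weights, rep(0.25, 4))

  wk <- eigenvalue_weights(l = 3, scheme = "kac")
  expect_equal(wk$weights, c(6, 3, 2) / 11)

  # identical flat histograms reduce to uniform
  flat <- rep(1 / 5, 5)
  wc <- eigenvalue_weights(flat, flat, l = 5)
  expect_equal(wc$weights, rep(0.2, 5))

  # zero bins get the floor, never zero weight
  h1 <- c(1, 0, 0, 0); h2 <- c(0, 0, 0, 1)
  wf <- eigenvalue_weights(h1, h2, l = 4)
  expect_true(all(wf$weights > 0))
  expect_equal(sum(wf$weights), 1, tolerance = 1e-12)
  expect_error(eigenvalue_weights(h1, h2, l = 3), "length")
})

test_that("ssd: identity, uniform-weight identity, symmetry, mode guard", {
  sp <- fx_spec_ico(2)
  wu <- eigenvalue_weights(l = 10, scheme = "uniform")
  expect_equal(ssd(sp, sp, wu)$value, 0)

  # against a perturbed copy: uniform SSD = euclidean / sqrt(l)
  sp2 <- sp
  set.seed(77)
  sp2$eigenvalues <- sp$eigenvalues + c(0, stats::runif(12, 0, 0.1))
  d_u <- ssd(sp, sp2, wu)$value
  d_e <- euclidean_spectral_distance(sp$eigenvalues, sp2$eigenvalues, 10)
  expect_equal(d_u, d_e / sqrt(10), tolerance = 1e-12)

  # symmetry with symmetric histogram-average weights
  h1 <- curvature_histogram(gaussian_curvature(fx_ico(2)), l = 10)
  h2 <- list(fractions = rev(h1$fractions))
  wc <- eigenvalue_weights(h1, h2, l = 10)
  expect_equal(ssd(sp, sp2, wc)$value, ssd(sp2, sp, wc)$value,
               tolerance = 1e-14)
  expect_gte(ssd(sp, sp2, wc)$value, 0)

  ar <- normalize_spectrum(sp, "area")
  expect_error(ssd(ar, sp2, wu), "normalization mode mismatch")
})
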