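# synth_shapes: fixture generators

test_that("icosphere combinatorics and exact radius", {
  ico0 <- make_icosphere(1, 0)
  expect_equal(dim(ico0$vertices), c(12L, 3L))
  expect_equal(nrow(ico0$faces), 20L)
  for (k in 0:3) {
    m <- if (k <= 2) make_icosphere(2, k) else fx_ico(3)
    expect_equal(nrow(m$faces), 20L * 4L^k)
    r <- sqrt(rowSums(m$vertices^2))
    expect_lt(max(abs(r - if (k <= 2) 2 else 1)), 1e-12)
    expect_equal(euler_characteristic(m), 2L)
  }
  expect_error(make_icosphere(1, 7), "0..6")
  expect_error(make_icosphere(-1, 2), "positive")
})

test_that("cylinder and cone are valid closed solids with analytic measures", {
  cyl <- make_cylinder(1, 4, rings = 64, layers = 6)
  expect_equal(enclosed_volume(cyl), 4 * pi, tolerance = 5e-3)
  cs <- extract_cross_section(cyl, 1.7)
  expect_equal(sqrt(cs$area / pi), 1, tolerance = 0.01)

  cone <- make_cone(1, 3, rings = 48, layers = 24)
  expect_equal(euler_characteristic(cone), 2L)
  expect_gt(enclosed_volume(cone), 0)
  expect_error(make_cylinder(-1, 1), "positive")
})

test_that("synthetic canal generator is deterministic and parameter-faithful", {
  p <- fx_canal_params()
  m1 <- make_synthetic_canal(p)
  m2 <- make_synthetic_canal(p)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)

  # different seed, different surface
  m3 <- make_synthetic_canal(fx_canal_params(seed = 12L))
  expect_false(identical(m1$vertices, m3$vertices))

  # generator does not disturb the caller's RNG stream
  set.seed(123); a <- stats::rnorm(1)
  set.seed(123); invisible(make_synthetic_canal(p)); b <- stats::rnorm(1)
  expect_identical(a, b)

  expect_error(synth_canal_params(top_radius = 0.3, bottom_radius = 0.5),
               "taper")
  expect_error(synth_canal_params(noise_sd = -1), ">= 0")
})

test_that("smooth tube sections are circular to the polygonal floor", {
  p <- synth_canal_params(bump_amplitude = 0, noise_sd = 0,
                          axis_curvature = 0, rings = 64L, layers = 30L)
  tube <- make_synthetic_canal(p)
  # analytic polygonal circularity floor for a ring with ~2*rings points,
  # plus diagonal-edge sag: d-bar stays below (2 pi/rings)^2 * r
  for (d in c(2, 6, 10)) {
    cs <- extract_cross_section(tube, d)
    expect_lt(mean_boundary_deviation(cs),
              (2 * pi / p$rings)^2 * ideal_radius(cs))
  }
})

test_that("surface noise raises area-weighted mean absolute curvature", {
  base <- synth_canal_params(bump_amplitude = 0, noise_sd = 0, seed = 4L,
                             rings = 32L, layers = 40L)
  noisy <- synth_canal_params(bump_amplitude = 0, noise_sd = 0.05, seed = 4L,
                              rings = 32L, layers = 40L)
  mean_absK <- function(m) {
    cf <- gaussian_curvature(m)
    sum(abs(cf$K) * cf$A) / sum(cf$A)
  }
  expect_gt(mean_absK(make_synthetic_canal(noisy)),
            mean_absK(make_synthetic_canal(base)))
})

test_that("canal pairs model even enlargement with smoothing", {
  p <- fx_canal_params(noise_sd = 0.02)
  idpair <- make_canal_pair(p, enlargement = 0, smoothing = 1)
  expect_identical(idpair$pre$vertices, idpair$post$vertices)

  pair <- make_canal_pair(p, enlargement = 0.3, smoothing = 0.2)
  expect_gt(enclosed_volume(pair$post), enclosed_volume(pair$pre))
  expect_identical(pair$pre$vertices, idpair$pre$vertices)
  expect_error(make_canal_pair(p, enlargement = -1), ">= 0")

  # all generated meshes pass closed-manifold validation
  for (m in list(idpair$pre, pair$post)) expect_s3_class(validate_mesh(m),
                                                         "triangle_mesh")
})
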