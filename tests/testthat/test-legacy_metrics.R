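# legacy_metrics: slice stacks and the historical volume/area/transportation
# formulas

test_that("slice stacks record analytic section data", {
  cyl <- make_cylinder(1, 10, rings = 96, layers = 8)
  st <- build_slice_stack(cyl, 100)
  expect_equal(st$delta * st$N, st$h, tolerance = 1e-9)
  expect_true(all(abs(st$slices$area - pi) < 0.01 * pi))

  cone <- make_cone(1, 3, rings = 64, layers = 48)
  stc <- build_slice_stack(cone, 40)
  expect_true(all(diff(stc$slices$area) < 0))   # strictly decreasing

  expect_error(build_slice_stack(cyl, 1), ">= 2")
})

test_that("legacy surface area: lateral area with N-1 truncation, O(1/N) decay", {
  cyl <- make_cylinder(1, 10, rings = 96, layers = 8)
  st100 <- build_slice_stack(cyl, 100)
  S100 <- total_surface_area(st100)
  expect_equal(S100, 20 * pi, tolerance = 0.02)  # caps omitted by design

  # against the faceted cylinder's own lateral area P*h, the truncation
  # error of the N-1 sum is exactly P*h/N: doubling N halves it
  P <- extract_cross_section(cyl, 5)$perimeter
  e1 <- abs(P * 10 - S100)
  e2 <- abs(P * 10 - total_surface_area(build_slice_stack(cyl, 200)))
  expect_equal(e2 / e1, 0.5, tolerance = 0.15)
})

test_that("legacy volume converges to the analytic and mesh volumes", {
  cyl <- make_cylinder(1, 10, rings = 96, layers = 8)
  expect_equal(total_volume(build_slice_stack(cyl, 100)), 10 * pi,
               tolerance = 0.01)

  cone <- make_cone(1, 3, rings = 96, layers = 60)
  expect_equal(total_volume(build_slice_stack(cone, 200)), pi,
               tolerance = 0.01)

  # Riemann-sum error decreases monotonically on a convex fixture
  ico <- fx_ico(3)
  vref <- enclosed_volume(ico)
  errs <- sapply(c(50, 100, 200, 400), function(N)
    abs(total_volume(build_slice_stack(ico, N)) - vref))
  expect_true(all(diff(errs) < 0))
})

test_that("center transportation measures per-level centroid offsets", {
  cyl <- make_cylinder(1, 10, rings = 48, layers = 8)
  st <- build_slice_stack(cyl, 30)
  tr0 <- center_transportation(st, st)
  expect_true(all(tr0$offsets == 0))
  expect_equal(tr0$mean, 0)

  moved <- transform_mesh(cyl, translation = c(0.3, 0, 0))
  st2 <- build_slice_stack(moved, 30)
  tr <- center_transportation(st, st2)
  expect_equal(tr$offsets, rep(0.3, 30), tolerance = 1e-9)
  expect_equal(tr$mean, 0.3, tolerance = 1e-9)
  expect_equal(tr$levels_used, 30)

  expect_error(center_transportation(st, build_slice_stack(cyl, 31)),
               "different N")

  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "stack.csv")
  write_slice_stack(st, p, tr)
  d <- utils::read.csv(p)
  expect_true(all(c("level", "height", "area", "perimeter", "offset") %in%
                    names(d)))
})
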