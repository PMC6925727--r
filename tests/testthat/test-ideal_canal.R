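# ideal_canal: cross sections, circularity scoring, key-section selection,
# lofting

test_that("extract_cross_section recovers analytic sections", {
  cyl <- make_cylinder(radius = 1, height = 2, rings = 128, layers = 8)
  cs <- extract_cross_section(cyl, 1)
  expect_equal(cs$area, pi, tolerance = 0.01)
  expect_equal(cs$perimeter, 2 * pi, tolerance = 0.01)
  expect_equal(unname(cs$centroid), c(0, 0), tolerance = 1e-9)
  # CCW orientation seen from above
  expect_gt(canalssd:::polygon_signed_area(cs$boundary_points), 0)

  cone <- make_cone(top_radius = 1, height = 2, rings = 128, layers = 64)
  csc <- extract_cross_section(cone, 1)        # analytic radius 0.5
  expect_equal(csc$area, pi / 4, tolerance = 0.01)

  expect_error(extract_cross_section(cyl, -0.1), "range error")
  expect_error(extract_cross_section(cyl, 2.5), "range error")
})

test_that("ideal_radius is the equal-area circle radius", {
  mk <- function(A) list(area = A)
  expect_equal(ideal_radius(mk(pi)), 1)
  expect_equal(ideal_radius(mk(4 * pi)), 2)
  expect_error(ideal_radius(mk(0)), "positive")

  # regular 64-gon inscribed in the unit circle, against the shoelace oracle
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  poly <- cbind(cos(th), sin(th))
  A_oracle <- 0.5 * 64 * sin(2 * pi / 64)      # closed-form n-gon area
  cs <- cross_section(poly, height = 1)
  expect_equal(cs$area, A_oracle, tolerance = 1e-12)
  expect_equal(ideal_radius(cs), sqrt(A_oracle / pi))
  expect_equal(ideal_radius(cs), 0.99920, tolerance = 1e-4)
})

test_that("mean boundary deviation: circle, ellipse oracle, square enumeration", {
  # dense circle: deviation at the polygon-vs-circle area gap, ~ r x^2/12
  n <- 4096
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  circ <- cross_section(cbind(2 * cos(th), 2 * sin(th)), 0)
  expect_lt(mean_boundary_deviation(circ), 1e-6)

  # ellipse: independent direct-summation oracle over the same points
  pe <- cbind(2 * cos(th[seq(1, n, by = 16)]), sin(th[seq(1, n, by = 16)]))
  cse <- cross_section(pe, 0)
  ctr <- canalssd:::polygon_centroid(pe)
  r_id <- sqrt(abs(canalssd:::polygon_signed_area(pe)) / pi)
  oracle <- mean(abs(sqrt((pe[, 1] - ctr[1])^2 + (pe[, 2] - ctr[2])^2) - r_id))
  expect_equal(mean_boundary_deviation(cse), oracle, tolerance = 1e-12)
  expect_gt(mean_boundary_deviation(cse), 0.1)  # clearly non-circular

  # square of side 2 sampled at corners + edge midpoints: hand enumeration
  sq <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
              c(0, -1), c(1, -1))
  css <- cross_section(sq, 0)
  r <- 2 / sqrt(pi)
  hand <- 0.5 * (sqrt(2) - r) + 0.5 * (r - 1)
  expect_equal(mean_boundary_deviation(css), hand, tolerance = 1e-12)

  # in-plane rigid invariance
  phi <- 0.83
  Rm <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  sq2 <- sweep(sq %*% t(Rm), 2, c(3.2, -1.4), "+")
  expect_equal(mean_boundary_deviation(cross_section(sq2, 0)),
               mean_boundary_deviation(css), tolerance = 1e-12)
})

test_that("select_key_sections: cone ties to the central candidate, bumps shift it", {
  cone <- make_cone(top_radius = 1.2, height = 12, rings = 48, layers = 96)
  plan <- select_key_sections(cone)
  expect_identical(unname(plan$chosen), c(2L, 2L, 2L))
  expect_true(all(plan$deviations < 5e-3))
  expect_equal(unname(plan$segment_heights), rep(4, 3))
  expect_equal(unname(plan$offsets), rep(0.2, 3))
  # candidate depths: seg_top + h/3 + {-a, 0, a}
  expect_equal(unname(plan$candidate_depths[1, ]), 4 / 3 + c(-0.2, 0, 0.2))
  expect_equal(unname(plan$candidate_depths[2, ]), 4 + 4 / 3 + c(-0.2, 0, 0.2))

  # bump localized at the coronal central candidate plane moves the choice
  bumped <- cone
  H <- 12
  zc <- H - (4 / 3)                    # z of the coronal central candidate
  band <- abs(bumped$vertices[, 3] - zc) < H / 96
  r <- sqrt(rowSums(bumped$vertices[, 1:2]^2))
  scalef <- ifelse(band & r > 1e-9, 1 + 0.25 * (bumped$vertices[, 1] > 0), 1)
  bumped$vertices[, 1:2] <- bumped$vertices[, 1:2] * scalef
  bumped <- validate_mesh(bumped)
  plan_b <- select_key_sections(bumped)
  expect_true(plan_b$chosen[1] != 2L)
  expect_gt(plan_b$deviations[1, 2], max(plan_b$deviations[1, c(1, 3)]))

  expect_error(select_key_sections(cone, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(select_key_sections(cone, c(-1, 1, 1)), "positive")
})

test_that("lofting reproduces a cylinder and is monotone for tapered plans", {
  # five equal circles spanning height 10 -> cylinder
  mkcirc <- function(r, d, n = 256) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cross_section(cbind(r * cos(th), r * sin(th)), d)
  }
  plan <- canal_plan(lapply(c(0, 2.5, 5, 7.5, 10), function(d) mkcirc(1, d)))
  cylm <- loft_ideal_canal(plan, rings = 64)
  expect_equal(enclosed_volume(cylm), pi * 10, tolerance = 0.02)
  expect_equal(euler_characteristic(cylm), 2L)

  # linearly decreasing radii -> strictly decreasing section areas
  radii <- c(1.0, 0.85, 0.7, 0.55, 0.4)
  plan2 <- canal_plan(mapply(mkcirc, radii, c(0, 2.5, 5, 7.5, 10),
                             SIMPLIFY = FALSE))
  taper <- loft_ideal_canal(plan2, rings = 48)
  areas <- sapply(seq(0.5, 9.5, length.out = 20), function(d)
    extract_cross_section(taper, d)$area)
  expect_true(all(diff(areas) < 0))

  expect_error(canal_plan(plan2$sections[1:4]), "five")
  expect_error(loft_ideal_canal(plan2, rings = 8), ">= 16")
})

test_that("loft reproduces plan centroids and areas at the key planes", {
  canal <- fx_canal()
  plan <- select_key_sections(canal)
  id <- loft_ideal_canal(plan, rings = 32)
  # full z-extent is preserved (idempotent construction)
  expect_equal(range(id$vertices[, 3]), range(canal$vertices[, 3]),
               tolerance = 1e-9)
  for (nm in c("coronal", "middle", "apical")) {
    s <- plan$sections[[nm]]
    cs <- extract_cross_section(id, s$height)
    expect_lt(sqrt(sum((cs$centroid - s$centroid)^2)), 1e-6)
    expect_equal(cs$area, s$area, tolerance = 1e-6)
  }
})
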