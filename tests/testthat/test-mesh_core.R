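# mesh_core: I/O, validation, discrete differential geometry, transforms

test_that("mesh I/O round-trips connectivity and coordinates in all formats", {
  tet <- fx_tetra()
  ico <- fx_ico(2)
  tdir <- withr::local_tempdir()

  same_geometry <- function(a, b, tol = 1e-12) {
    # STL stores a triangle soup: vertex order follows face order on read,
    # so compare as a point set (nearest-neighbour match) plus measures
    expect_equal(dim(a$vertices), dim(b$vertices))
    expect_equal(nrow(a$faces), nrow(b$faces))
    dmat <- as.matrix(stats::dist(rbind(a$vertices, b$vertices)))
    n <- nrow(a$vertices)
    nearest <- apply(dmat[seq_len(n), n + seq_len(n), drop = FALSE], 1, min)
    expect_lt(max(nearest), max(tol, 1e-15) * max(abs(b$vertices)) + 1e-300)
    expect_equal(enclosed_volume(a), enclosed_volume(b), tolerance = max(tol, 1e-12))
  }

  for (m in list(tet, ico)) {
    for (ext in c("off", "obj", "ply")) {
      p <- file.path(tdir, paste0(m$name, ".", ext))
      write_mesh(m, p, binary = FALSE)
      back <- read_mesh(p)
      expect_equal(back$faces, m$faces, info = ext)       # order preserved
      expect_equal(back$vertices, m$vertices, tolerance = 0, info = ext)
    }
    # binary PLY: bit-exact doubles
    p <- file.path(tdir, paste0(m$name, "_b.ply"))
    write_mesh(m, p, binary = TRUE)
    expect_identical(read_mesh(p)$vertices, m$vertices)

    # ascii STL: exact coordinates up to soup merging/reordering
    p <- file.path(tdir, paste0(m$name, ".stl"))
    write_mesh(m, p, binary = FALSE)
    same_geometry(read_mesh(p), m)

    # binary STL: float32 storage, one read/write cycle is a fixpoint
    p <- file.path(tdir, paste0(m$name, "_b.stl"))
    write_mesh(m, p, binary = TRUE)
    once <- read_mesh(p)
    write_mesh(once, p, binary = TRUE)
    expect_identical(read_mesh(p)$vertices, once$vertices)
    same_geometry(once, m, tol = 1e-5)
  }
})

test_that("read_mesh rejects broken inputs with informative errors", {
  tdir <- withr::local_tempdir()
  expect_error(read_mesh(file.path(tdir, "nope.off")), "does not exist")

  # tetrahedron with a deleted face: 3 boundary edges
  tet <- fx_tetra()
  open_mesh <- structure(list(vertices = tet$vertices,
                              faces = tet$faces[-4L, , drop = FALSE],
                              name = "open"), class = "triangle_mesh")
  p <- file.path(tdir, "open.ply")
  write_mesh(open_mesh, p, binary = FALSE)
  expect_error(read_mesh(p), "3 edge\\(s\\)")

  # garbage file
  writeLines("not a mesh at all", file.path(tdir, "bad.off"))
  expect_error(read_mesh(file.path(tdir, "bad.off")), "OFF")

  # empty mesh refuses to write
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(0L, 0, 3), name = "empty"),
                     class = "triangle_mesh")
  expect_error(write_mesh(empty, file.path(tdir, "e.off")), "empty")
})

test_that("validation catches duplicates, degeneracy and orientation", {
  tet <- fx_tetra()
  dup <- tet
  dup$vertices[2, ] <- dup$vertices[1, ] + 1e-12
  expect_error(validate_mesh(dup), "duplicate|zero-area")

  flipped <- tet
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_warning(out <- validate_mesh(flipped), "flipping")
  expect_gt(enclosed_volume(out), 0)
  expect_error(validate_mesh(flipped, fix_orientation = FALSE), "inward")
})

test_that("areas and volumes match closed forms and the orientation law", {
  cube <- fx_cube()
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)

  ico <- fx_ico(4)
  expect_equal(surface_area(ico), 4 * pi, tolerance = 5e-3)
  expect_equal(enclosed_volume(ico), 4 * pi / 3, tolerance = 5e-3)

  rev_cube <- cube
  rev_cube$faces <- rev_cube$faces[, c(1, 3, 2)]
  expect_equal(enclosed_volume(rev_cube), -1)

  expect_equal(euler_characteristic(ico), 2L)
  expect_equal(euler_characteristic(fx_tetra()), 2L)
})

test_that("gaussian curvature: sphere values, cube deficits, exact Gauss-Bonnet", {
  ico <- fx_ico(4)
  cf_v <- gaussian_curvature(ico, area = "voronoi")
  expect_true(all(abs(cf_v$K - 1) < 0.05))      # analytic K = 1/R^2

  cf <- gaussian_curvature(ico)                  # barycentric default
  expect_lt(abs(sum(cf$K * cf$A) - 4 * pi), 1e-10)
  expect_lt(abs(stats::median(cf$K) - 1), 0.05)

  cube <- fx_cube()
  cfc <- gaussian_curvature(cube)
  expect_equal(unname(cfc$deficit), rep(pi / 2, 8), tolerance = 1e-12)

  # Gauss-Bonnet holds on every closed genus-0 fixture, both area rules
  for (m in list(fx_tetra(), cube, fx_ico(2), fx_canal())) {
    for (rule in c("barycentric", "voronoi")) {
      cf <- gaussian_curvature(m, area = rule)
      expect_lt(abs(sum(cf$K * cf$A) - 2 * pi * euler_characteristic(m)), 1e-10)
    }
    expect_equal(sum(vertex_areas(m)), surface_area(m), tolerance = 1e-12)
  }
})

test_that("solid angle coefficient: smooth ~ 0.5, flat exactly 0.5, cube corner 1/8", {
  cube <- fx_cube()
  expect_equal(solid_angle_coefficient(cube, 1), 0.125, tolerance = 1e-12)

  cyl <- make_cylinder(1, 1, rings = 32, layers = 4)
  itop <- 32L * 5L + 1L                        # flat top-cap centre vertex
  expect_equal(solid_angle_coefficient(cyl, itop), 0.5, tolerance = 1e-12)

  s <- solid_angle_coefficient(make_icosphere(1, 5))
  expect_true(all(abs(s - 0.5) < 0.02))
  expect_true(all(s > 0 & s < 1))
  expect_error(solid_angle_coefficient(cube, 99), "out of range")
})

test_that("transform_mesh: identity, similarity scaling laws, rigid isometry", {
  ico <- fx_ico(2)
  expect_equal(transform_mesh(ico), ico)

  s <- 2
  big <- transform_mesh(ico, scale = s)
  expect_equal(enclosed_volume(big), s^3 * enclosed_volume(ico), tolerance = 1e-10)
  expect_equal(surface_area(big), s^2 * surface_area(ico), tolerance = 1e-10)

  set.seed(5)
  R <- random_rotation()
  rig <- transform_mesh(ico, rotation = R, translation = c(1, -2, 3))
  edge_len <- function(m) {
    he <- canalssd:::half_edges(m)
    sqrt(rowSums((m$vertices[he[, 1], ] - m$vertices[he[, 2], ])^2))
  }
  expect_equal(edge_len(rig), edge_len(ico), tolerance = 1e-12)

  expect_error(transform_mesh(ico, rotation = diag(3) * 1.01), "orthonormal")
  expect_error(transform_mesh(ico, scale = -1), "positive")
})
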