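# bem_steklov: Galerkin operator structure, Steklov solve, ICCG

test_that("assembled operators have the required structure", {
  for (sub in c(1, 2)) {
    ops <- fx_ops_ico(sub)
    expect_lt(norm(ops$Kstar - t(ops$K), "F"), 1e-10 * norm(ops$K, "F"))
    expect_lt(max(abs(ops$V - t(ops$V))), 1e-10 * max(abs(ops$V)))
    expect_lt(max(abs(ops$D - t(ops$D))), 1e-10 * max(abs(ops$D)))
    expect_lt(max(abs(ops$G - t(ops$G))), 1e-14 * max(abs(ops$G)))

    # D annihilates constants (exact by the curl weak form)
    expect_lt(sqrt(sum((ops$D %*% rep(1, ops$n))^2)), 1e-8 * norm(ops$D, "F"))

    # SPD single-layer and mass matrices
    expect_gt(min(eigen(ops$V, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_gt(min(eigen(ops$G, symmetric = TRUE, only.values = TRUE)$values), 0)

    # G row sums are the barycentric vertex areas (hat partition of unity)
    expect_equal(rowSums(ops$G), vertex_areas(ops$mesh), tolerance = 1e-12)

    # sigma is a valid solid-angle fraction, near 1/2 once the mesh is fine
    expect_true(all(ops$sigma > 0 & ops$sigma < 1))
    if (sub == 2) expect_true(all(abs(ops$sigma - 0.5) < 0.1))
  }
  expect_error(assemble_operators(fx_ico(1), quadrature_order = 2), ">= 3")
})

test_that("far-field entries match the 64-point product-quadrature oracle", {
  # two well-separated tetrahedra in one (disconnected, still closed) mesh
  tet <- fx_tetra()
  shift <- 10
  v <- rbind(tet$vertices, sweep(tet$vertices, 2, c(shift, 0, 0), "+"))
  f <- rbind(tet$faces, tet$faces + 4L)
  m2 <- triangle_mesh(v, f, name = "two_tets")
  ops <- assemble_operators(m2)

  # oracle: sum the 8x8 Duffy-Gauss (64-point) pair blocks over face pairs
  Vref <- matrix(0, 8, 8)
  Kref <- matrix(0, 8, 8)
  for (a in 1:4) for (b in 5:8) {
    fa <- m2$faces[a, ]; fb <- m2$faces[b, ]
    orc <- canalssd:::.bem_pair_oracle(m2$vertices[fa, ], m2$vertices[fb, ], 8L)
    Vref[fa, fb] <- Vref[fa, fb] + orc$V
    Kref[fa, fb] <- Kref[fa, fb] + orc$K
  }
  blk <- ops$V[1:4, 5:8]
  expect_lt(max(abs(blk - Vref[1:4, 5:8])) / max(abs(blk)), 1e-3)
  blkK <- ops$K[1:4, 5:8]
  expect_lt(max(abs(blkK - Kref[1:4, 5:8])) / max(abs(blkK)), 1e-3)

  # leading-order magnitude: (1/(4 pi d)) x product of hat masses
  i <- 1; j <- 5
  mass_i <- sum(ops$G[i, ]); mass_j <- sum(ops$G[j, ])
  expect_equal(ops$V[i, j], mass_i * mass_j / (4 * pi * shift),
               tolerance = 0.1)
})

test_that("ball spectrum matches the closed form and improves under refinement", {
  ref <- ball_reference(9)
  errs <- sapply(2:3, function(sub) {
    sp <- fx_spec_ico(sub)
    expect_lt(abs(sp$eigenvalues[1]), 1e-6 * sp$eigenvalues[2])  # zero mode
    max_rel_err(sp$eigenvalues[2:10], ref)
  })
  expect_lt(errs[1], 0.05)          # subdiv 2 already within 5%
  expect_lt(errs[2], errs[1])       # refinement helps

  # eigenvector structure: G-orthonormal, first one constant
  sp <- fx_spec_ico(2)
  ops <- fx_ops_ico(2)
  M <- t(sp$eigenvectors) %*% ops$G %*% sp$eigenvectors
  expect_lt(max(abs(M - diag(ncol(M)))), 1e-8)
  v0 <- sp$eigenvectors[, 1]
  expect_lt(diff(range(v0)) / max(abs(v0)), 1e-4)
})

test_that("spectrum obeys the scaling law and rigid invariance", {
  sp <- fx_spec_ico(2)
  base <- sp$eigenvalues[-1]
  for (s in c(0.5, 2)) {
    sc <- transform_mesh(fx_ico(2), scale = s)
    sps <- solve_steklov(assemble_operators(sc), m = 13)
    expect_lt(max_rel_err(sps$eigenvalues[-1], base / s), 1e-8)
  }
  set.seed(99)
  for (k in 1:2) {
    rig <- transform_mesh(fx_ico(2), rotation = random_rotation(),
                          translation = stats::rnorm(3))
    spr <- solve_steklov(assemble_operators(rig), m = 13)
    expect_lt(max_rel_err(spr$eigenvalues[-1], base), 1e-8)
  }
})

test_that("normalize_spectrum is scale invariant and idempotent", {
  sp <- fx_spec_ico(2)
  expect_identical(normalize_spectrum(sp, "raw"), sp)
  a1 <- normalize_spectrum(sp, "area")
  expect_equal(a1$eigenvalues, sp$eigenvalues * sqrt(surface_area(fx_ico(2))))
  expect_identical(normalize_spectrum(a1, "area"), a1)
  expect_lt(abs(a1$eigenvalues[1]), 1e-6 * a1$eigenvalues[2])

  sc <- transform_mesh(fx_ico(2), scale = 3)
  a2 <- normalize_spectrum(solve_steklov(assemble_operators(sc), m = 13), "area")
  expect_lt(max_rel_err(a2$eigenvalues[-1], a1$eigenvalues[-1]), 1e-8)
})

test_that("solve_steklov validates arguments and spectra serialize", {
  ops <- fx_ops_ico(1)
  expect_error(solve_steklov(ops, m = ops$n), "n - 1")
  sp <- fx_spec_ico(2)
  tdir <- withr::local_tempdir()
  pj <- file.path(tdir, "s.json"); pc <- file.path(tdir, "s.csv")
  write_spectrum(sp, pj); write_spectrum(sp, pc)
  expect_equal(read_spectrum(pj)$eigenvalues, sp$eigenvalues)
  expect_equal(read_spectrum(pc)$eigenvalues, sp$eigenvalues)
  expect_identical(read_spectrum(pj)$normalization, "raw")
})

test_that("iccg_solve matches direct solves and preconditioning helps", {
  expect_equal(iccg_solve(diag(4), c(1, 2, 3, 4))$iterations, 1L)

  set.seed(31)
  B <- matrix(stats::rnorm(2500), 50, 50)
  A <- crossprod(B) + 50 * diag(50)
  b <- stats::rnorm(50)
  res <- iccg_solve(A, b, tol = 1e-12)
  expect_equal(res$x, solve(A, b), tolerance = 1e-9)

  V <- fx_ops_ico(1)$V
  bb <- stats::rnorm(nrow(V))
  with_pc <- iccg_solve(V, bb, tol = 1e-10)
  no_pc <- iccg_solve(V, bb, tol = 1e-10, precondition = FALSE)
  expect_lte(with_pc$iterations, no_pc$iterations)
  expect_equal(with_pc$x, no_pc$x, tolerance = 1e-6)

  expect_error(iccg_solve(matrix(c(1, 2, 3, 4), 2, 2), c(1, 1)), "symmetric")
  expect_error(iccg_solve(-diag(3), rep(1, 3)), "positive definite")
})
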