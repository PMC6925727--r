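#' Assemble the Galerkin boundary-operator matrices
#'
#' Builds the five matrices of the piecewise-linear Galerkin discretization of
#' the Laplace layer potentials on a closed mesh: single layer `V`, double
#' layer `K`, its adjoint `Kstar`, hypersingular `D` (regularized
#' integration-by-parts form) and mass matrix `G`, together with the
#' per-vertex interior solid-angle fractions `sigma`.
#'
#' Far triangle pairs are integrated by a tensor Gauss rule of the requested
#' order; coincident, adjacent and close pairs by adaptive outer subdivision
#' with exact closed-form inner panel integrals, which removes the weak
#' singularity of the kernels analytically.
#'
#' @param mesh a [triangle_mesh()] with at least 4 vertices.
#' @param quadrature_order polynomial order of the far-field tensor Gauss rule
#'   (>= 3; default 5, a 7-point rule per triangle).
#' @param near_order order of the outer rule on subdivided near panels.
#' @param max_subdiv adaptive outer subdivision depth for near pairs.
#' @param eta admissibility constant: pairs with centroid distance greater
#'   than `eta * (r1 + r2)` (bounding radii) take the far path.
#' @return an object of class `boundary_operators`: list with matrices
#'   `V`, `K`, `Kstar`, `D`, `G`, vector `sigma`, `n`, the parent `mesh` and
#'   `quadrature` metadata.
#' @export
assemble_operators <- function(mesh, quadrature_order = 5L, near_order = 5L,
                               max_subdiv = 3L, eta = 2.0) {
  if (!inherits(mesh, "triangle_mesh")) stop("`mesh` must be a triangle_mesh")
  n <- nrow(mesh$vertices)
  if (n < 4L) stop("mesh must have at least 4 vertices")
  if (quadrature_order < 3L) stop("`quadrature_order` must be >= 3")

  raw <- .assemble_bem(mesh$vertices, mesh$faces,
                       far_order = as.integer(quadrature_order),
                       near_order = as.integer(near_order),
                       max_subdiv = as.integer(max_subdiv), eta = eta)
  G <- mass_matrix(mesh)
  sigma <- solid_angle_coefficient(mesh)
  structure(list(V = raw$V, K = raw$K, Kstar = t(raw$K), D = raw$D, G = G,
                 sigma = sigma, n = n, mesh = mesh,
                 quadrature = list(far_order = quadrature_order,
                                   near_order = near_order,
                                   far_points = raw$far_points,
                                   near_points = raw$near_points,
                                   max_subdiv = max_subdiv, eta = eta,
                                   regularization = "exact-inner-panel+curl-weak-form")),
            class = "boundary_operators")
}

#' @export
print.boundary_operators <- function(x, ...) {
  cat(sprintf("<boundary_operators: n = %d (mesh '%s'), far rule %d pts, near rule %d pts>\n",
              x$n, x$mesh$name, x$quadrature$far_points, x$quadrature$near_points))
  invisible(x)
}

## exact P1 mass matrix (dense; meshes here are small enough)
mass_matrix <- function(mesh) {
  n <- nrow(mesh$vertices)
  f <- mesh$faces
  fa <- face_areas(mesh)
  G <- matrix(0, n, n)
  idx <- cbind(rep(seq_len(nrow(f)), each = 9L),
               a = rep(rep(1:3, each = 3L), times = nrow(f)),
               b = rep(rep(1:3, times = 3L), times = nrow(f)))
  i <- f[cbind(idx[, 1L], idx[, 2L])]
  j <- f[cbind(idx[, 1L], idx[, 3L])]
  w <- ifelse(idx[, 2L] == idx[, 3L], fa[idx[, 1L]] / 6, fa[idx[, 1L]] / 12)
  for (k in seq_along(i)) G[i[k], j[k]] <- G[i[k], j[k]] + w[k]
  G
}

## sigma-weighted mass matrix: int sigma~(x) phi_i phi_j with sigma~ the P1
## interpolant of the per-vertex values; int phi_a phi_b phi_k over a triangle
## is A/10 (a=b=k), A/30 (two equal), A/60 (all distinct)
sigma_mass_matrix <- function(mesh, sigma) {
  n <- nrow(mesh$vertices)
  f <- mesh$faces
  fa <- face_areas(mesh)
  M <- matrix(0, n, n)
  for (t in seq_len(nrow(f))) {
    v <- f[t, ]
    s <- sigma[v]
    A <- fa[t]
    loc <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      w <- 0
      for (k in 1:3) {
        cnt <- 1L + (a == b) + (a == k) + (b == k)
        coef <- if (cnt == 4L) A / 10 else if (cnt >= 2L && (a == b || a == k || b == k)) A / 30 else A / 60
        w <- w + s[k] * coef
      }
      loc[a, b] <- w
    }
    M[v, v] <- M[v, v] + loc
  }
  M
}

#' Solve the discrete Steklov eigenvalue problem
#'
#' Solves the symmetric Galerkin form of the Dirichlet-to-Neumann (Steklov)
#' eigenproblem
#' \deqn{ \left[ D + (G_\sigma + K)^\top V^{-1} (G_\sigma + K) \right] u = \lambda G u, }
#' where \eqn{G_\sigma} is the \eqn{\sigma}-weighted mass matrix (the Galerkin
#' realization of \eqn{\sigma(x) I}, with \eqn{\sigma = 1/2} almost everywhere
#' on smooth surfaces).  `V` is inverted through its Cholesky factorization
#' after symmetric diagonal equilibration.
#'
#' @param ops a [assemble_operators()] result.
#' @param m number of eigenpairs to return (`m <= n - 1`; default 50,
#'   the "first dozens" regime).
#' @param sigma `"half"` (default) uses the almost-everywhere value
#'   \eqn{\sigma = 1/2}: the vertex set where the polyhedral solid angle
#'   deviates from 1/2 has measure zero, so this is the Galerkin-consistent
#'   choice (and the one the continuous eigenproblem uses on smooth
#'   surfaces).  `"vertex"` weights the mass matrix by the interpolated
#'   per-vertex interior solid-angle fractions instead; on smooth meshes the
#'   polyhedral solid angle converges to 1/2 only at O(h), which injects a
#'   first-order eigenvalue bias, so use it only for genuinely creased
#'   geometry.
#' @return an object of class `steklov_spectrum`: ascending `eigenvalues`
#'   (mm^-1, the first one is the zero mode), a matrix of G-orthonormal
#'   `eigenvectors` (columns), `normalization` flag, and the parent mesh.
#' @export
solve_steklov <- function(ops, m = 50L, sigma = c("half", "vertex")) {
  if (!inherits(ops, "boundary_operators")) stop("`ops` must be boundary_operators")
  sigma <- match.arg(sigma)
  n <- ops$n
  m <- as.integer(m)
  if (m > n - 1L) stop("`m` must be <= n - 1")
  if (m < 1L) stop("`m` must be >= 1")

  Gs <- if (sigma == "half") 0.5 * ops$G
        else sigma_mass_matrix(ops$mesh, ops$sigma)
  A <- Gs + ops$K

  ## symmetric diagonal equilibration of V, then Cholesky
  d <- 1 / sqrt(diag(ops$V))
  if (any(!is.finite(d)))
    stop("V has non-positive diagonal entries; mesh may be degenerate")
  Vs <- ops$V * tcrossprod(d)
  U <- tryCatch(chol(Vs), error = function(e)
    stop("single-layer matrix V is numerically indefinite/singular; ",
         "try a finer mesh or rescale the geometry (conditioning error): ",
         conditionMessage(e)))
  ## V^{-1} A  =  d * Vs^{-1} * (d * A)
  X <- d * backsolve(U, backsolve(U, d * A, transpose = TRUE))
  S <- ops$D + crossprod(A, X)
  S <- (S + t(S)) / 2

  ## reduce the G-generalized problem to standard form with chol(G)
  Ug <- chol(ops$G)
  B <- backsolve(Ug, t(backsolve(Ug, t(S), transpose = TRUE)), transpose = TRUE)
  B <- (B + t(B)) / 2
  ee <- eigen(B, symmetric = TRUE)
  take <- n:(n - m + 1L)                       # eigen() sorts descending
  lambda <- ee$values[take]                    # ascending
  vecs <- ee$vectors[, take, drop = FALSE]
  evec <- backsolve(Ug, vecs)                  # G-orthonormal by construction

  structure(list(eigenvalues = lambda, eigenvectors = evec,
                 normalization = "raw", m = m, sigma_mode = sigma,
                 mesh = ops$mesh, mesh_name = ops$mesh$name,
                 quadrature = ops$quadrature),
            class = "steklov_spectrum")
}

#' @export
print.steklov_spectrum <- function(x, ...) {
  cat(sprintf("<steklov_spectrum '%s' (%s): %d eigenvalues, lambda_1..5 = %s>\n",
              x$mesh_name, x$normalization, length(x$eigenvalues),
              paste(signif(x$eigenvalues[2:min(6, length(x$eigenvalues))], 4),
                    collapse = ", ")))
  invisible(x)
}

#' Normalize a Steklov spectrum
#'
#' `mode = "area"` multiplies every eigenvalue by the square root of the mesh
#' surface area, yielding a dimensionless, scale-invariant spectrum
#' (raw Steklov eigenvalues scale as 1/s under uniform scaling by s, the
#' area as s^2).  `mode = "raw"` is the identity.
#'
#' @param spec a [solve_steklov()] result.
#' @param mode `"raw"` or `"area"`.
#' @return the spectrum with rescaled eigenvalues and updated
#'   `normalization` flag.
#' @export
normalize_spectrum <- function(spec, mode = c("raw", "area")) {
  mode <- match.arg(mode)
  if (!inherits(spec, "steklov_spectrum")) stop("`spec` must be a steklov_spectrum")
  if (mode == "raw") return(spec)
  if (spec$normalization == "area") return(spec)
  spec$eigenvalues <- spec$eigenvalues * sqrt(surface_area(spec$mesh))
  spec$normalization <- "area"
  spec
}

#' Incomplete-Cholesky preconditioned conjugate gradients
#'
#' Solves `A x = b` for symmetric positive definite `A`.  The preconditioner
#' is the incomplete Cholesky factor that keeps the sparsity pattern of `A`
#' (entries where `a_ij != 0` are computed by the complete formula, all
#' others dropped), so `A = L L' + R` with `R` the dropped residual; each CG
#' step applies the preconditioner through the two triangular solves.
#' A non-positive pivot triggers a diagonally shifted refactorization.
#'
#' @param A SPD matrix (positive definiteness is checked by factorization
#'   success, not by eigendecomposition).
#' @param b right-hand-side vector.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap (default `10 n`).
#' @param precondition set `FALSE` for plain conjugate gradients.
#' @return list with `x`, `iterations`, `residual` and the diagonal `shift`
#'   used (0 when the factorization succeeded directly).
#' @export
iccg_solve <- function(A, b, tol = 1e-10, maxit = 0L, precondition = TRUE) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("`A` must be square")
  if (max(abs(A - t(A))) > 1e-8 * max(abs(A))) stop("`A` must be symmetric")
  if (length(b) != nrow(A)) stop("length(b) must match nrow(A)")
  res <- .iccg_solve_cpp(A, as.numeric(b), tol = tol,
                         maxit = as.integer(maxit),
                         precondition = precondition)
  res$x <- drop(res$x)
  res
}

#' Write / read a spectrum as JSON or CSV
#'
#' JSON carries `mesh_name`, `normalization`, `eigenvalues`, `sigma_mode` and
#' quadrature metadata; CSV has columns `index,eigenvalue` (index 0 is the
#' zero mode).
#'
#' @param spec a `steklov_spectrum`.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path` invisibly (write) or a `steklov_spectrum`-like list (read;
#'   eigenvectors and mesh are not serialized).
#' @export
write_spectrum <- function(spec, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") {
    jsonlite::write_json(
      list(mesh_name = spec$mesh_name, normalization = spec$normalization,
           sigma_mode = spec$sigma_mode, eigenvalues = spec$eigenvalues,
           quadrature = spec$quadrature[c("far_order", "near_order",
                                          "max_subdiv", "eta")]),
      path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(data.frame(index = seq_along(spec$eigenvalues) - 1L,
                                eigenvalue = spec$eigenvalues),
                     path, row.names = FALSE)
  } else stop("unsupported spectrum format: use .json or .csv")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(list(eigenvalues = as.numeric(obj$eigenvalues),
                   normalization = obj$normalization,
                   sigma_mode = obj$sigma_mode,
                   mesh_name = obj$mesh_name, quadrature = obj$quadrature),
              class = "steklov_spectrum")
  } else if (ext == "csv") {
    d <- utils::read.csv(path)
    structure(list(eigenvalues = as.numeric(d$eigenvalue),
                   normalization = "unknown", mesh_name = basename(path)),
              class = "steklov_spectrum")
  } else stop("unsupported spectrum format: use .json or .csv")
}
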