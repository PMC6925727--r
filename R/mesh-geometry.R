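#' Discrete Gaussian curvature (angle deficit) of a closed mesh
#'
#' Per-vertex Gaussian curvature
#' \eqn{K(x) = (2\pi - \sum_i \theta_i)/A(x)}, where the \eqn{\theta_i} are
#' the interior angles at `x` of its incident triangles and `A(x)` is the
#' 1-ring vertex area.  With the default barycentric area (one third of the
#' incident triangle areas) the Gauss--Bonnet identity
#' \eqn{\sum_x K(x) A(x) = 2\pi\chi} holds to machine precision.
#'
#' @param mesh a [triangle_mesh()].
#' @param area one of `"barycentric"` (default) or `"voronoi"` (mixed Voronoi
#'   area, clamped for obtuse triangles).
#' @return an object of class `curvature_field`: list with per-vertex `K`
#'   (mm^-2), `A` (mm^2), the angle deficits `deficit`, the `area` rule used
#'   and the parent `mesh`.
#' @export
gaussian_curvature <- function(mesh, area = c("barycentric", "voronoi")) {
  area <- match.arg(area)
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)

  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]

  ang <- function(a, b, c) {
    ## interior angle at a
    u <- b - a; w <- c - a
    nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
    cosang <- rowSums(u * w) / (nu * nw)
    acos(pmin(1, pmax(-1, cosang)))
  }
  th1 <- ang(p1, p2, p3)
  th2 <- ang(p2, p3, p1)
  th3 <- ang(p3, p1, p2)

  angle_sum <- as.numeric(
    rowsum(c(th1, th2, th3), group = c(f[, 1L], f[, 2L], f[, 3L]),
           reorder = TRUE))
  idx <- sort(unique(as.integer(f)))
  full_sum <- numeric(nv)
  full_sum[idx] <- angle_sum
  deficit <- 2 * pi - full_sum

  A <- vertex_areas(mesh, rule = area)
  structure(list(K = deficit / A, A = A, deficit = deficit,
                 area = area, mesh = mesh),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf(
    "<curvature_field: %d vertices, %s areas, sum K*A = %.6f (2*pi*chi = %.6f)>\n",
    length(x$K), x$area, sum(x$K * x$A),
    2 * pi * euler_characteristic(x$mesh)))
  invisible(x)
}

#' Per-vertex 1-ring areas
#'
#' @param mesh a [triangle_mesh()].
#' @param rule `"barycentric"` (1/3 of incident triangle areas) or
#'   `"voronoi"` (mixed Voronoi area of Meyer et al., obtuse-safe).
#' @return numeric vector of vertex areas (mm^2) summing to [surface_area()].
#' @export
vertex_areas <- function(mesh, rule = c("barycentric", "voronoi")) {
  rule <- match.arg(rule)
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  fa <- face_areas(mesh)
  if (rule == "barycentric") {
    contrib <- rep(fa / 3, 3L)
    grp <- c(f[, 1L], f[, 2L], f[, 3L])
  } else {
    p1 <- v[f[, 1L], , drop = FALSE]
    p2 <- v[f[, 2L], , drop = FALSE]
    p3 <- v[f[, 3L], , drop = FALSE]
    cot <- function(a, b, c) {
      ## cotangent of angle at a
      u <- b - a; w <- c - a
      cr <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
                  u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
                  u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
      rowSums(u * w) / sqrt(rowSums(cr^2))
    }
    ct1 <- cot(p1, p2, p3); ct2 <- cot(p2, p3, p1); ct3 <- cot(p3, p1, p2)
    l12 <- rowSums((p1 - p2)^2)  # edge opposite ct3
    l23 <- rowSums((p2 - p3)^2)  # opposite ct1
    l31 <- rowSums((p3 - p1)^2)  # opposite ct2
    ## Voronoi area of corner i: (1/8)(l_ij cot(k) + l_ik cot(j))
    a1 <- (l12 * ct3 + l31 * ct2) / 8
    a2 <- (l12 * ct3 + l23 * ct1) / 8
    a3 <- (l31 * ct2 + l23 * ct1) / 8
    obtuse1 <- ct1 < 0; obtuse2 <- ct2 < 0; obtuse3 <- ct3 < 0
    anyob <- obtuse1 | obtuse2 | obtuse3
    ## mixed rule: obtuse at the corner -> area/2, else area/4
    a1[anyob] <- ifelse(obtuse1[anyob], fa[anyob] / 2, fa[anyob] / 4)
    a2[anyob] <- ifelse(obtuse2[anyob], fa[anyob] / 2, fa[anyob] / 4)
    a3[anyob] <- ifelse(obtuse3[anyob], fa[anyob] / 2, fa[anyob] / 4)
    contrib <- c(a1, a2, a3)
    grp <- c(f[, 1L], f[, 2L], f[, 3L])
  }
  s <- rowsum(contrib, group = grp, reorder = TRUE)
  idx <- as.integer(rownames(s))
  out <- numeric(nv)
  out[idx] <- s
  out
}

#' Interior solid-angle fraction at mesh vertices
#'
#' Returns \eqn{\sigma(x)}: the solid angle subtended at the vertex by the
#' interior of the solid, divided by \eqn{4\pi}.  At a smooth point of the
#' limiting surface \eqn{\sigma = 0.5}; at a cube corner \eqn{\sigma = 1/8}.
#' Computed from the spherical-polygon area of the vertex link:
#' \eqn{\Omega = \sum_e \theta_e - (m-2)\pi}, with \eqn{\theta_e} the interior
#' dihedral angles of the solid along the `m` incident edges.
#'
#' @param mesh a [triangle_mesh()].
#' @param vertex optional vertex index (1-based); if `NULL`, the whole
#'   per-vertex vector is returned.
#' @return sigma value(s) in (0, 1).
#' @export
solid_angle_coefficient <- function(mesh, vertex = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  if (!is.null(vertex)) {
    vertex <- as.integer(vertex)
    if (any(vertex < 1L | vertex > nv)) stop("vertex index out of range")
  }

  nrm <- face_normals(mesh)
  he <- half_edges(mesh)                      # 3F x 2, face id recycled
  fid <- rep.int(seq_len(nrow(f)), 3L)
  key <- edge_keys(he)
  ord <- order(key)
  ke <- key[ord]; fe <- fid[ord]; hee <- he[ord, , drop = FALSE]
  ## after sorting, rows come in pairs with equal keys (validated manifold)
  first <- seq(1L, length(ke), by = 2L)
  stopifnot(all(ke[first] == ke[first + 1L]))
  fA <- fe[first]; fB <- fe[first + 1L]
  eA <- hee[first, , drop = FALSE]            # directed edge as seen by face A

  edir <- v[eA[, 2L], , drop = FALSE] - v[eA[, 1L], , drop = FALSE]
  edir <- edir / sqrt(rowSums(edir^2))
  n1 <- nrm[fA, , drop = FALSE]
  n2 <- nrm[fB, , drop = FALSE]
  cr <- cbind(n1[, 2L] * n2[, 3L] - n1[, 3L] * n2[, 2L],
              n1[, 3L] * n2[, 1L] - n1[, 1L] * n2[, 3L],
              n1[, 1L] * n2[, 2L] - n1[, 2L] * n2[, 1L])
  sinphi <- rowSums(cr * edir)
  cosphi <- rowSums(n1 * n2)
  ## interior dihedral angle along the edge (pi on a flat surface,
  ## < pi along convex creases)
  theta <- pi - atan2(sinphi, pmin(1, pmax(-1, cosphi)))

  ## accumulate per endpoint: each undirected edge is incident to both its ends
  grp <- c(eA[, 1L], eA[, 2L])
  s <- rowsum(c(theta, theta), group = grp, reorder = TRUE)
  idx <- as.integer(rownames(s))
  theta_sum <- numeric(nv); theta_sum[idx] <- s
  m <- numeric(nv)
  cnt <- rowsum(rep(1, length(grp)), group = grp, reorder = TRUE)
  m[as.integer(rownames(cnt))] <- cnt

  omega <- theta_sum - (m - 2) * pi
  sigma <- omega / (4 * pi)
  if (is.null(vertex)) sigma else sigma[vertex]
}
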