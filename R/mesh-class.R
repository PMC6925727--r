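#' Triangle surface mesh
#'
#' A closed, consistently oriented (counter-clockwise, outward normals)
#' 2-manifold triangle mesh bounding a solid cavity.  Coordinates are in mm.
#' The canal axis convention is +z with the coronal (top) end at larger z;
#' heights/depths elsewhere in the package are measured down from the top.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices, CCW when seen
#'   from outside the solid.
#' @param name free-text label carried through I/O and reports.
#' @param validate check the closed-manifold invariants (default `TRUE`).
#' @param fix_orientation if the signed enclosed volume is negative, flip all
#'   faces (with a warning) instead of failing.  Default `TRUE`.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", validate = TRUE,
                          fix_orientation = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an m x 3 matrix")
  mesh <- structure(list(vertices = vertices, faces = faces,
                         name = as.character(name)[1L]),
                    class = "triangle_mesh")
  if (validate) mesh <- validate_mesh(mesh, fix_orientation = fix_orientation)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces, chi = %d>\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              euler_characteristic(x)))
  invisible(x)
}

## directed half-edge table: one row per face corner, columns (from, to)
half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(from = c(f[, 1L], f[, 2L], f[, 3L]),
        to   = c(f[, 2L], f[, 3L], f[, 1L]))
}

## undirected edge keys "i:j" with i < j
edge_keys <- function(he) {
  i <- pmin(he[, 1L], he[, 2L])
  j <- pmax(he[, 1L], he[, 2L])
  paste(i, j, sep = ":")
}

#' Euler characteristic |V| - |E| + |F|
#' @param mesh a [triangle_mesh()].
#' @return integer Euler characteristic of the surface.
#' @export
euler_characteristic <- function(mesh) {
  he <- half_edges(mesh)
  ne <- length(unique(edge_keys(he)))
  as.integer(nrow(mesh$vertices) - ne + nrow(mesh$faces))
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  u <- b - a
  w <- c - a
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  nrm <- sqrt(rowSums(cr^2))
  cr / pmax(nrm, .Machine$double.xmin)
}

#' Validate the closed-manifold invariants of a mesh
#'
#' Checks that every undirected edge is shared by exactly two faces with
#' opposite orientation, that no face is degenerate, that no two vertices
#' coincide within `1e-9` mm, and that the signed enclosed volume is positive
#' under the outward-normal convention.
#'
#' @inheritParams triangle_mesh
#' @param mesh a [triangle_mesh()].
#' @return the validated (possibly reoriented) mesh, invisibly classed.
#' @export
validate_mesh <- function(mesh, fix_orientation = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) < 3L || nrow(f) < 1L)
    stop("mesh is empty or too small to bound a solid (need >= 4 vertices and faces)")
  if (anyNA(v) || anyNA(f)) stop("mesh contains NA values")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face indices out of range")

  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
    stop("degenerate face(s) with repeated vertex indices")
  areas <- face_areas(mesh)
  if (any(areas <= 1e-300))
    stop(sprintf("zero-area face(s): %s",
                 paste(utils::head(which(areas <= 1e-300), 10L), collapse = ", ")))

  ## duplicate vertices within 1e-9 mm (grid hash at the tolerance)
  key <- paste(round(v[, 1L] / 1e-9), round(v[, 2L] / 1e-9),
               round(v[, 3L] / 1e-9))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop(sprintf("duplicate vertices within 1e-9 mm (e.g. vertex %d)", dup[1L]))
  }

  he <- half_edges(mesh)
  key <- edge_keys(he)
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad) > 0L)
    stop(sprintf(
      "surface is not a closed 2-manifold: %d edge(s) not shared by exactly 2 faces (e.g. %s)",
      length(bad), paste(utils::head(bad, 5L), collapse = ", ")))
  ## opposite orientation: each directed edge must appear exactly once
  dkey <- paste(he[, 1L], he[, 2L], sep = ">")
  if (anyDuplicated(dkey)) {
    d <- dkey[duplicated(dkey)][1L]
    stop(sprintf("inconsistent face orientation: directed edge %s appears twice", d))
  }

  vol <- enclosed_volume(mesh)
  if (vol < 0) {
    if (!fix_orientation)
      stop("signed enclosed volume is negative: faces are oriented inward")
    warning("mesh '", mesh$name,
            "': negative signed volume; flipping face orientation to outward")
    mesh$faces <- f[, c(1L, 3L, 2L), drop = FALSE]
  } else if (vol == 0) {
    stop("signed enclosed volume is zero: mesh does not bound a solid")
  }
  mesh
}

#' Total surface area of a mesh
#' @param mesh a [triangle_mesh()].
#' @return total triangle area (mm^2).
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume \eqn{V = \frac16 \sum_T \langle a, b \times c\rangle};
#' positive under the outward-normal convention.
#'
#' @param mesh a [triangle_mesh()].
#' @return signed volume (mm^3).
#' @export
enclosed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  cr <- cbind(b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L],
              b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L],
              b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
  sum(a * cr) / 6
}

#' Apply a similarity transform to a mesh
#'
#' Maps every vertex `x` to `scale * R %*% x + t`; connectivity is unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param rotation 3 x 3 orthonormal matrix (checked to 1e-10).
#' @param translation length-3 numeric vector (mm).
#' @param scale positive scalar.
#' @return the transformed [triangle_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(dim(rotation), c(3L, 3L))))
    stop("`rotation` must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("`rotation` is not orthonormal within 1e-10")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a positive scalar")
  v <- mesh$vertices %*% t(rotation) * scale
  v <- sweep(v, 2L, as.numeric(translation), "+")
  mesh$vertices <- v
  ## a proper rotation preserves orientation; reflections are rejected above
  ## only if non-orthonormal, so guard against det = -1 flipping the volume
  if (det(rotation) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

## z-extent helpers: depth is measured down from the top plane (z = zmax)
mesh_z_range <- function(mesh) range(mesh$vertices[, 3L])
mesh_height <- function(mesh) diff(mesh_z_range(mesh))
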