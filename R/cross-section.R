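## Planar cross sections of the canal cavity.  Depths are measured down from
## the top plane (largest z): a section at depth d lies in the plane
## z = zmax - d.

#' Construct a cross section from an explicit boundary loop
#'
#' @param points N x 2 matrix of in-plane boundary points (mm), ordered
#'   around the loop (either orientation; stored counter-clockwise).
#' @param height depth of the section below the top plane (mm).
#' @return an object of class `cross_section` with fields `height`,
#'   `boundary_points`, `area`, `perimeter`, `centroid` (polygon area
#'   centroid) and `N`.
#' @export
cross_section <- function(points, height = 0) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L)
    stop("`points` must be an N x 2 matrix with N >= 3")
  a2 <- polygon_signed_area(points)
  if (a2 < 0) {
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
    a2 <- -a2
  }
  if (a2 <= 0) stop("degenerate boundary loop with zero area")
  structure(list(height = height, boundary_points = points, area = a2,
                 perimeter = polygon_perimeter(points),
                 centroid = polygon_centroid(points), N = nrow(points)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section at depth %.3f mm: N = %d, area = %.4f mm^2, perimeter = %.4f mm>\n",
              x$height, x$N, x$area, x$perimeter))
  invisible(x)
}

polygon_signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(p) {
  pn <- p[c(seq_len(nrow(p))[-1L], 1L), , drop = FALSE]
  sum(sqrt(rowSums((pn - p)^2)))
}

polygon_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

## all closed intersection loops of the mesh with the plane z = z0,
## as 2D (x, y) polygons; segments are chained through mesh-edge keys
slice_loops <- function(mesh, z0) {
  v <- mesh$vertices
  f <- mesh$faces
  zr <- mesh_z_range(mesh)
  ## nudge off exact vertex z values for robustness
  eps <- 1e-9 * max(diff(zr), 1)
  if (any(abs(v[, 3L] - z0) < eps)) z0 <- z0 + 1.37 * eps

  s <- v[, 3L] - z0
  sf <- matrix(s[f], ncol = 3L)
  below <- sf < 0
  nb <- rowSums(below)
  cut <- which(nb == 1L | nb == 2L)
  if (length(cut) == 0L) return(list())

  loops <- list()
  segs_from <- character(0); segs_to <- character(0)
  pts <- list()
  key_of <- function(i, j) paste(min(i, j), max(i, j), sep = ":")
  ## for each cut face, the two crossed edges (order chosen so that walking
  ## from edge1 to edge2 keeps the below-plane side on a consistent hand)
  for (t in cut) {
    vid <- f[t, ]
    sv <- s[vid]
    neg <- which(sv < 0)
    if (length(neg) == 2L) {
      apex <- setdiff(1:3, neg)
    } else {
      apex <- neg
    }
    o <- c(apex, setdiff(1:3, apex))
    ## crossed edges: (apex, other1) and (apex, other2)
    i1 <- vid[apex]; j1 <- vid[o[2L]]; j2 <- vid[o[3L]]
    t1 <- s[i1] / (s[i1] - s[j1])
    t2 <- s[i1] / (s[i1] - s[j2])
    p1 <- v[i1, 1:2] + t1 * (v[j1, 1:2] - v[i1, 1:2])
    p2 <- v[i1, 1:2] + t2 * (v[j2, 1:2] - v[i1, 1:2])
    k1 <- key_of(i1, j1); k2 <- key_of(i1, j2)
    segs_from <- c(segs_from, k1); segs_to <- c(segs_to, k2)
    pts[[k1]] <- p1; pts[[k2]] <- p2
  }
  ## chain: each edge key appears in exactly two segments (manifold)
  nxt <- new.env(parent = emptyenv())
  for (i in seq_along(segs_from)) {
    a <- segs_from[i]; b <- segs_to[i]
    nxt[[a]] <- c(nxt[[a]], b)
    nxt[[b]] <- c(nxt[[b]], a)
  }
  visited <- new.env(parent = emptyenv())
  for (start in segs_from) {
    if (!is.null(visited[[start]])) next
    loop_keys <- character(0)
    cur <- start; prev <- ""
    repeat {
      visited[[cur]] <- TRUE
      loop_keys <- c(loop_keys, cur)
      nb2 <- nxt[[cur]]
      nb2 <- nb2[nb2 != prev]
      if (length(nb2) == 0L) break
      prev <- cur
      cur <- nb2[1L]
      if (cur == start) break
    }
    if (length(loop_keys) >= 3L)
      loops[[length(loops) + 1L]] <- do.call(rbind, pts[loop_keys])
  }
  loops
}

#' Extract the canal cross section at a depth below the top plane
#'
#' Intersects the mesh with the horizontal plane at depth `height` below the
#' top (z = zmax - height) and returns the boundary loop of the cavity,
#' ordered counter-clockwise viewed from above.  When the plane cuts several
#' loops (e.g. multi-canal anatomy), the largest-area loop is returned by
#' default, or the loop containing `axis_point`.
#'
#' @param mesh a [triangle_mesh()].
#' @param height depth below the top plane (mm), strictly inside the
#'   z-extent.
#' @param axis_point optional (x, y) point selecting the loop that contains
#'   it.
#' @return a [cross_section()].
#' @export
extract_cross_section <- function(mesh, height, axis_point = NULL) {
  zr <- mesh_z_range(mesh)
  H <- diff(zr)
  if (!is.finite(height) || height <= 0 || height >= H)
    stop(sprintf("range error: depth %.4g mm is not strictly inside the mesh z-extent (0, %.4g)",
                 height, H))
  z0 <- zr[2L] - height
  loops <- slice_loops(mesh, z0)
  if (length(loops) == 0L)
    stop("topology error: the section plane produced no closed loop")
  if (!is.null(axis_point)) {
    inside <- vapply(loops, function(L)
      point_in_polygon(axis_point, L), logical(1L))
    if (!any(inside))
      stop("topology error: no loop contains the supplied axis point")
    loop <- loops[[which(inside)[1L]]]
  } else {
    areas <- vapply(loops, function(L) abs(polygon_signed_area(L)), numeric(1L))
    loop <- loops[[which.max(areas)]]
  }
  cross_section(loop, height = height)
}

point_in_polygon <- function(p, poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  crossings <- (y > p[2L]) != (y[j] > p[2L])
  xints <- x[j] + (p[2L] - y[j]) / (y - y[j]) * (x - x[j])
  sum(crossings & (p[1L] < xints)) %% 2L == 1L
}
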