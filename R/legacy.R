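## Legacy slice-integration metrics: the volume / lateral-area / center
## transportation evaluation the spectral method supersedes.  The canal
## height h is divided into N equal intervals of delta = h/N; sections are
## measured at interval midpoints (second-order volume accuracy).  The
## lateral-area sum deliberately runs to N-1 and ignores the end caps,
## mirroring the legacy formula verbatim.

#' Build a stack of horizontal slices through a canal
#'
#' @param mesh a [triangle_mesh()].
#' @param N number of equal intervals (>= 2).
#' @param axis_point optional loop selector for multi-loop levels.
#' @return object of class `slice_stack`: `N`, `delta` (mm), `h`, and a
#'   data frame `slices` with per-level `height` (depth of the midpoint
#'   below the top), `area`, `perimeter`, `centroid_x`, `centroid_y`
#'   (`NA` centroid and 0 area where the plane misses the cavity).
#' @export
build_slice_stack <- function(mesh, N = 100L, axis_point = NULL) {
  N <- as.integer(N)
  if (N < 2L) stop("`N` must be >= 2")
  h <- mesh_height(mesh)
  delta <- h / N
  mids <- (seq_len(N) - 0.5) * delta
  area <- numeric(N); per <- numeric(N)
  cx <- rep(NA_real_, N); cy <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    cs <- tryCatch(extract_cross_section(mesh, mids[i], axis_point = axis_point),
                   error = function(e) NULL)
    if (!is.null(cs)) {
      area[i] <- cs$area; per[i] <- cs$perimeter
      cx[i] <- cs$centroid[1L]; cy[i] <- cs$centroid[2L]
    }
  }
  structure(list(N = N, delta = delta, h = h,
                 slices = data.frame(level = seq_len(N), height = mids,
                                     area = area, perimeter = per,
                                     centroid_x = cx, centroid_y = cy)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack: N = %d, delta = %.4f mm, h = %.4f mm, %d non-empty levels>\n",
              x$N, x$delta, x$h, sum(x$slices$area > 0)))
  invisible(x)
}

#' Legacy slice-sum lateral surface area
#'
#' `S = sum_{i=1}^{N-1} delta * l_i` --- the historical formula, including
#' its `N-1` upper limit (end caps are not counted).
#'
#' @param stack a [build_slice_stack()] result.
#' @return area (mm^2).
#' @export
total_surface_area <- function(stack) {
  l <- stack$slices$perimeter
  stack$delta * sum(l[seq_len(stack$N - 1L)])
}

#' Legacy slice-sum volume
#'
#' `V = sum_{i=1}^{N} delta * S_i`.
#'
#' @param stack a [build_slice_stack()] result.
#' @return volume (mm^3).
#' @export
total_volume <- function(stack) {
  stack$delta * sum(stack$slices$area)
}

#' Center transportation between two slice stacks
#'
#' Per-level Euclidean distance between the pre- and post-preparation canal
#' centroids, with the mean taken over levels where both loops exist.  The
#' meshes are assumed to be registered into a common frame upstream.
#'
#' @param stack_pre,stack_post [build_slice_stack()] results with equal `N`
#'   and matching heights.
#' @return list with per-level `offsets` (NA where either loop is missing),
#'   `mean` offset and the level count used.
#' @export
center_transportation <- function(stack_pre, stack_post) {
  if (stack_pre$N != stack_post$N)
    stop("slice stacks have different N")
  if (abs(stack_pre$h - stack_post$h) > 1e-6 * max(stack_pre$h, stack_post$h))
    stop("slice stacks have different heights")
  dx <- stack_post$slices$centroid_x - stack_pre$slices$centroid_x
  dy <- stack_post$slices$centroid_y - stack_pre$slices$centroid_y
  off <- sqrt(dx^2 + dy^2)
  ok <- !is.na(off)
  list(offsets = off, mean = mean(off[ok]), levels_used = sum(ok))
}

#' Export a slice stack (plus optional transportation) as CSV
#' @param stack a `slice_stack`.
#' @param path output path.
#' @param transport optional [center_transportation()] result aligned with
#'   the stack levels.
#' @return `path`, invisibly.
#' @export
write_slice_stack <- function(stack, path, transport = NULL) {
  d <- stack$slices
  if (!is.null(transport)) d$offset <- transport$offsets
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
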