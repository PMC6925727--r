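## Ideal benchmark canal: key-section selection by circularity scoring and
## lofting of the idealized surface.  The ideal model realizes the four
## preparation criteria: consistent central axis, even enlargement, minimal
## cut volume, and smooth transitions between sections.

#' Equal-area circle radius of a section
#'
#' The "ideal inner radius" of a cross section: the radius of the circle
#' with the same enclosed area, `sqrt(A / pi)`.
#'
#' @param section a [cross_section()] (or anything with an `area` field).
#' @return radius in mm.
#' @export
ideal_radius <- function(section) {
  A <- section$area
  if (!is.finite(A) || A <= 0) stop("section area must be positive")
  sqrt(A / pi)
}

#' Mean absolute radial deviation of a section boundary from its ideal circle
#'
#' \deqn{ \bar d = \frac1N \sum_{i=1}^{N} \left| \, \|p_i - c\| - r_{ideal} \right| }
#' with `c` the polygon area centroid and `r_ideal` the equal-area circle
#' radius.  Zero exactly for a circular section (up to the polygon-vs-circle
#' area gap at finite N); used to rank candidate key sections.
#'
#' @param section a [cross_section()].
#' @return nonnegative deviation (mm).
#' @export
mean_boundary_deviation <- function(section) {
  p <- section$boundary_points
  if (nrow(p) < 3L) stop("degenerate loop: need at least 3 boundary points")
  r <- sqrt(rowSums(sweep(p, 2L, section$centroid)^2))
  mean(abs(r - ideal_radius(section)))
}

#' Select the key cross sections of the ideal canal
#'
#' Splits the canal z-extent into coronal/middle/apical segments of height
#' fractions `segment_fractions`; within each segment scores the three
#' candidate sections at depths `h_seg/3 - a`, `h_seg/3`, `h_seg/3 + a`
#' below the segment top (`a = 0.05 h_seg`) by [mean_boundary_deviation()]
#' and keeps the candidate with minimum deviation.  Candidates whose
#' deviations are tied within the polygonal circularity floor
#' `(2 pi / N)^2 r_ideal` resolve to the central candidate.  Top and bottom
#' sections are taken at an inset of `edge_inset` times the total height
#' from the extremes (an exact extreme plane meets the mesh in a point).
#'
#' @param mesh a [triangle_mesh()].
#' @param segment_fractions positive coronal/middle/apical height fractions
#'   summing to 1 (default thirds).
#' @param edge_inset fractional inset for the top/bottom sections
#'   (default 0.01).
#' @param axis_point optional loop selector passed to
#'   [extract_cross_section()].
#' @return an object of class `canal_plan`: list with `sections`
#'   (`S^t`, coronal, middle, apical, `S^b`), `segment_heights`, `offsets`
#'   (the `a` values), a `deviations` 3 x 3 matrix (segment x candidate),
#'   `chosen` candidate indices, `candidate_depths`, and `height`.
#' @export
select_key_sections <- function(mesh, segment_fractions = c(1, 1, 1) / 3,
                                edge_inset = 0.01, axis_point = NULL) {
  fr <- as.numeric(segment_fractions)
  if (length(fr) != 3L || any(fr <= 0))
    stop("`segment_fractions` must be 3 positive numbers")
  if (abs(sum(fr) - 1) > 1e-9) stop("`segment_fractions` must sum to 1")
  H <- mesh_height(mesh)
  seg_h <- fr * H                             # h_c, h_m, h_a
  seg_top <- c(0, cumsum(seg_h))[1:3]         # depth of each segment's top

  dev <- matrix(NA_real_, 3L, 3L,
                dimnames = list(c("coronal", "middle", "apical"),
                                c("minus", "center", "plus")))
  depths <- dev
  secs <- vector("list", 3L)
  chosen <- integer(3L)
  for (s in 1:3) {
    a <- 0.05 * seg_h[s]
    cand_d <- seg_top[s] + seg_h[s] / 3 + c(-a, 0, a)
    cand <- vector("list", 3L)
    for (k in 1:3) {
      cand[[k]] <- tryCatch(
        extract_cross_section(mesh, cand_d[k], axis_point = axis_point),
        error = function(e)
          stop(sprintf("topology error in %s segment candidate %d: %s",
                       rownames(dev)[s], k, conditionMessage(e))))
      dev[s, k] <- mean_boundary_deviation(cand[[k]])
      depths[s, k] <- cand_d[k]
    }
    ## tie handling: deviations within the polygonal circularity floor of the
    ## minimum are ties; prefer the central candidate among them
    floorv <- (2 * pi / cand[[2L]]$N)^2 * ideal_radius(cand[[2L]])
    tied <- which(dev[s, ] <= min(dev[s, ]) + floorv)
    chosen[s] <- if (2L %in% tied) 2L else tied[which.min(dev[s, tied])]
    secs[[s]] <- cand[[chosen[s]]]
  }

  eps_d <- edge_inset * H
  s_top <- extract_cross_section(mesh, eps_d, axis_point = axis_point)
  s_bot <- extract_cross_section(mesh, H - eps_d, axis_point = axis_point)
  sections <- c(list(s_top), secs, list(s_bot))
  names(sections) <- c("top", "coronal", "middle", "apical", "bottom")
  hts <- vapply(sections, function(s) s$height, numeric(1L))
  if (any(diff(hts) <= 0))
    stop("section depths are not strictly increasing; degenerate geometry")
  structure(list(sections = sections, segment_heights = seg_h,
                 offsets = 0.05 * seg_h, deviations = dev,
                 candidate_depths = depths, chosen = chosen,
                 height = H, z_top = mesh_z_range(mesh)[2L],
                 mesh_name = mesh$name),
            class = "canal_plan")
}

#' Construct a canal plan directly from sections
#'
#' Mainly for testing and for building reference shapes: wraps five
#' [cross_section()]s (top to bottom, strictly increasing depth) into the
#' object accepted by [loft_ideal_canal()].
#'
#' @param sections list of five `cross_section`s ordered top to bottom.
#' @param z_top the z coordinate of the depth origin (default 0 means depths
#'   are -z).
#' @return a `canal_plan`.
#' @export
canal_plan <- function(sections, z_top = 0) {
  if (length(sections) != 5L) stop("a canal plan has exactly five sections")
  hts <- vapply(sections, function(s) s$height, numeric(1L))
  if (any(diff(hts) <= 0)) stop("section depths must be strictly increasing")
  names(sections) <- c("top", "coronal", "middle", "apical", "bottom")
  structure(list(sections = sections,
                 segment_heights = rep(diff(range(hts)) / 3, 3L),
                 offsets = rep(NA_real_, 3L),
                 deviations = matrix(NA_real_, 3L, 3L),
                 candidate_depths = matrix(NA_real_, 3L, 3L),
                 chosen = rep(NA_integer_, 3L),
                 height = diff(range(hts)), z_top = z_top,
                 mesh_name = "plan"),
            class = "canal_plan")
}

#' @export
print.canal_plan <- function(x, ...) {
  cat(sprintf("<canal_plan '%s': depths %s mm, chosen candidates %s>\n",
              x$mesh_name,
              paste(signif(vapply(x$sections, function(s) s$height, 1), 4),
                    collapse = ", "),
              paste(x$chosen, collapse = "/")))
  invisible(x)
}

#' Serialize a canal plan to JSON
#' @param plan a `canal_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    mesh_name = plan$mesh_name, height = plan$height,
    segment_heights = plan$segment_heights, offsets = plan$offsets,
    deviations = plan$deviations, chosen = plan$chosen,
    candidate_depths = plan$candidate_depths,
    sections = lapply(plan$sections, function(s)
      list(height = s$height, area = s$area, perimeter = s$perimeter,
           centroid = s$centroid, N = s$N,
           r_ideal = ideal_radius(s))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## resample a closed polygon to n points by arc length, starting at the
## point with azimuth closest to `phase` about the centroid
resample_loop <- function(p, n, phase = 0) {
  ctr <- polygon_centroid(p)
  m <- nrow(p)
  pn <- p[c(2:m, 1L), , drop = FALSE]
  seg <- sqrt(rowSums((pn - p)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1L]
  ## rotate the start to the vertex whose azimuth is closest to `phase`
  az <- atan2(p[, 2L] - ctr[2L], p[, 1L] - ctr[1L])
  dstart <- abs(atan2(sin(az - phase), cos(az - phase)))
  i0 <- which.min(dstart)
  ord <- c(i0:m, seq_len(i0 - 1L))
  p <- p[ord, , drop = FALSE]
  pn <- p[c(2:(m), 1L), , drop = FALSE]
  seg <- sqrt(rowSums((pn - p)^2))
  cum <- c(0, cumsum(seg))
  tgt <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  out <- matrix(0, n, 2L)
  j <- 1L
  for (k in seq_len(n)) {
    while (cum[j + 1L] < tgt[k] && j < m) j <- j + 1L
    t <- (tgt[k] - cum[j]) / max(seg[j], 1e-300)
    out[k, ] <- p[j, ] + t * (pn[j, ] - p[j, ])
  }
  out
}

#' Loft the ideal canal surface through a five-section plan
#'
#' Each key section (coronal/middle/apical) is replaced by its equal-area
#' circle centered at the section centroid (even enlargement with minimal
#' volume); the top and bottom sections keep their actual loops, resampled
#' to the ring count.  Rings are azimuthally aligned to minimize twist and
#' connected by a triangulated skin whose ring centers and radial offsets
#' are interpolated along depth with natural cubic splines (smooth
#' transitions), then capped flat at both ends.
#'
#' @param plan a [select_key_sections()] / [canal_plan()] result.
#' @param rings points per ring (>= 16, default 64).
#' @param layers_per_span interpolated layers between consecutive sections
#'   (>= 4, default 8).
#' @param circularize replace key sections by equal-area circles (default
#'   `TRUE`); `FALSE` keeps the actual resampled loops.
#' @return a closed [triangle_mesh()] of the ideal canal.
#' @export
loft_ideal_canal <- function(plan, rings = 64L, layers_per_span = 8L,
                             circularize = TRUE) {
  if (!inherits(plan, "canal_plan")) stop("`plan` must be a canal_plan")
  rings <- as.integer(rings); layers_per_span <- as.integer(layers_per_span)
  if (rings < 16L) stop("`rings` must be >= 16")
  if (layers_per_span < 4L) stop("`layers_per_span` must be >= 4")

  secs <- plan$sections
  depths <- vapply(secs, function(s) s$height, numeric(1L))
  ctrs <- t(vapply(secs, function(s) s$centroid, numeric(2L)))
  theta <- seq(0, 2 * pi, length.out = rings + 1L)[-(rings + 1L)]

  ## station rings as radial offsets about their centroid, aligned in phase.
  ## Rings are emitted so their POLYGON encloses the section's area exactly
  ## (circumradius r * sqrt(x / sin x), x = 2 pi / rings, for circles; an
  ## area-preserving rescale for resampled loops): the discrete pipeline is
  ## then self-consistent and re-lofting an ideal canal is near-idempotent.
  poly_corr <- sqrt((2 * pi / rings) / sin(2 * pi / rings))
  offsets <- array(0, dim = c(5L, rings, 2L))
  for (i in 1:5) {
    s <- secs[[i]]
    key <- i %in% 2:4
    if (key && circularize) {
      r <- ideal_radius(s) * poly_corr
      offsets[i, , ] <- cbind(r * cos(theta), r * sin(theta))
    } else {
      rp <- resample_loop(s$boundary_points, rings, phase = 0)
      off <- sweep(rp, 2L, s$centroid)
      a_rs <- abs(polygon_signed_area(rp))
      off <- off * sqrt(s$area / a_rs)
      offsets[i, , ] <- off
    }
  }

  ## sample depth stations: each span shares its endpoints so the section
  ## planes are reproduced exactly.  The skin is extended (natural-spline
  ## linear extrapolation) over the small top/bottom insets back to the full
  ## canal extent [0, height], so re-lofting an already-lofted ideal canal
  ## reproduces (nearly) the same surface instead of shrinking it.
  zs <- list()
  span_avg <- (depths[5L] - depths[1L]) / 4
  ext_layers <- function(len) max(2L, ceiling(layers_per_span * len / span_avg))
  if (depths[1L] > 1e-12 * plan$height) {
    d <- seq(0, depths[1L], length.out = ext_layers(depths[1L]) + 1L)
    zs[[length(zs) + 1L]] <- d[-length(d)]
  }
  for (sp in 1:4) {
    d <- seq(depths[sp], depths[sp + 1L], length.out = layers_per_span + 1L)
    zs[[length(zs) + 1L]] <- d[-length(d)]
  }
  zs[[length(zs) + 1L]] <- depths[5L]
  if (plan$height - depths[5L] > 1e-12 * plan$height) {
    d <- seq(depths[5L], plan$height, length.out = ext_layers(plan$height - depths[5L]) + 1L)
    zs[[length(zs) + 1L]] <- d[-1L]
  }
  dall <- unlist(zs)
  nlay <- length(dall)

  ## natural cubic spline interpolation of centers and offsets along depth
  interp <- function(y) stats::spline(depths, y, xout = dall,
                                      method = "natural")$y
  cx <- interp(ctrs[, 1L]); cy <- interp(ctrs[, 2L])
  V <- matrix(0, nlay * rings, 3L)
  for (j in seq_len(rings)) {
    ox <- interp(offsets[, j, 1L])
    oy <- interp(offsets[, j, 2L])
    idx <- (seq_len(nlay) - 1L) * rings + j
    V[idx, ] <- cbind(cx + ox, cy + oy, plan$z_top - dall)
  }

  idx <- function(k, j) (k - 1L) * rings + ((j - 1L) %% rings) + 1L
  F <- vector("list", nlay - 1L)
  j <- seq_len(rings)
  for (k in seq_len(nlay - 1L)) {
    F[[k]] <- rbind(cbind(idx(k, j), idx(k + 1L, j), idx(k + 1L, j + 1L)),
                    cbind(idx(k, j), idx(k + 1L, j + 1L), idx(k, j + 1L)))
  }
  F <- do.call(rbind, F)
  top_ctr <- c(cx[1L], cy[1L], plan$z_top - dall[1L])
  bot_ctr <- c(cx[nlay], cy[nlay], plan$z_top - dall[nlay])
  V <- rbind(V, top_ctr, bot_ctr)
  itop <- nlay * rings + 1L; ibot <- nlay * rings + 2L
  Ftop <- cbind(rep(itop, rings), idx(1L, j), idx(1L, j + 1L))
  Fbot <- cbind(rep(ibot, rings), idx(nlay, j + 1L), idx(nlay, j))

  mesh <- tryCatch(
    triangle_mesh(V, rbind(F, Ftop, Fbot),
                  name = paste0(plan$mesh_name, "_ideal"),
                  fix_orientation = FALSE),
    error = function(e)
      stop("geometry error: lofted surface is not a valid closed mesh (",
           conditionMessage(e), ")"))
  mesh
}

#' End-to-end ideal canal construction
#'
#' Convenience wrapper: [select_key_sections()] then [loft_ideal_canal()].
#'
#' @inheritParams select_key_sections
#' @inheritParams loft_ideal_canal
#' @return list with `mesh` (the ideal canal) and `plan`.
#' @export
ideal_canal <- function(mesh, segment_fractions = c(1, 1, 1) / 3,
                        rings = 64L, layers_per_span = 8L,
                        circularize = TRUE, edge_inset = 0.01,
                        axis_point = NULL) {
  plan <- select_key_sections(mesh, segment_fractions,
                              edge_inset = edge_inset,
                              axis_point = axis_point)
  list(mesh = loft_ideal_canal(plan, rings = rings,
                               layers_per_span = layers_per_span,
                               circularize = circularize),
       plan = plan)
}
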