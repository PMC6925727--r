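## Deterministic fixture generators: analytic solids for oracles and
## parametric synthetic root-canal meshes.  All generators are bitwise
## deterministic in their arguments (and seed, where randomness is used).

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Geodesic icosphere
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected onto
#' the sphere of the given radius.  `20 * 4^k` faces, Euler characteristic 2.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions integer in 0..6.
#' @return a [triangle_mesh()].
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3L) {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L || subdivisions > 6L)
    stop("`subdivisions` must be in 0..6")
  if (radius <= 0) stop("`radius` must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    ekey <- character(0)
    midx <- integer(0)
    newv <- list()
    mid_of <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_of[[key]]
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      newv[[length(newv) + 1L]] <<- m
      id <- nrow(v) + length(newv)
      mid_of[[key]] <- id
      id
    }
    fnew <- matrix(0L, nrow = 4L * nf, ncol = 3L)
    for (t in seq_len(nf)) {
      a <- f[t, 1L]; b <- f[t, 2L]; c <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      fnew[4L * t - 3L, ] <- c(a, ab, ca)
      fnew[4L * t - 2L, ] <- c(b, bc, ab)
      fnew[4L * t - 1L, ] <- c(c, ca, bc)
      fnew[4L * t, ]      <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- fnew
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f, name = sprintf("icosphere_r%g_s%d", radius, subdivisions))
}

## Shared tube builder: stations along the axis from top (z = height) to
## bottom (z = 0); `radius_fun(t, theta)` gives the local radius (t in [0,1]
## measured down from the top), `center_fun(t)` the (x, y) axis position.
## Caps are triangle fans around cap-centre vertices.  When the bottom
## radius collapses below `apex_tol` the bottom cap degenerates to an apex.
build_tube <- function(height, rings, layers, radius_fun, center_fun,
                       name = "tube") {
  if (height <= 0) stop("height must be positive")
  rings <- as.integer(rings); layers <- as.integer(layers)
  if (rings < 8L) stop("`rings` must be >= 8")
  if (layers < 2L) stop("`layers` must be >= 2")
  tset <- seq(0, 1, length.out = layers + 1L)
  theta <- seq(0, 2 * pi, length.out = rings + 1L)[-(rings + 1L)]
  nv <- (layers + 1L) * rings
  v <- matrix(0, nrow = nv, ncol = 3L)
  for (k in seq_len(layers + 1L)) {
    t <- tset[k]
    ctr <- center_fun(t)
    r <- radius_fun(t, theta)
    if (any(r <= 0)) stop("geometry error: non-positive tube radius")
    row0 <- (k - 1L) * rings
    v[row0 + seq_len(rings), ] <- cbind(ctr[1L] + r * cos(theta),
                                        ctr[2L] + r * sin(theta),
                                        height * (1 - t))
  }
  idx <- function(k, j) (k - 1L) * rings + ((j - 1L) %% rings) + 1L
  f <- vector("list", layers)
  for (k in seq_len(layers)) {
    j <- seq_len(rings)
    ## outward orientation: CCW seen from outside the tube wall
    quad1 <- cbind(idx(k, j), idx(k + 1L, j), idx(k + 1L, j + 1L))
    quad2 <- cbind(idx(k, j), idx(k + 1L, j + 1L), idx(k, j + 1L))
    f[[k]] <- rbind(quad1, quad2)
  }
  f <- do.call(rbind, f)
  ## caps: top (z = height, t = 0) faces +z, bottom faces -z
  top_ctr <- c(center_fun(0), height)
  bot_ctr <- c(center_fun(1), 0)
  v <- rbind(v, top_ctr, bot_ctr)
  itop <- nv + 1L; ibot <- nv + 2L
  j <- seq_len(rings)
  ftop <- cbind(rep(itop, rings), idx(1L, j), idx(1L, j + 1L))
  fbot <- cbind(rep(ibot, rings), idx(layers + 1L, j + 1L), idx(layers + 1L, j))
  triangle_mesh(v, rbind(f, ftop, fbot), name = name)
}

#' Capped cylinder fixture
#' @param radius,height dimensions in mm.
#' @param rings azimuthal resolution (>= 8).
#' @param layers vertical resolution (>= 2).
#' @return a [triangle_mesh()].
#' @export
make_cylinder <- function(radius = 1, height = 1, rings = 64L, layers = 8L) {
  if (radius <= 0) stop("`radius` must be positive")
  build_tube(height, rings, layers,
             radius_fun = function(t, th) rep(radius, length(th)),
             center_fun = function(t) c(0, 0),
             name = sprintf("cylinder_r%g_h%g", radius, height))
}

#' Capped cone fixture (apex down, canal-like taper)
#'
#' Radius decreases linearly from `top_radius` at the top (z = `height`) to
#' a small residual tip radius at the bottom, so the mesh stays a valid
#' closed manifold; the analytic section radius at depth `d` below the top
#' is `top_radius * (1 - d/height)` away from the tip neighbourhood.
#'
#' @param top_radius radius at the coronal end (mm).
#' @param height cone height (mm).
#' @param rings,layers resolution.
#' @param tip_fraction residual tip radius as a fraction of `top_radius`
#'   (default 0.01; an exact apex would create degenerate faces).
#' @return a [triangle_mesh()].
#' @export
make_cone <- function(top_radius = 1, height = 1, rings = 64L, layers = 16L,
                      tip_fraction = 0.01) {
  if (top_radius <= 0) stop("`top_radius` must be positive")
  if (tip_fraction <= 0 || tip_fraction >= 1)
    stop("`tip_fraction` must be in (0, 1)")
  build_tube(height, rings, layers,
             radius_fun = function(t, th)
               rep(pmax(top_radius * (1 - t), top_radius * tip_fraction),
                   length(th)),
             center_fun = function(t) c(0, 0),
             name = sprintf("cone_r%g_h%g", top_radius, height))
}

#' Parameter set for the synthetic canal generator
#'
#' Defaults describe a realistic single-rooted canal: 12 mm long, tapering
#' from a 1.2 mm coronal radius to a 0.35 mm apical radius, with a gently
#' curved axis, a handful of wall bumps (un-instrumented ledges/debris) and
#' small radial surface noise emulating segmentation roughness.
#'
#' @param height canal length (mm).
#' @param top_radius,bottom_radius coronal/apical radii (mm); the canal must
#'   taper apically (`bottom_radius <= top_radius`).
#' @param axis_curvature lateral sinusoid amplitude of the axis (mm).
#' @param bump_amplitude radial amplitude of Gaussian wall bumps (mm).
#' @param bump_count number of bumps.
#' @param noise_sd sd of i.i.d. radial jitter (mm); clamped to 10% of the
#'   local radius.
#' @param rings,layers mesh resolution.
#' @param seed integer RNG seed; identical params + seed give a bitwise
#'   identical mesh.
#' @return a list of class `synth_canal_params`.
#' @export
synth_canal_params <- function(height = 12, top_radius = 1.2,
                               bottom_radius = 0.35, axis_curvature = 0.6,
                               bump_amplitude = 0.15, bump_count = 6L,
                               noise_sd = 0.02, rings = 48L, layers = 60L,
                               seed = 42L) {
  if (top_radius <= 0 || bottom_radius <= 0) stop("radii must be positive")
  if (bottom_radius > top_radius)
    stop("canals taper apically: `bottom_radius` must be <= `top_radius`")
  if (height <= 0) stop("`height` must be positive")
  if (bump_amplitude < 0 || noise_sd < 0)
    stop("`bump_amplitude` and `noise_sd` must be >= 0")
  structure(list(height = height, top_radius = top_radius,
                 bottom_radius = bottom_radius,
                 axis_curvature = axis_curvature,
                 bump_amplitude = bump_amplitude,
                 bump_count = as.integer(bump_count),
                 noise_sd = noise_sd, rings = as.integer(rings),
                 layers = as.integer(layers), seed = as.integer(seed)),
            class = "synth_canal_params")
}

#' Synthetic root-canal mesh
#'
#' A tube of linearly tapering radius along a laterally curved axis, with
#' `bump_count` smooth (C2) Gaussian radial bumps at seeded locations and
#' i.i.d. radial noise, capped and closed.  Deterministic in the seed.
#'
#' @param params a [synth_canal_params()] (or arguments forwarded to it).
#' @param ... forwarded to [synth_canal_params()] when `params` is missing.
#' @return a [triangle_mesh()].
#' @export
make_synthetic_canal <- function(params = synth_canal_params(...), ...) {
  p <- params
  if (!inherits(p, "synth_canal_params")) stop("`params` must be synth_canal_params")
  with_seed(p$seed, {
    ## seeded bump locations (axial position away from the caps, azimuth)
    tb <- if (p$bump_count > 0L) stats::runif(p$bump_count, 0.12, 0.88) else numeric(0)
    thb <- if (p$bump_count > 0L) stats::runif(p$bump_count, 0, 2 * pi) else numeric(0)
    st <- 0.05                      # axial Gaussian width (fraction of length)
    sth <- 0.45                     # azimuthal width (radians)
    noise <- matrix(stats::rnorm((p$layers + 1L) * p$rings), nrow = p$layers + 1L)

    radius_fun <- function(t, theta) {
      r0 <- p$top_radius + (p$bottom_radius - p$top_radius) * t
      r <- rep(r0, length(theta))
      for (b in seq_along(tb)) {
        dth <- atan2(sin(theta - thb[b]), cos(theta - thb[b]))
        r <- r + p$bump_amplitude *
          exp(-((t - tb[b]) / st)^2 - (dth / sth)^2)
      }
      k <- round(t * p$layers) + 1L         # layer index for the noise draw
      sd_eff <- min(p$noise_sd, 0.1 * r0)
      r + sd_eff * noise[k, ]
    }
    center_fun <- function(t) c(p$axis_curvature * sin(pi * t), 0)
    build_tube(p$height, p$rings, p$layers, radius_fun, center_fun,
               name = sprintf("synth_canal_seed%d", p$seed))
  })
}

#' Pre/post preparation canal pair
#'
#' `post` shares the axis and seed of `pre`, with the radius field enlarged
#' uniformly and bump/noise amplitudes multiplied by `smoothing` (1 keeps
#' them, 0 removes them) -- emulating even mechanical enlargement.
#'
#' @param params_pre a [synth_canal_params()] describing the untreated canal.
#' @param enlargement uniform radial enlargement (mm, >= 0).
#' @param smoothing multiplier in `[0, 1]` applied to bump and noise
#'   amplitudes of the prepared canal.
#' @return list with `pre` and `post` [triangle_mesh()]es and their params.
#' @export
make_canal_pair <- function(params_pre = synth_canal_params(),
                            enlargement = 0.25, smoothing = 0.2) {
  if (enlargement < 0) stop("`enlargement` must be >= 0")
  if (smoothing < 0 || smoothing > 1) stop("`smoothing` must be in [0, 1]")
  p <- params_pre
  q <- p
  q$top_radius <- p$top_radius + enlargement
  q$bottom_radius <- p$bottom_radius + enlargement
  q$bump_amplitude <- p$bump_amplitude * smoothing
  q$noise_sd <- p$noise_sd * smoothing
  pre <- make_synthetic_canal(p)
  post <- make_synthetic_canal(q)
  post$name <- paste0(pre$name, "_prepared")
  list(pre = pre, post = post, params_pre = p, params_post = q)
}

#' Write a fixture manifest next to a generated mesh
#' @param params a [synth_canal_params()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
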