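# Shared fixtures, built in code and memoised so expensive BEM solves are
# reused across test files (test_dir runs all files in one session).

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

fx_tetra <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f, name = "tetra")
}

fx_cube <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),    # z = 0
    c(5, 6, 8), c(5, 8, 7),    # z = side
    c(1, 2, 6), c(1, 6, 5),    # y = 0
    c(3, 7, 8), c(3, 8, 4),    # y = side
    c(1, 5, 7), c(1, 7, 3),    # x = 0
    c(2, 4, 8), c(2, 8, 6))    # x = side
  triangle_mesh(v, f, name = "cube")
}

fx_ico <- function(sub) fx(paste0("ico", sub), function() make_icosphere(1, sub))

fx_ops_ico <- function(sub) fx(paste0("ops_ico", sub), function()
  assemble_operators(fx_ico(sub)))

fx_spec_ico <- function(sub, m = 13L) fx(paste0("spec_ico", sub, "_", m), function()
  solve_steklov(fx_ops_ico(sub), m = m))

# coarse synthetic canal used across BEM-level tests (kept small on purpose;
# generator defaults are finer -- see the methods vignette on test scaling)
fx_canal_params <- function(bump_amplitude = 0.15, noise_sd = 0, seed = 11L,
                            rings = 32L, layers = 40L)
  synth_canal_params(bump_amplitude = bump_amplitude, noise_sd = noise_sd,
                     seed = seed, rings = rings, layers = layers)

fx_canal <- function() fx("canal", function() make_synthetic_canal(fx_canal_params()))

fx_area_spectrum <- function(mesh, key, m = 24L) fx(key, function()
  normalize_spectrum(solve_steklov(assemble_operators(mesh), m = m), "area"))

fx_ssd_to_ideal <- function(mesh, key, l = 20L, rings = 32L) fx(key, function() {
  ic <- ideal_canal(mesh, rings = rings)
  spm <- fx_area_spectrum(mesh, paste0(key, "_specM"))
  spi <- fx_area_spectrum(ic$mesh, paste0(key, "_specI"))
  w <- eigenvalue_weights(
    curvature_histogram(gaussian_curvature(mesh), l = l),
    curvature_histogram(gaussian_curvature(ic$mesh), l = l), l = l)
  list(ssd = ssd(spm, spi, w, l = l)$value, ideal = ic$mesh,
       spec_M = spm, spec_I = spi)
})

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

max_rel_err <- function(x, ref) max(abs(x - ref) / abs(ref))

# closed-form ball spectrum reference: eigenvalue k with multiplicity 2k+1
ball_reference <- function(n_nonzero = 9L) {
  ref <- unlist(lapply(1:10, function(k) rep(k, 2 * k + 1)))
  ref[seq_len(n_nonzero)]
}
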