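#' End-to-end preparation quality evaluation
#'
#' The full workflow: build the ideal benchmark canal from the prepared
#' model, compute both Steklov spectra, the curvature-weighted SSD between
#' the prepared canal and its ideal, and the legacy slice metrics
#' (volume/area differences pre vs post, center transportation).
#'
#' @param pre,post [triangle_mesh()]es of the canal before and after
#'   preparation, registered into a common frame.
#' @param l number of compared eigenvalues (default 20).
#' @param m eigenpairs to compute (default `l + 10`).
#' @param normalization `"area"` (default; scale-invariant) or `"raw"`.
#' @param weight_scheme passed to [eigenvalue_weights()].
#' @param quadrature_order passed to [assemble_operators()].
#' @param segment_fractions passed to [select_key_sections()].
#' @param slice_N legacy slice count (default 100).
#' @param rings,layers_per_span lofting resolution.
#' @return a list report: `ssd` (prepared vs its ideal), `ssd_pre_post`,
#'   legacy `volume`/`area`/`transportation` blocks, the `plan`, and the
#'   parameters used.
#' @export
evaluate_preparation <- function(pre, post, l = 20L, m = l + 10L,
                                 normalization = c("area", "raw"),
                                 weight_scheme = "curvature-histogram",
                                 quadrature_order = 5L,
                                 segment_fractions = c(1, 1, 1) / 3,
                                 slice_N = 100L, rings = 48L,
                                 layers_per_span = 8L) {
  normalization <- match.arg(normalization)
  ic <- ideal_canal(post, segment_fractions = segment_fractions,
                    rings = rings, layers_per_span = layers_per_span)

  spec_of <- function(mesh) {
    sp <- solve_steklov(assemble_operators(mesh, quadrature_order), m = m)
    if (normalization == "area") normalize_spectrum(sp, "area") else sp
  }
  sp_post <- spec_of(post)
  sp_ideal <- spec_of(ic$mesh)
  sp_pre <- spec_of(pre)

  wts <- function(a, b) {
    if (weight_scheme == "curvature-histogram") {
      eigenvalue_weights(curvature_histogram(gaussian_curvature(a), l = l),
                         curvature_histogram(gaussian_curvature(b), l = l),
                         l = l, scheme = weight_scheme)
    } else eigenvalue_weights(l = l, scheme = weight_scheme)
  }
  ssd_ideal <- ssd(sp_post, sp_ideal, wts(post, ic$mesh), l = l)
  ssd_pp <- ssd(sp_pre, sp_post, wts(pre, post), l = l)

  st_pre <- build_slice_stack(pre, slice_N)
  st_post <- build_slice_stack(post, slice_N)
  trans <- center_transportation(st_pre, st_post)

  list(ssd = ssd_ideal$value,
       ssd_pre_post = ssd_pp$value,
       ssd_detail = ssd_ideal,
       volume = list(pre = enclosed_volume(pre), post = enclosed_volume(post),
                     diff = enclosed_volume(post) - enclosed_volume(pre),
                     legacy_pre = total_volume(st_pre),
                     legacy_post = total_volume(st_post)),
       area = list(pre = surface_area(pre), post = surface_area(post),
                   diff = surface_area(post) - surface_area(pre),
                   legacy_pre = total_surface_area(st_pre),
                   legacy_post = total_surface_area(st_post)),
       transportation = trans,
       plan = ic$plan,
       ideal_mesh = ic$mesh,
       params = list(l = l, m = m, normalization = normalization,
                     weight_scheme = weight_scheme,
                     quadrature_order = quadrature_order,
                     segment_fractions = segment_fractions,
                     slice_N = slice_N, rings = rings,
                     layers_per_span = layers_per_span,
                     schema_version = "1.0"))
}
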