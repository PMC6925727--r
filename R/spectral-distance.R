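## Spectral shape distances between Steklov spectra: naive Euclidean,
## Kac i^-1 weighting, and the Gaussian-curvature-histogram weighting that
## defines the SSD.  The zero mode lambda_0 is always excluded: it is
## shape-independent and only injects numerical noise.

#' Plain Euclidean distance between two eigenvalue sequences
#'
#' `|| (lambda_1..lambda_l) - (mu_1..mu_l) ||_2`, excluding the zero mode.
#'
#' @param lambda,mu numeric eigenvalue sequences (ascending, starting at the
#'   zero mode), each with at least `l + 1` entries.
#' @param l number of compared eigenvalues.
#' @return nonnegative distance.
#' @export
euclidean_spectral_distance <- function(lambda, mu, l) {
  l <- as.integer(l)
  if (length(lambda) < l + 1L || length(mu) < l + 1L)
    stop("need at least l + 1 eigenvalues in both sequences (lambda_0 is excluded)")
  sqrt(sum((lambda[2:(l + 1L)] - mu[2:(l + 1L)])^2))
}

#' Area-weighted histogram of absolute Gaussian curvature
#'
#' Histogram of `|K(x)|` weighted by vertex area over `l` bins spanning
#' `[0, q95]`, where `q95` is the 95th area-weighted percentile of `|K|`;
#' the top bin absorbs the clipped tail (guarding against curvature blow-up
#' at sliver triangles).  Fractions sum to 1.
#'
#' @param field a [gaussian_curvature()] result.
#' @param l number of bins (>= 2).
#' @param signed histogram the signed curvature instead of `|K|` (then the
#'   range is symmetric about 0); default `FALSE`.
#' @return list with `fractions`, `breaks`, and the clip value `k_max`.
#' @export
curvature_histogram <- function(field, l = 50L, signed = FALSE) {
  l <- as.integer(l)
  if (l < 2L) stop("`l` must be >= 2")
  k <- if (signed) field$K else abs(field$K)
  w <- field$A / sum(field$A)
  ord <- order(k)
  cw <- cumsum(w[ord])
  k_max <- k[ord][min(which(cw >= 0.95))]
  if (!signed) {
    k_min <- 0
  } else {
    k_min <- -k_max
    k_max <- max(abs(k_max), 1e-300)
  }
  if (k_max <= k_min) k_max <- k_min + 1e-12 + abs(k_min) * 1e-12
  breaks <- seq(k_min, k_max, length.out = l + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), l)          # clipped tails land in the end bins
  fr <- numeric(l)
  agg <- rowsum(w, group = bin, reorder = TRUE)
  fr[as.integer(rownames(agg))] <- agg
  list(fractions = fr, breaks = breaks, k_max = k_max)
}

#' Eigenvalue weights for the spectral distance
#'
#' `uniform`: `w_i = 1/l`.  `kac`: `w_i` proportional to `1/i`.
#' `curvature-histogram` (default, the SSD weighting): bin `i` of the
#' averaged curvature histograms of the two shapes (ascending curvature) is
#' mapped to eigenvalue rank `i` (ascending frequency) --- low-frequency
#' eigenvalues carry the global geometry, high-frequency ones the local
#' detail, so detail-heavy (high-curvature) surfaces up-weight the
#' high-frequency end --- with a floor `1/(10 l)` preventing zero weights.
#' All schemes are normalized to sum 1.
#'
#' @param hist_M,hist_N per-bin area fractions (length `l`) from
#'   [curvature_histogram()]; ignored for `uniform`/`kac`.
#' @param l number of compared eigenvalues.
#' @param scheme `"curvature-histogram"`, `"uniform"` or `"kac"`.
#' @return object of class `spectral_weights`: list with `weights`, `l`,
#'   `scheme` and histogram metadata.
#' @export
eigenvalue_weights <- function(hist_M = NULL, hist_N = NULL, l = 50L,
                               scheme = c("curvature-histogram", "uniform",
                                          "kac")) {
  scheme <- match.arg(scheme)
  l <- as.integer(l)
  if (l < 1L) stop("`l` must be >= 1")
  if (scheme == "uniform") {
    w <- rep(1 / l, l)
    meta <- NULL
  } else if (scheme == "kac") {
    w <- 1 / seq_len(l)
    w <- w / sum(w)
    meta <- NULL
  } else {
    fm <- if (is.list(hist_M)) hist_M$fractions else hist_M
    fn <- if (is.list(hist_N)) hist_N$fractions else hist_N
    if (is.null(fm) || is.null(fn)) stop("curvature-histogram scheme needs both histograms")
    if (length(fm) != l || length(fn) != l)
      stop("histogram length must equal `l`")
    w <- 0.5 * (fm + fn) + 1 / (10 * l)
    w <- w / sum(w)
    meta <- list(hist_M = fm, hist_N = fn,
                 breaks_M = if (is.list(hist_M)) hist_M$breaks else NULL,
                 breaks_N = if (is.list(hist_N)) hist_N$breaks else NULL)
  }
  structure(list(weights = w, l = l, scheme = scheme, histograms = meta),
            class = "spectral_weights")
}

#' @export
print.spectral_weights <- function(x, ...) {
  cat(sprintf("<spectral_weights: l = %d, scheme = %s, sum = %g>\n",
              x$l, x$scheme, sum(x$weights)))
  invisible(x)
}

#' Steklov spectrum distance (SSD) between two shapes
#'
#' \deqn{ SSD = \sqrt{ \sum_{i=1}^{l} w_i (\lambda_i - \mu_i)^2 } }
#' with ascending eigenvalues, the zero mode excluded, and weights from
#' [eigenvalue_weights()].  Symmetric in its arguments when the weights are
#' built from the symmetric histogram average.
#'
#' @param spec_M,spec_N [solve_steklov()] results (same normalization mode).
#' @param weights a [eigenvalue_weights()] result; when `NULL`, the
#'   curvature-histogram weights are computed from the two parent meshes.
#' @param l number of compared eigenvalues (defaults to the weight length,
#'   or `min(m) - 1`).
#' @return object of class `ssd_result`: list with `value`, `weights`,
#'   eigenvalue vectors and the normalization mode.
#' @export
ssd <- function(spec_M, spec_N, weights = NULL, l = NULL) {
  if (!inherits(spec_M, "steklov_spectrum") || !inherits(spec_N, "steklov_spectrum"))
    stop("`spec_M` and `spec_N` must be steklov_spectrum objects")
  if (!identical(spec_M$normalization, spec_N$normalization))
    stop("normalization mode mismatch: comparing raw to area-normalized spectra is meaningless")
  if (is.null(l))
    l <- if (!is.null(weights)) weights$l
         else min(length(spec_M$eigenvalues), length(spec_N$eigenvalues)) - 1L
  l <- as.integer(l)
  if (length(spec_M$eigenvalues) < l + 1L || length(spec_N$eigenvalues) < l + 1L)
    stop("need at least l + 1 eigenvalues in both spectra")
  if (is.null(weights)) {
    if (is.null(spec_M$mesh) || is.null(spec_N$mesh))
      stop("deserialized spectra lack meshes: supply `weights` explicitly")
    hM <- curvature_histogram(gaussian_curvature(spec_M$mesh), l = l)
    hN <- curvature_histogram(gaussian_curvature(spec_N$mesh), l = l)
    weights <- eigenvalue_weights(hM, hN, l = l)
  }
  if (weights$l != l) stop("weight length mismatch with `l`")
  dl <- spec_M$eigenvalues[2:(l + 1L)] - spec_N$eigenvalues[2:(l + 1L)]
  structure(list(value = sqrt(sum(weights$weights * dl^2)),
                 weights = weights, l = l,
                 normalization = spec_M$normalization,
                 mesh_M = spec_M$mesh_name, mesh_N = spec_N$mesh_name,
                 eigenvalues_M = spec_M$eigenvalues[seq_len(l + 1L)],
                 eigenvalues_N = spec_N$eigenvalues[seq_len(l + 1L)]),
            class = "ssd_result")
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(sprintf("<ssd: %s vs %s (%s, l = %d, %s weights): %.6g>\n",
              x$mesh_M, x$mesh_N, x$normalization, x$l,
              x$weights$scheme, x$value))
  invisible(x)
}
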