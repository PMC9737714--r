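# Orthogonal Daubechies DWT with periodized boundaries. Scaling (lowpass
# synthesis) filters are the standard published Daubechies constants; the
# highpass filter is the quadrature mirror g[k] = (-1)^k h[L-1-k].

.daubechies <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
          0.0033357252854737712)
)

#' Wavelet configuration
#' @param wavelet_name mother wavelet identifier (one of `"db1"`, `"db2"`,
#'   `"db4"`, `"db5"`; default `"db5"`).
#' @param levels decomposition depth (default 4).
#' @return a `wavelet_config` object.
#' @export
wavelet_config <- function(wavelet_name = "db5", levels = 4L) {
  if (!wavelet_name %in% names(.daubechies)) {
    stop("unknown wavelet '", wavelet_name, "'; available: ",
         paste(names(.daubechies), collapse = ", "))
  }
  if (levels < 1) stop("levels must be >= 1")
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels)),
            class = "wavelet_config")
}

wavelet_filters <- function(name) {
  h <- .daubechies[[name]]
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g, L = L)
}

# One analysis step of the periodized orthogonal DWT. Odd lengths are evened
# out by repeating the last sample (recorded so synthesis can undo it).
dwt_step <- function(x, flt) {
  odd <- length(x) %% 2L == 1L
  if (odd) x <- c(x, x[length(x)])
  N <- length(x)
  M <- N %/% 2L
  a <- numeric(M); d <- numeric(M)
  base <- 2L * (seq_len(M) - 1L)
  for (k in seq_len(flt$L)) {
    xs <- x[((base + k - 1L) %% N) + 1L]
    a <- a + flt$h[k] * xs
    d <- d + flt$g[k] * xs
  }
  list(a = a, d = d, odd = odd)
}

idwt_step <- function(a, d, flt, odd) {
  M <- length(a)
  N <- 2L * M
  x <- numeric(N)
  base <- 2L * (seq_len(M) - 1L)
  for (k in seq_len(flt$L)) {
    p <- ((base + k - 1L) %% N) + 1L
    x[p] <- x[p] + flt$h[k] * a + flt$g[k] * d
  }
  if (odd) x <- x[-N]
  x
}

#' Multi-level discrete wavelet transform (periodized, orthogonal)
#'
#' @param x numeric vector of samples.
#' @param cfg a [wavelet_config()].
#' @return An object of class `dwt_coeffs`: `approx` (deepest-level
#'   approximation), `details` (list of detail coefficient vectors, level 1 =
#'   finest first), `odd` (per-level length bookkeeping) and `cfg`.
#' @export
dwt <- function(x, cfg = wavelet_config()) {
  flt <- wavelet_filters(cfg$wavelet_name)
  min_len <- 2^cfg$levels
  if (length(x) < max(flt$L, min_len)) {
    stop("signal too short for a ", cfg$levels, "-level ", cfg$wavelet_name,
         " decomposition")
  }
  details <- vector("list", cfg$levels)
  odd <- logical(cfg$levels)
  a <- x
  for (l in seq_len(cfg$levels)) {
    st <- dwt_step(a, flt)
    details[[l]] <- st$d
    odd[l] <- st$odd
    a <- st$a
  }
  structure(list(approx = a, details = details, odd = odd, cfg = cfg),
            class = "dwt_coeffs")
}

#' Inverse multi-level discrete wavelet transform
#' @param coeffs a `dwt_coeffs` object from [dwt()].
#' @return numeric vector, the reconstructed signal.
#' @export
idwt <- function(coeffs) {
  flt <- wavelet_filters(coeffs$cfg$wavelet_name)
  a <- coeffs$approx
  for (l in rev(seq_along(coeffs$details))) {
    a <- idwt_step(a, coeffs$details[[l]], flt, coeffs$odd[l])
  }
  a
}

#' Universal threshold
#'
#' The universal (Donoho-Johnstone style) shrinkage threshold
#' `T = sigma * sqrt(2 * ln(R))` used on level-wise detail coefficients, with
#' `sigma` the standard deviation of the coefficients at that level and `R`
#' the number of samples of the signal.
#'
#' @param sigma_l coefficient standard deviation (>= 0).
#' @param R sample count (>= 1).
#' @return the threshold value.
#' @export
#' @examples
#' universal_threshold(2, 100)  # 2 * sqrt(2 * log(100))
universal_threshold <- function(sigma_l, R) {
  if (any(sigma_l < 0)) stop("sigma_l must be >= 0")
  if (any(R < 1)) stop("R must be >= 1")
  sigma_l * sqrt(2 * log(R))
}

#' Soft thresholding
#'
#' Shrinkage operator `sign(c) * max(|c| - T, 0)` applied elementwise.
#'
#' @param coeffs numeric vector of coefficients.
#' @param T_l threshold (>= 0).
#' @return shrunk coefficients, same length.
#' @export
#' @examples
#' soft_threshold(c(3, -3, 0), 1)  # 2 -2 0
soft_threshold <- function(coeffs, T_l) {
  if (T_l < 0) stop("T_l must be >= 0")
  sign(coeffs) * pmax(abs(coeffs) - T_l, 0)
}

#' Decompose a signal and soft-threshold its detail coefficients
#'
#' Runs the DWT to `cfg$levels` levels and shrinks each detail level with its
#' own universal threshold `sigma_l * sqrt(2 * ln(R))`, where `R` is the
#' signal's sample count and `sigma_l` estimates the noise scale of that
#' level's coefficients. Approximation coefficients are left untouched.
#'
#' The noise scale must come from an estimator that the signal itself does
#' not inflate, or the threshold destroys the very features the filtering is
#' meant to keep. The default (`sigma = "mad_finest"`) is the classical
#' choice: the robust median-absolute-deviation estimate (`MAD / 0.6745`) of
#' the finest detail level, applied to every level. It is robust both to
#' sparse transients (seizure bursts) and to sustained band-limited rhythms
#' leaking into coarser detail levels. Two per-level estimators are kept for
#' comparison: `"mad"` (per-level MAD) and `"sd"` (per-level standard
#' deviation); the latter annihilates any strong component at its own level
#' because the component inflates its own threshold.
#'
#' @param x numeric vector of samples.
#' @param cfg a [wavelet_config()].
#' @param sigma noise-scale estimator: `"mad_finest"` (default), `"mad"`,
#'   or `"sd"`.
#' @return a `dwt_coeffs` object with thresholded details; the applied
#'   thresholds are stored in the `thresholds` field.
#' @export
decompose_denoise <- function(x, cfg = wavelet_config(),
                              sigma = c("mad_finest", "mad", "sd")) {
  sigma <- match.arg(sigma)
  co <- dwt(x, cfg)
  R <- length(x)
  thr <- numeric(length(co$details))
  s_finest <- stats::mad(co$details[[1]], center = 0)
  for (l in seq_along(co$details)) {
    d <- co$details[[l]]
    s <- switch(sigma,
                mad_finest = s_finest,
                mad = stats::mad(d, center = 0),
                sd = sd(d))
    if (is.na(s)) s <- 0
    thr[l] <- universal_threshold(s, R)
    co$details[[l]] <- soft_threshold(d, thr[l])
  }
  co$thresholds <- thr
  co
}

#' Wavelet soft-threshold denoising
#'
#' Convenience wrapper: [decompose_denoise()] followed by reconstruction.
#'
#' @inheritParams decompose_denoise
#' @return denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, cfg = wavelet_config()) {
  idwt(decompose_denoise(x, cfg))
}
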