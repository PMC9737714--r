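#' Band definition
#' @param name band name.
#' @param f_low,f_high band edges in Hz.
#' @return a one-row band data.frame compatible with [eeg_bands()].
#' @export
band_definition <- function(name, f_low, f_high) {
  if (!(f_low >= 0 && f_high > f_low)) stop("need 0 <= f_low < f_high")
  data.frame(name = name, f_low = f_low, f_high = f_high, stringsAsFactors = FALSE)
}

#' Per-segment, per-band power spectral density
#'
#' One-sided rectangular-window periodogram of one analysis segment at the
#' native resolution `fs / N` Hz, restricted to a frequency band. The PSD is
#' scaled so that `sum(psd) * fs / N` over the full grid equals the segment's
#' mean square value (a Parseval-consistent density). The band's average
#' spectral power `ps_avg` is the mean PSD over the retained bins.
#'
#' @param segment numeric vector of samples (one analysis window).
#' @param fs sampling frequency in Hz.
#' @param band one-row band data.frame (see [band_definition()], [eeg_bands()]).
#' @param segment_index optional index for bookkeeping.
#' @return An object of class `band_spectrum` with fields `band`, `freqs`,
#'   `psd`, `ps_avg`, `segment_index`.
#' @export
compute_psd <- function(segment, fs, band, segment_index = NA_integer_) {
  n <- length(segment)
  if (n < 1) stop("empty segment")
  if (band$f_high > fs / 2 + 1e-9) {
    stop("band edge ", band$f_high, " Hz exceeds Nyquist (", fs / 2, " Hz)")
  }
  X <- fft(segment)
  p <- (Mod(X)^2) / (n * fs)
  half <- seq_len(n %/% 2 + 1)
  p1 <- p[half]
  # double interior bins (all but DC and, for even n, Nyquist)
  interior <- seq_along(p1) > 1 & (seq_along(p1) < length(p1) | n %% 2 == 1)
  p1[interior] <- 2 * p1[interior]
  freqs <- (half - 1) * fs / n
  keep <- freqs >= band$f_low - 1e-9 & freqs <= band$f_high + 1e-9
  structure(list(band = band, freqs = freqs[keep], psd = p1[keep],
                 ps_avg = mean(p1[keep]), segment_index = segment_index),
            class = "band_spectrum")
}

#' Average spectral power
#'
#' Arithmetic mean of a power spectral density sequence over its grid.
#'
#' @param psd numeric vector of non-negative densities.
#' @return the mean density.
#' @export
#' @examples
#' average_spectral_power(c(1, 1, 5, 1, 5))  # 2.6
average_spectral_power <- function(psd) {
  if (length(psd) < 1) stop("empty psd")
  mean(psd)
}

#' Spectral verge of a band spectrum
#'
#' The spectral verge (SV) is the highest frequency point whose PSD strictly
#' exceeds the band's average spectral power. When no bin exceeds the average
#' (e.g. a perfectly flat spectrum) the verge is undefined and a sentinel
#' (`frequency = NA`, `valid = FALSE`) is returned.
#'
#' @param spectrum a `band_spectrum` from [compute_psd()], or a list with
#'   `freqs`, `psd` and optionally `ps_avg`.
#' @return An object of class `spectral_verge`: `frequency` (Hz or `NA`),
#'   `valid`, and `candidate_set` (all frequencies passing the condition).
#' @export
spectral_verge <- function(spectrum) {
  avg <- spectrum$ps_avg %||% average_spectral_power(spectrum$psd)
  ms <- spectrum$freqs[spectrum$psd > avg]
  if (length(ms) == 0) {
    structure(list(frequency = NA_real_, valid = FALSE, candidate_set = numeric(0)),
              class = "spectral_verge")
  } else {
    structure(list(frequency = max(ms), valid = TRUE, candidate_set = ms),
              class = "spectral_verge")
  }
}
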