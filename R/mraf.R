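#' Standard EEG frequency bands
#'
#' Default band edges used throughout the pipeline: delta 0.5-4, theta 4-8,
#' alpha 8-13, beta 13-30 Hz; gamma runs from 30 Hz to Nyquist so that
#' high-frequency oscillations (> 120 Hz at clinical sampling rates) stay
#' inside it, and the full band spans 0.5 Hz to Nyquist.
#'
#' @param fs sampling frequency in Hz.
#' @return data.frame with columns `name`, `f_low`, `f_high`.
#' @export
eeg_bands <- function(fs) {
  nyq <- fs / 2
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma", "full"),
    f_low = c(0.5, 4, 8, 13, 30, 0.5),
    f_high = c(4, 8, 13, 30, nyq, nyq),
    stringsAsFactors = FALSE
  )
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth filtered forward and backward (zero phase) so the
#' output stays sample-aligned with annotations. A band reaching Nyquist is
#' realized as a high-pass; a band starting at 0 as a low-pass.
#'
#' @param x numeric vector of samples.
#' @param fs sampling frequency in Hz.
#' @param f_low,f_high band edges in Hz (`0 <= f_low < f_high <= fs/2`).
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, f_low, f_high) {
  nyq <- fs / 2
  if (f_low < 0 || f_high <= f_low) stop("need 0 <= f_low < f_high")
  if (f_high > nyq + 1e-9) stop("band edge ", f_high, " Hz is outside Nyquist (", nyq, " Hz)")
  at_nyq <- f_high >= nyq * (1 - 1e-6)
  at_zero <- f_low <= 0
  flt <- if (at_nyq && at_zero) {
    return(x)
  } else if (at_nyq) {
    signal::butter(4, f_low / nyq, type = "high")
  } else if (at_zero) {
    signal::butter(4, f_high / nyq, type = "low")
  } else {
    signal::butter(4, c(f_low, f_high) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(flt, x))
}

#' Multiresolution adaptive filtering (MRAF)
#'
#' Artifact-attenuating pre-processing for a single EEG channel. The signal
#' is wavelet-denoised (DWT, per-level universal soft thresholding), then for
#' each frequency band an adaptive FIR filter (normalized LMS) is run with
#' the band-passed raw signal as reference input and the band-passed denoised
#' reconstruction as desired signal. The adaptive filter output per band is
#' the MRAF output: it tracks genuine band-limited activity (including
#' seizure bursts, which survive thresholding) while transient artifacts are
#' attenuated.
#'
#' @param x numeric vector, single-channel samples.
#' @param fs sampling frequency in Hz.
#' @param cfg a [wavelet_config()] (default db5, 4 levels).
#' @param bands band table as from [eeg_bands()]; defaults to `eeg_bands(fs)`.
#' @param order adaptive filter tap count (default 8).
#' @param mu NLMS step size in (0, 1] (default 0.1).
#' @return An object of class `band_signals`: a named list of per-band output
#'   signals (each the length of `x`), with attributes `fs` and `bands`.
#' @export
mraf_filter <- function(x, fs, cfg = wavelet_config(), bands = NULL,
                        order = 8L, mu = 0.1) {
  if (order < 1) stop("order must be >= 1")
  if (mu <= 0 || mu > 1) stop("mu must be in (0, 1]")
  if (is.null(bands)) bands <- eeg_bands(fs)
  denoised <- wavelet_denoise(x, cfg)
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    ref <- bandpass_filter(x, fs, bands$f_low[i], bands$f_high[i])
    des <- bandpass_filter(denoised, fs, bands$f_low[i], bands$f_high[i])
    out[[i]] <- nlms_filter(ref, des, as.integer(order), mu)
  }
  structure(out, fs = fs, bands = bands, class = "band_signals")
}

#' @export
print.band_signals <- function(x, ...) {
  cat(sprintf("<band_signals> %s; %d samples @ %g Hz\n",
              paste(names(x), collapse = ", "), length(x[[1]]), attr(x, "fs")))
  invisible(x)
}

#' Band power of a signal via the periodogram
#'
#' Total power of `x` in the band `[f_low, f_high]`, integrated from the
#' one-sided periodogram. Used as an oracle in tests and for localization
#' summaries.
#'
#' @inheritParams bandpass_filter
#' @return power (signal units squared).
#' @export
band_power <- function(x, fs, f_low, f_high) {
  sp <- compute_psd(x, fs, band_definition("custom", f_low, f_high))
  df <- fs / length(x)
  sum(sp$psd) * df
}
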