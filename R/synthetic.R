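# 21-channel 10-20 montage labels.
montage_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                  "T3", "C3", "Cz", "C4", "T4",
                  "T5", "P3", "Pz", "P4", "T6", "O1", "O2", "A1", "A2")

#' Synthetic EEG generator configuration
#'
#' Parameters of the ground-truth EEG simulator: a pink (1/f) background with
#' a 10 Hz alpha rhythm on every channel, amplitude-modulated high-frequency
#' (HFO-like) sinusoidal bursts on focal channels during configured seizure
#' intervals, and biphasic 1-3 Hz blink-like transients on frontal channels.
#'
#' @param n_channels channel count (default 21, the 10-20 montage).
#' @param fs sampling frequency in Hz (default 400, so that a 130 Hz burst
#'   is well inside Nyquist).
#' @param duration_s record length in seconds.
#' @param seizure_intervals list of `list(start_s, end_s, channels)` entries;
#'   `channels` is a character vector of focal channels.
#' @param hfo_freq_hz burst carrier frequency (default 130; must be < fs/2).
#' @param hfo_amplitude_ratio burst peak amplitude divided by background RMS
#'   (default 3).
#' @param pink_exponent exponent of the 1/f^a background (default 1).
#' @param pink_rms background pink-noise RMS in microvolts (default 10).
#' @param alpha_amplitude alpha-rhythm RMS in microvolts (default 20).
#' @param artifact_rate blink events per minute on frontal channels (default 4).
#' @param artifact_amplitude blink peak amplitude in microvolts (default 100).
#' @param channel_names montage labels (defaults to the first `n_channels`
#'   of the 10-20 set).
#' @param rng_seed integer seed, or `NULL`.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_channels = 21L, fs = 400, duration_s = 60,
                             seizure_intervals = list(),
                             hfo_freq_hz = 130, hfo_amplitude_ratio = 3,
                             pink_exponent = 1, pink_rms = 10,
                             alpha_amplitude = 20,
                             artifact_rate = 4, artifact_amplitude = 100,
                             channel_names = NULL, rng_seed = NULL) {
  if (hfo_freq_hz >= fs / 2) stop("hfo_freq_hz must be below Nyquist (fs/2)")
  if (is.null(channel_names)) {
    channel_names <- if (n_channels <= length(montage_1020)) {
      montage_1020[seq_len(n_channels)]
    } else paste0("ch", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels) stop("channel_names length mismatch")
  for (iv in seizure_intervals) {
    if (iv$start_s < 0 || iv$end_s <= iv$start_s || iv$end_s > duration_s) {
      stop("seizure interval outside the recording")
    }
    bad <- setdiff(iv$channels, channel_names)
    if (length(bad)) stop("focal channel(s) not in montage: ", paste(bad, collapse = ", "))
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, seizure_intervals = seizure_intervals,
                 hfo_freq_hz = hfo_freq_hz,
                 hfo_amplitude_ratio = hfo_amplitude_ratio,
                 pink_exponent = pink_exponent, pink_rms = pink_rms,
                 alpha_amplitude = alpha_amplitude,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 channel_names = channel_names, rng_seed = rng_seed),
            class = "synthetic_config")
}

# 1/f^a noise via spectral shaping of white noise, scaled to a target RMS.
pink_noise <- function(n, exponent, rms) {
  w <- rnorm(n)
  W <- fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)                 # two-sided frequency magnitude
  f[f == 0] <- 1                      # avoid dividing by zero at DC
  W <- W / f^(exponent / 2)
  x <- Re(fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

# Tapered-cosine (Tukey) window: cosine ramps over a `taper` fraction at each
# end, flat in between. Used as the seizure-burst envelope so that annotated
# intervals carry appreciable activity over their whole labeled extent.
tukey_window <- function(n, taper = 0.2) {
  u <- seq(0, 1, length.out = n)
  env <- rep(1, n)
  a <- taper
  lo <- u < a
  hi <- u > 1 - a
  env[lo] <- 0.5 * (1 - cos(pi * u[lo] / a))
  env[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / a))
  env
}

# Biphasic blink-like transient: derivative-of-Gaussian pulse, dominant
# energy between 1 and 3 Hz, peak amplitude `amp`.
blink_pulse <- function(fs, amp, width_s = 0.15) {
  tt <- seq(-3 * width_s, 3 * width_s, by = 1 / fs)
  p <- -tt / width_s * exp(-tt^2 / (2 * width_s^2))
  amp * p / max(abs(p))
}

#' Generate a synthetic multichannel EEG recording
#'
#' Produces an [eeg_recording()] with known ground truth: every channel gets
#' pink-noise background plus a 10 Hz alpha rhythm (random phase per
#' channel); during each configured seizure interval the focal channels
#' additionally receive a Hann-enveloped sinusoidal burst at `hfo_freq_hz`
#' whose peak amplitude is `hfo_amplitude_ratio` times the background RMS;
#' blink artifacts land on frontal channels at the configured rate. The
#' returned annotations are exactly the configured intervals and channels.
#'
#' @param cfg a [synthetic_config()].
#' @return an [eeg_recording()] with ground-truth annotations.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$rng_seed, {
    n <- as.integer(round(cfg$duration_s * cfg$fs))
    tt <- (seq_len(n) - 1) / cfg$fs
    bg_rms <- sqrt(cfg$pink_rms^2 + cfg$alpha_amplitude^2)
    data <- matrix(0, nrow = cfg$n_channels, ncol = n)
    for (ci in seq_len(cfg$n_channels)) {
      ph <- runif(1, 0, 2 * pi)
      data[ci, ] <- pink_noise(n, cfg$pink_exponent, cfg$pink_rms) +
        cfg$alpha_amplitude * sqrt(2) * sin(2 * pi * 10 * tt + ph)
    }
    rownames(data) <- cfg$channel_names
    for (iv in cfg$seizure_intervals) {
      i0 <- time_to_sample(iv$start_s, cfg$fs) + 1L
      i1 <- min(time_to_sample(iv$end_s, cfg$fs), n)
      idx <- i0:i1
      # ~2 s onset/offset ramps (capped for very short events): seizure
      # bursts switch on quickly relative to their annotated duration
      taper <- min(0.2, 2 / (iv$end_s - iv$start_s))
      env <- tukey_window(length(idx), taper = taper)
      amp <- cfg$hfo_amplitude_ratio * bg_rms
      for (ch in iv$channels) {
        ph <- runif(1, 0, 2 * pi)
        data[ch, idx] <- data[ch, idx] +
          amp * env * sin(2 * pi * cfg$hfo_freq_hz * tt[idx] + ph)
      }
    }
    frontal <- intersect(c("Fp1", "Fp2", "F7", "F8"), cfg$channel_names)
    if (length(frontal) && cfg$artifact_rate > 0) {
      n_blinks <- rpois(1, cfg$artifact_rate * cfg$duration_s / 60)
      pulse <- blink_pulse(cfg$fs, cfg$artifact_amplitude)
      half <- length(pulse) %/% 2
      for (b in seq_len(n_blinks)) {
        center <- sample.int(n, 1)
        ch <- sample(frontal, 1)
        lo <- max(1L, center - half)
        hi <- min(n, center + (length(pulse) - half - 1L))
        data[ch, lo:hi] <- data[ch, lo:hi] + pulse[(lo - center + half + 1L):(hi - center + half + 1L)]
      }
    }
    ann <- lapply(cfg$seizure_intervals, function(iv) {
      seizure_annotation(iv$start_s, iv$end_s, iv$channels)
    })
    eeg_recording(data, cfg$fs, cfg$channel_names, ann)
  })
}

#' Standard small fixture suite
#'
#' Writes three deterministic EDF records (plus annotation sidecars) used by
#' tests and examples: (a) a clean 2-channel record without seizures, (b) a
#' 21-channel record of 79,200 samples at 400 Hz with one seizure from
#' 5.15 s to 37.2075 s focal on T3/T4, and (c) an artifact-heavy 21-channel
#' record at 250 Hz with a 100 Hz burst (below that rate's Nyquist).
#'
#' @param seed base RNG seed.
#' @param dir output directory (default a session temp directory).
#' @return named list of EDF paths (`clean`, `subject1`, `artifact`).
#' @export
make_fixture_suite <- function(seed, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  rec_a <- generate_recording(synthetic_config(
    n_channels = 2L, fs = 250, duration_s = 40, artifact_rate = 0,
    hfo_freq_hz = 100, channel_names = c("C3", "C4"), rng_seed = seed))
  write_edf(rec_a, p("clean.edf"))
  rec_b <- generate_recording(synthetic_config(
    n_channels = 21L, fs = 400, duration_s = 198,
    seizure_intervals = list(list(start_s = 5.15, end_s = 37.2075,
                                  channels = c("T3", "T4"))),
    rng_seed = seed + 1L))
  write_edf(rec_b, p("subject1.edf"))
  rec_c <- generate_recording(synthetic_config(
    n_channels = 21L, fs = 250, duration_s = 60, hfo_freq_hz = 100,
    seizure_intervals = list(list(start_s = 20, end_s = 40,
                                  channels = c("T3", "T4"))),
    artifact_rate = 30, rng_seed = seed + 2L))
  write_edf(rec_c, p("artifact.edf"))
  list(clean = p("clean.edf"), subject1 = p("subject1.edf"),
       artifact = p("artifact.edf"))
}
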