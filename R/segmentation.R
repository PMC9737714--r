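#' Convert a time in seconds to a sample index
#'
#' Maps an annotation time to a 0-based sample index as `round(t * fs)`,
#' rounding half away from zero. For a record sampled at 400 Hz an onset at
#' 5.15 s lands on sample 2060.
#'
#' @param t time in seconds (>= 0); vectorized.
#' @param fs sampling frequency in Hz (> 0).
#' @return integer sample index (0-based).
#' @export
#' @examples
#' time_to_sample(5.15, 400)    # 2060
#' time_to_sample(37.2075, 400) # 14883
time_to_sample <- function(t, fs) {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  as.integer(floor(t * fs + 0.5))
}

#' Split a recording into fixed-length analysis windows
#'
#' Sliding-window segmentation of the record into windows of `window_s`
#' seconds with `overlap_s` seconds of overlap. With no overlap the segment
#' count is `floor(n / (fs * window_s))`; any trailing partial window is
#' discarded.
#'
#' @param recording an [eeg_recording()], or an integer sample count if `fs`
#'   is given.
#' @param window_s window length in seconds (default 4).
#' @param overlap_s overlap between consecutive windows in seconds (default 0;
#'   must be < `window_s`).
#' @param fs sampling frequency, only needed when `recording` is a raw sample
#'   count.
#' @return An object of class `segment_set`: fields `window_s`, `overlap_s`,
#'   `fs`, `k` (segment count) and `bounds`, a `k x 2` integer matrix of
#'   0-based half-open `[start, end)` sample bounds.
#' @export
#' @examples
#' seg <- segment_signal(79200L, window_s = 4, fs = 400)
#' seg$k  # 49
segment_signal <- function(recording, window_s = 4, overlap_s = 0, fs = NULL) {
  if (inherits(recording, "eeg_recording")) {
    n <- n_samples(recording)
    fs <- recording$fs
  } else {
    n <- as.integer(recording)
    if (is.null(fs)) stop("fs must be supplied when `recording` is a sample count")
  }
  if (!(window_s > overlap_s && overlap_s >= 0)) stop("need window_s > overlap_s >= 0")
  w <- as.integer(round(window_s * fs))
  step <- as.integer(round((window_s - overlap_s) * fs))
  if (w < 1 || step < 1) stop("window too short for this sampling rate")
  if (w > n) stop("window longer than the signal")
  k <- (n - w) %/% step + 1L
  starts <- (seq_len(k) - 1L) * step
  bounds <- cbind(start = starts, end = starts + w)
  structure(list(window_s = window_s, overlap_s = overlap_s, fs = fs,
                 n = n, k = k, bounds = bounds),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %g s (overlap %g s) @ %g Hz\n",
              x$k, x$window_s, x$overlap_s, x$fs))
  invisible(x)
}

#' Extract one segment of a signal
#' @param x numeric vector (single-channel samples).
#' @param segments a `segment_set`.
#' @param i segment index (1-based).
#' @return numeric vector of `window_s * fs` samples.
#' @export
segment_samples <- function(x, segments, i) {
  b <- segments$bounds[i, ]
  x[(b[1] + 1L):b[2]]
}

#' Assign seizure labels to segments, per channel
#'
#' A segment is labeled seizure (1) for a channel when its temporal overlap
#' with any annotation covering that channel is at least
#' `min_overlap_fraction * window_s` seconds. Annotations with an empty
#' channel set cover all channels.
#'
#' @param segments a `segment_set`.
#' @param annotations list of [seizure_annotation()] objects.
#' @param channel_names channel labels defining the label matrix columns.
#' @param min_overlap_fraction fraction of the window that must be covered,
#'   in (0, 1] (default 0.5).
#' @return integer matrix, `k` segments x channels, of 0/1 labels.
#' @export
label_segments <- function(segments, annotations, channel_names,
                           min_overlap_fraction = 0.5) {
  if (!(min_overlap_fraction > 0 && min_overlap_fraction <= 1)) {
    stop("min_overlap_fraction must be in (0, 1]")
  }
  k <- segments$k
  fs <- segments$fs
  lab <- matrix(0L, nrow = k, ncol = length(channel_names),
                dimnames = list(NULL, channel_names))
  need <- min_overlap_fraction * segments$window_s
  seg_start <- segments$bounds[, 1] / fs
  seg_end <- segments$bounds[, 2] / fs
  for (a in annotations) {
    ov <- pmin(seg_end, a$end_s) - pmax(seg_start, a$start_s)
    hit <- ov >= need - 1e-12
    cols <- if (length(a$channels)) a$channels else channel_names
    cols <- intersect(cols, channel_names)
    lab[hit, cols] <- 1L
  }
  lab
}
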