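#' Multichannel EEG recording
#'
#' Container for a multichannel scalp EEG record: a channels x samples matrix
#' of microvolt values, its sampling frequency, ordered channel labels
#' (10-20 system) and any seizure annotations.
#'
#' @param data numeric matrix, channels in rows, samples in columns (microvolts).
#' @param fs sampling frequency in Hz (positive scalar).
#' @param channel_names character vector of channel labels, one per row of
#'   `data`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param annotations list of [seizure_annotation()] objects.
#'
#' @return An object of class `eeg_recording` with fields `data`, `fs`,
#'   `channel_names` and `annotations`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), nrow = 2), fs = 250)
#' n_samples(rec)
eeg_recording <- function(data, fs, channel_names = NULL, annotations = list()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data), nrow(data) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  dur <- ncol(data) / fs
  for (a in annotations) {
    if (!inherits(a, "seizure_annotation")) stop("annotations must be seizure_annotation objects")
    if (a$end_s > dur + 1e-9) stop("annotation extends past the end of the recording")
    unknown <- setdiff(a$channels, channel_names)
    if (length(unknown)) stop("annotation references unknown channel(s): ",
                              paste(unknown, collapse = ", "))
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = as.character(channel_names),
                 annotations = annotations),
            class = "eeg_recording")
}

#' Seizure annotation
#'
#' A single annotated seizure event: start/end in seconds and the channels it
#' applies to. An empty channel set means the event applies to every channel
#' (the convention used by corpus-style per-record label files).
#'
#' @param start_s event onset in seconds (>= 0).
#' @param end_s event end in seconds (> `start_s`).
#' @param channels character vector of channel labels; empty = all channels.
#' @param label free-text category, e.g. `"seiz"`.
#' @return An object of class `seizure_annotation`.
#' @export
seizure_annotation <- function(start_s, end_s, channels = character(), label = "seiz") {
  if (!is.numeric(start_s) || start_s < 0) stop("start_s must be >= 0")
  if (!is.numeric(end_s) || end_s <= start_s) stop("end_s must be > start_s")
  structure(list(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                 channels = as.character(channels), label = as.character(label)),
            class = "seizure_annotation")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              length(x$annotations)))
  invisible(x)
}

#' Number of samples per channel
#' @param recording an [eeg_recording()].
#' @return integer sample count.
#' @export
n_samples <- function(recording) ncol(recording$data)

#' Keep a subset of channels
#' @param recording an [eeg_recording()].
#' @param channels character vector of channel labels to keep, in the given order.
#' @return an [eeg_recording()] restricted to `channels`; annotations are kept,
#'   with their channel lists intersected with the selection.
#' @export
select_channels <- function(recording, channels) {
  missing_ch <- setdiff(channels, recording$channel_names)
  if (length(missing_ch)) stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
  ann <- lapply(recording$annotations, function(a) {
    if (length(a$channels) == 0) return(a)
    kept <- intersect(a$channels, channels)
    if (length(kept) == 0) return(NULL)
    seizure_annotation(a$start_s, a$end_s, kept, a$label)
  })
  ann <- ann[!vapply(ann, is.null, logical(1))]
  eeg_recording(recording$data[channels, , drop = FALSE], recording$fs, channels, ann)
}
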