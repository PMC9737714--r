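# Minimal European Data Format (EDF) reader/writer, 16-bit samples.
# Covers the subset used for scalp EEG exchange: one common sampling rate,
# continuous records, physical/digital linear scaling. Annotations travel in a
# plain-text CSV sidecar ("<record>_annotations.csv") with columns
# start_s, end_s, channels (';'-separated, empty = all), label.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Annotation sidecar path for an EDF file
#' @param path path to an EDF file.
#' @return the path of the associated annotation CSV.
#' @export
annotation_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_annotations.csv")
}

#' Write seizure annotations to a CSV sidecar
#' @param annotations list of [seizure_annotation()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  df <- data.frame(
    start_s = vapply(annotations, `[[`, numeric(1), "start_s"),
    end_s = vapply(annotations, `[[`, numeric(1), "end_s"),
    channels = vapply(annotations, function(a) paste(a$channels, collapse = ";"), character(1)),
    label = vapply(annotations, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read seizure annotations from a CSV sidecar
#' @param path annotation CSV path.
#' @return list of [seizure_annotation()] objects.
#' @export
read_annotations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(channels = "character", label = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    ch <- df$channels[i]
    ch <- if (is.na(ch) || !nzchar(ch)) character() else strsplit(ch, ";", fixed = TRUE)[[1]]
    seizure_annotation(df$start_s[i], df$end_s[i], ch, df$label[i])
  })
}

#' Write a recording to an EDF file
#'
#' Samples are linearly quantized to 16-bit integers using per-channel
#' physical min/max taken from the data, so a read-back reproduces values to
#' within one quantization step. Annotations, if present, are written to the
#' CSV sidecar next to the file (see [annotation_sidecar_path()]).
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$fs
  nc <- nrow(data)
  n <- ncol(data)
  # 1-second records when the length allows it, otherwise one long record
  if (n %% fs == 0 && abs(fs - round(fs)) < 1e-9) {
    n_rec <- n %/% fs
    spr <- as.integer(fs)
    rec_dur <- 1
  } else {
    n_rec <- 1L
    spr <- n
    rec_dur <- n / fs
  }
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate 01-JAN-2000 X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nc), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_num(rec_dur, 8), edf_pad(nc, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width), collapse = ""),
              con, eos = NULL)
  }
  field(recording$channel_names, 16)
  field(rep("", nc), 80)                     # transducer
  field(rep("uV", nc), 8)                    # physical dimension
  field(vapply(pmin_, edf_num, character(1), width = 8), 8)
  field(vapply(pmax_, edf_num, character(1), width = 8), 8)
  field(rep(dmin, nc), 8)
  field(rep(dmax, nc), 8)
  field(rep("", nc), 80)                     # prefiltering
  field(rep(spr, nc), 8)
  field(rep("", nc), 32)                     # reserved

  # re-read the header's printed physical range so scaling matches exactly
  pmin_h <- as.numeric(vapply(pmin_, edf_num, character(1), width = 8))
  pmax_h <- as.numeric(vapply(pmax_, edf_num, character(1), width = 8))
  scale_ <- (dmax - dmin) / (pmax_h - pmin_h)
  dig <- round((data - pmin_h) * scale_ + dmin)
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2, endian = "little")
  }
  if (length(recording$annotations)) {
    write_annotations_csv(recording$annotations, annotation_sidecar_path(path))
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Reads a 16-bit EDF/EDF+ file with a single common sampling rate. If an
#' annotation CSV sidecar is present (see [annotation_sidecar_path()]) its
#' events are attached to the returned recording.
#'
#' @param path path to an EDF file.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (sz < 256) stop("not an EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("not an EDF file (bad version field): ", path)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1 || is.na(n_rec) || n_rec < 1) stop("corrupt EDF header: ", path)
  if (sz < 256 + 256 * nc) stop("truncated EDF signal header: ", path)
  rdv <- function(width) vapply(seq_len(nc), function(i) trimws(readChar(con, width, useBytes = TRUE)), character(1))
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) stop("channels with differing sampling rates are not supported")
  spr1 <- spr[1]
  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (sz < expected) stop("truncated EDF data section: ", path)
  fs <- spr1 / rec_dur
  raw_all <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                     endian = "little", signed = TRUE)
  data <- matrix(0, nrow = nc, ncol = n_rec * spr1)
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- raw_all[((r - 1L) * per_rec + 1L):(r * per_rec)]
    blk <- matrix(block, nrow = spr1, ncol = nc)
    data[, ((r - 1L) * spr1 + 1L):(r * spr1)] <- t(blk)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- sweep(sweep(data, 1, dmin, "-") * gain, 1, pmin_, "+")
  side <- annotation_sidecar_path(path)
  ann <- if (file.exists(side)) read_annotations_csv(side) else list()
  eeg_recording(data, fs, labels, ann)
}
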