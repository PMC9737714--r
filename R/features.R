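# Band ordering of the CSV feature map rows.
csv_band_order <- c("alpha", "beta", "gamma", "theta", "delta", "full")

#' Build the per-channel CSV feature map
#'
#' Assembles the 6 bands x k segments matrix of critical spectral verge
#' frequencies for one channel. Rows are ordered alpha, beta, gamma, theta,
#' delta, full. Sentinel entries (no bin above the band average) are imputed
#' as 0 Hz and flagged invalid in the validity mask.
#'
#' @param band_spectra named list (one entry per band, all of
#'   `csv_band_order` required) of lists of `band_spectrum` objects, one per
#'   segment.
#' @param fpa_cfg an [fpa_config()]; its `rng_seed` (when non-`NULL`) is used
#'   to derive a distinct, reproducible sub-seed per (band, segment) cell.
#' @param channel channel name for bookkeeping.
#' @return An object of class `csv_feature_map`: `channel`, `values`
#'   (6 x k numeric, Hz), `validity` (6 x k logical), `bands`.
#' @export
build_feature_map <- function(band_spectra, fpa_cfg = fpa_config(), channel = NA_character_) {
  missing_bands <- setdiff(csv_band_order, names(band_spectra))
  if (length(missing_bands)) {
    stop("missing band(s): ", paste(missing_bands, collapse = ", "))
  }
  k <- length(band_spectra[[csv_band_order[1]]])
  values <- matrix(0, nrow = 6, ncol = k, dimnames = list(csv_band_order, NULL))
  validity <- matrix(FALSE, nrow = 6, ncol = k, dimnames = list(csv_band_order, NULL))
  for (b in seq_along(csv_band_order)) {
    specs <- band_spectra[[csv_band_order[b]]]
    if (length(specs) != k) stop("bands disagree on segment count")
    for (s in seq_len(k)) {
      cfg <- fpa_cfg
      if (!is.null(cfg$rng_seed)) cfg$rng_seed <- derive_seed(cfg$rng_seed, b, s)
      res <- compute_csv(specs[[s]], cfg)
      if (res$valid) {
        values[b, s] <- res$frequency
        validity[b, s] <- TRUE
      }
    }
  }
  structure(list(channel = channel, values = values, validity = validity,
                 bands = csv_band_order),
            class = "csv_feature_map")
}

#' @export
print.csv_feature_map <- function(x, ...) {
  cat(sprintf("<csv_feature_map> channel %s: 6 bands x %d segments\n",
              x$channel, ncol(x$values)))
  invisible(x)
}

#' Channel-pairwise CSV matrix for one band and segment
#'
#' Builds the N x N channel "connectivity" matrix at a given band and
#' segment: off-diagonal entries are absolute CSV differences between channel
#' pairs, diagonal entries the channel's own CSV. With 21 channels this is
#' the 21 x 21 per-frequency feature matrix that PCA reduces to 21 x 1.
#'
#' @param maps list of `csv_feature_map` objects, one per channel, equal `k`.
#' @param band band name (one of `csv_band_order`).
#' @param segment segment index (1-based).
#' @return N x N numeric matrix with channel names on both dimensions.
#' @export
build_channel_matrix <- function(maps, band, segment) {
  ks <- vapply(maps, function(m) ncol(m$values), integer(1))
  if (length(unique(ks)) != 1) stop("channels disagree on segment count")
  v <- vapply(maps, function(m) m$values[band, segment], numeric(1))
  M <- abs(outer(v, v, "-"))
  diag(M) <- v
  chn <- vapply(maps, `[[`, character(1), "channel")
  dimnames(M) <- list(chn, chn)
  M
}

#' PCA reduction of a channel feature matrix
#'
#' Centers the matrix column-wise and projects its rows onto the leading
#' principal components, reducing an N x N matrix to an N x
#' `n_components` score matrix (N x 1 by default). Explained-variance
#' fractions are reported for all components in descending order.
#'
#' @param matrix numeric N x N (or N x p) matrix.
#' @param n_components number of components to retain (default 1).
#' @return An object of class `reduced_features`: `vector` (scores on the
#'   first component, length N), `scores` (N x n_components),
#'   `explained_variance` (descending fractions summing to <= 1), and
#'   `degenerate` flag for zero-variance input.
#' @export
pca_reduce <- function(matrix, n_components = 1L) {
  if (n_components > ncol(matrix)) stop("n_components exceeds matrix dimension")
  tot_var <- sum(apply(matrix, 2, var))
  if (!is.finite(tot_var) || tot_var < 1e-24) {
    return(structure(list(vector = numeric(nrow(matrix)),
                          scores = matrix(0, nrow(matrix), n_components),
                          explained_variance = rep(NA_real_, n_components),
                          degenerate = TRUE),
                     class = "reduced_features"))
  }
  pr <- prcomp(matrix, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  structure(list(vector = scores[, 1], scores = scores,
                 explained_variance = ev, degenerate = FALSE),
            class = "reduced_features")
}

#' Extract CSV feature maps for every channel of a recording
#'
#' Runs the feature-extraction chain for each channel: MRAF band filtering,
#' segmentation of each band signal, per-segment periodogram, and CSV
#' computation, yielding one [build_feature_map()] result per channel.
#'
#' @param recording an [eeg_recording()].
#' @param segments a `segment_set` from [segment_signal()].
#' @param wavelet_cfg a [wavelet_config()].
#' @param fpa_cfg an [fpa_config()].
#' @param bands band table (default `eeg_bands(fs)`).
#' @param order,mu MRAF adaptive-filter parameters (see [mraf_filter()]).
#' @return named list of `csv_feature_map`, one per channel.
#' @export
extract_features <- function(recording, segments,
                             wavelet_cfg = wavelet_config(),
                             fpa_cfg = fpa_config(), bands = NULL,
                             order = 8L, mu = 0.1) {
  fs <- recording$fs
  if (is.null(bands)) bands <- eeg_bands(fs)
  maps <- vector("list", length(recording$channel_names))
  names(maps) <- recording$channel_names
  for (ci in seq_along(recording$channel_names)) {
    ch <- recording$channel_names[ci]
    bs <- mraf_filter(recording$data[ch, ], fs, wavelet_cfg, bands, order, mu)
    band_spectra <- lapply(setNames(bands$name, bands$name), function(bn) {
      bd <- bands[bands$name == bn, ]
      lapply(seq_len(segments$k), function(s) {
        compute_psd(segment_samples(bs[[bn]], segments, s), fs, bd, s)
      })
    })
    cfg <- fpa_cfg
    if (!is.null(cfg$rng_seed)) {
      # derive the channel stream from the channel *name* so that feature
      # maps are invariant to channel ordering
      cfg$rng_seed <- derive_seed(cfg$rng_seed, utf8ToInt(ch))
    }
    maps[[ci]] <- build_feature_map(band_spectra, cfg, channel = ch)
  }
  maps
}

#' Flatten feature maps into a classification feature table
#'
#' One row per (channel, segment): the six band CSVs (Hz), their validity
#' flags as 0/1 features, and, when labels are supplied, the segment's
#' seizure label for that channel.
#'
#' @param maps named list of `csv_feature_map` per channel.
#' @param labels optional k x channels 0/1 matrix from [label_segments()].
#' @return data.frame with columns `channel`, `segment`, `csv_<band>`,
#'   `valid_<band>` and optionally `label`.
#' @export
feature_table <- function(maps, labels = NULL) {
  rows <- lapply(maps, function(m) {
    k <- ncol(m$values)
    df <- data.frame(channel = rep(m$channel, k), segment = seq_len(k),
                     stringsAsFactors = FALSE)
    for (b in m$bands) df[[paste0("csv_", b)]] <- m$values[b, ]
    for (b in m$bands) df[[paste0("valid_", b)]] <- as.integer(m$validity[b, ])
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(labels)) {
    out$label <- mapply(function(ch, s) labels[s, ch], out$channel, out$segment)
  }
  out
}

#' Numeric feature matrix from a feature table
#' @param features data.frame from [feature_table()].
#' @return numeric matrix of the `csv_*` and `valid_*` columns.
#' @export
feature_matrix <- function(features) {
  cols <- grep("^(csv|valid)_", names(features), value = TRUE)
  as.matrix(features[, cols])
}
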