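#' Per-channel seizure localization scores
#'
#' Summarizes channel-wise predictions into a localization map: each
#' channel's seizure score is the fraction of its segments classified as
#' seizure, and the mean CSV per band is reported alongside. Channels are
#' returned ranked by score (ties broken by mean gamma-band CSV, then by
#' channel name for determinism), so focal channels — whose segments carry
#' the high-frequency seizure bursts — rise to the top.
#'
#' @param predictions 0/1 predicted labels, one per row of `features`.
#' @param features data.frame from [feature_table()] (columns `channel`,
#'   `segment`, `csv_<band>`).
#' @return data.frame of class `localization_map`, one row per channel,
#'   columns `channel`, `score` (in \[0, 1\]), `rank`, and `mean_csv_<band>`,
#'   ordered by decreasing score.
#' @export
localize <- function(predictions, features) {
  predictions <- as.integer(as.character(predictions))
  if (length(predictions) != nrow(features)) {
    stop("predictions must align with the feature table rows")
  }
  chans <- unique(features$channel)
  band_cols <- grep("^csv_", names(features), value = TRUE)
  rows <- lapply(chans, function(ch) {
    sel <- features$channel == ch
    out <- data.frame(channel = ch, score = mean(predictions[sel]),
                      stringsAsFactors = FALSE)
    for (bc in band_cols) out[[sub("^csv_", "mean_csv_", bc)]] <- mean(features[[bc]][sel])
    out
  })
  map <- do.call(rbind, rows)
  ord <- order(-map$score, -map$mean_csv_gamma, map$channel)
  map <- map[ord, ]
  map$rank <- seq_len(nrow(map))
  rownames(map) <- NULL
  class(map) <- c("localization_map", "data.frame")
  map
}
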