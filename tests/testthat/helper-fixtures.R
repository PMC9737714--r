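# Shared fixtures, built in code at test time.

# Small seizure recording: 21 channels, 400 Hz, one focal burst on T3/T4.
small_seizure_recording <- function(seed = 42, duration_s = 60,
                                    start_s = 10, end_s = 30,
                                    focal = c("T3", "T4"), ...) {
  generate_recording(synthetic_config(
    n_channels = 21L, fs = 400, duration_s = duration_s,
    seizure_intervals = list(list(start_s = start_s, end_s = end_s,
                                  channels = focal)),
    rng_seed = seed, ...))
}

# Two well-separated Gaussian blobs in 2-D with binary labels.
make_blobs <- function(n_per_class = 60, sep = 6, seed = 1) {
  mcsv:::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
               matrix(rnorm(2 * n_per_class, mean = sep), ncol = 2))
    list(x = x, y = rep(c(0L, 1L), each = n_per_class))
  })
}

# Random small band spectrum on an integer frequency grid.
random_spectrum <- function(n_bins, seed = NULL) {
  mcsv:::with_seed(seed, {
    psd <- rexp(n_bins)
    freqs <- seq(0, n_bins - 1)
    structure(list(band = band_definition("test", 0, n_bins - 1),
                   freqs = freqs, psd = psd, ps_avg = mean(psd),
                   segment_index = 1L),
              class = "band_spectrum")
  })
}

expect_same_report <- function(a, b) {
  expect_equal(a$counts, b$counts)
  expect_equal(a$sen, b$sen)
  expect_equal(a$spe, b$spe)
  expect_equal(a$acc, b$acc)
  expect_equal(a$folds, b$folds)
  expect_equal(a$predictions, b$predictions)
}
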