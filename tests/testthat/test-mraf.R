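test_that("universal threshold evaluates sigma * sqrt(2 ln R)", {
  expect_equal(universal_threshold(5, 1), 0)
  expect_equal(universal_threshold(0, 1000), 0)
  expect_equal(universal_threshold(2, 100), 2 * sqrt(2 * log(100)))
  expect_error(universal_threshold(1, 0), "R")
  expect_error(universal_threshold(-1, 10), "sigma")
})

test_that("soft thresholding shrinks toward zero and is odd and non-expansive", {
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-1.5, 2), 0)
  expect_equal(soft_threshold(c(3, -3, 0), 1), c(2, -2, 0))
  cs <- mcsv:::with_seed(1, rnorm(500, sd = 4))
  for (T_l in c(0, 0.5, 2, 10)) {
    expect_equal(soft_threshold(-cs, T_l), -soft_threshold(cs, T_l))
    expect_true(all(abs(soft_threshold(cs, T_l)) <= abs(cs)))
  }
  expect_error(soft_threshold(1, -1), "T_l")
})

test_that("periodized DWT reconstructs perfectly and preserves energy", {
  for (n in c(64L, 1600L, 1601L, 1000L)) {
    x <- mcsv:::with_seed(n, rnorm(n))
    for (w in c("db2", "db5")) {
      co <- dwt(x, wavelet_config(w, 4))
      expect_equal(idwt(co), x, tolerance = 1e-10)
    }
  }
  # orthogonality: coefficient energy equals signal energy (even lengths)
  x <- mcsv:::with_seed(7, rnorm(2048))
  co <- dwt(x, wavelet_config("db5", 4))
  expect_equal(sum(co$approx^2) + sum(unlist(co$details)^2), sum(x^2),
               tolerance = 1e-10)
  expect_error(dwt(rnorm(8), wavelet_config("db5", 4)), "too short")
  expect_error(wavelet_config("haar9"), "unknown wavelet")
})

test_that("wavelet denoising leaves zero signals alone and reduces noise energy", {
  z <- decompose_denoise(numeric(256))
  expect_true(all(unlist(z$details) == 0))
  expect_true(all(z$approx == 0))

  x <- mcsv:::with_seed(3, rnorm(4096))
  den <- wavelet_denoise(x)
  expect_lt(sum(den^2), sum(x^2))

  # a large isolated impulse survives (with reduced amplitude)
  imp <- numeric(1024); imp[500] <- 100
  den_imp <- wavelet_denoise(imp)
  expect_gt(max(abs(den_imp[495:505])), 10)
})

test_that("denoising never increases total coefficient energy", {
  for (s in 1:5) {
    x <- mcsv:::with_seed(s, rnorm(512) + sin(2 * pi * 0.05 * (1:512)) * s)
    co0 <- dwt(x)
    co1 <- decompose_denoise(x)
    e0 <- sum(co0$approx^2) + sum(unlist(co0$details)^2)
    e1 <- sum(co1$approx^2) + sum(unlist(co1$details)^2)
    expect_lte(e1, e0)
  }
})

test_that("NLMS adaptive filter converges to the reference when it is also the target", {
  t <- (0:3999) / 400
  x <- sin(2 * pi * 10 * t)
  y <- mcsv:::nlms_filter(x, x, 8L, 0.1)
  burn <- 801:4000
  rel_err <- sqrt(mean((y[burn] - x[burn])^2) / mean(x[burn]^2))
  expect_lt(rel_err, 1e-2)
  # zero input gives zero output in every band
  bs <- mraf_filter(numeric(2048), fs = 400)
  expect_true(all(vapply(bs, function(b) all(b == 0), logical(1))))
})

test_that("MRAF band outputs respect their pass bands", {
  t <- (0:8191) / 400
  x <- sin(2 * pi * 10 * t) + 0.05 * mcsv:::with_seed(5, rnorm(8192))
  bs <- mraf_filter(x, fs = 400)
  p_in <- band_power(x, 400, 0, 200)
  p_alpha <- band_power(bs$alpha, 400, 8, 13)
  p_gamma_total <- band_power(bs$gamma, 400, 0, 200)
  expect_gt(p_alpha / band_power(x, 400, 8, 13), 0.9)
  expect_lt(p_gamma_total / p_in, 0.01)
})

test_that("MRAF preserves seizure bursts in the gamma band", {
  rec <- small_seizure_recording(seed = 21, duration_s = 40, start_s = 12,
                                 end_s = 28, focal = "T3")
  fs <- rec$fs
  bs <- mraf_filter(rec$data["T3", ], fs)
  ictal <- (12 * fs + 1):(28 * fs)
  inter <- c(1:(10 * fs), (30 * fs + 1):(40 * fs))
  e_ictal <- mean(bs$gamma[ictal]^2)
  e_inter <- mean(bs$gamma[inter]^2)
  expect_gt(e_ictal / e_inter, 5)
})

test_that("blink-like artifacts barely perturb beta and gamma MRAF outputs", {
  fs <- 400
  base <- generate_recording(synthetic_config(
    n_channels = 1L, fs = fs, duration_s = 30, artifact_rate = 0,
    channel_names = "Fp1", rng_seed = 9))
  x <- base$data[1, ]
  # superimpose blink transients explicitly
  pulse <- mcsv:::blink_pulse(fs, 100)
  xa <- x
  for (center in c(5, 12, 19, 26) * fs) {
    idx <- center + seq_along(pulse) - length(pulse) %/% 2
    xa[idx] <- xa[idx] + pulse
  }
  b0 <- mraf_filter(x, fs)
  b1 <- mraf_filter(xa, fs)
  for (band in c("beta", "gamma")) {
    e0 <- mean(b0[[band]]^2)
    e1 <- mean(b1[[band]]^2)
    expect_lt(abs(e1 - e0) / e0, 0.05)
  }
})

test_that("band edges outside Nyquist are rejected", {
  expect_error(bandpass_filter(rnorm(100), 100, 30, 80), "Nyquist")
  expect_error(mraf_filter(rnorm(100), 100, bands = band_definition("bad", 10, 60)),
               "Nyquist")
})
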