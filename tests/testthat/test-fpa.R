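test_that("Levy steps are reproducible, scalable and heavy-tailed with index lambda", {
  cfg <- fpa_config(rng_seed = 5)
  s1 <- mcsv:::with_seed(5, levy_step(cfg, 100))
  s2 <- mcsv:::with_seed(5, levy_step(cfg, 100))
  expect_identical(s1, s2)

  cfg0 <- fpa_config(levy_scale = 0)
  expect_true(all(levy_step(cfg0, 50) == 0))

  expect_error(levy_step(fpa_config(levy_lambda = 0.5, levy_scale = 1), -1), "count")
  expect_error(fpa_config(levy_lambda = 2.5), "levy_lambda")

  # tail index: P(|L| > s) ~ s^(-lambda); log-log slope of the empirical
  # survival function over upper quantiles should be close to -lambda
  L <- mcsv:::with_seed(99, levy_step(fpa_config(levy_lambda = 0.5, levy_scale = 1), 1e5))
  a <- abs(L)
  qs <- quantile(a, probs = seq(0.99, 0.9995, length.out = 12))
  surv <- vapply(qs, function(q) mean(a > q), numeric(1))
  fit <- stats::lm(log(surv) ~ log(as.numeric(qs)))
  expect_lt(abs(unname(stats::coef(fit)[2]) - (-0.5)), 0.2)
})

test_that("FPA keeps its seed under a zero budget and respects bounds and elitism", {
  obj <- function(x) -(x - 7)^2
  cfg <- fpa_config(max_iter = 0L, bounds = c(0, 20), rng_seed = 1)
  res <- fpa_optimize(obj, 7, cfg)
  expect_equal(res$best, 7)
  expect_equal(res$n_iter, 0L)

  cfg2 <- fpa_config(population_size = 20L, max_iter = 150L, bounds = c(0, 20),
                     rng_seed = 2, stagnation = 150L)
  res2 <- fpa_optimize(obj, 19, cfg2)
  expect_true(all(diff(res2$history) >= 0))            # monotone best fitness
  expect_true(res2$best >= 0 && res2$best <= 20)
})

test_that("FPA locates the analytic maximum of a smooth objective", {
  obj <- function(x) -(x - 7)^2
  err <- vapply(1:20, function(s) {
    cfg <- fpa_config(population_size = 20L, max_iter = 200L, bounds = c(0, 20),
                      rng_seed = s, stagnation = 200L)
    abs(fpa_optimize(obj, 15, cfg)$best - 7)
  }, numeric(1))
  expect_true(all(err < 0.1))
})

test_that("FPA matches brute-force search on a discrete spectral objective", {
  psd <- c(1, 1, 5, 1, 5); freqs <- 0:4
  avg <- mean(psd)
  obj <- function(f) {
    b <- pmax(1L, pmin(5L, as.integer(round(f)) + 1L))
    ifelse(psd[b] > avg, freqs[b], -1e12)
  }
  cfg <- fpa_config(population_size = 10L, max_iter = 50L, bounds = c(0, 4),
                    rng_seed = 3)
  res <- fpa_optimize(obj, 2, cfg)
  brute <- max(freqs[psd > avg])
  expect_equal(obj(res$best), brute)
})

test_that("compute_csv equals the spectral verge by elitism and propagates sentinels", {
  sp <- random_spectrum(32, seed = 10)
  res <- compute_csv(sp, fpa_config(rng_seed = 1))
  sv <- spectral_verge(sp)
  expect_true(res$valid)
  expect_gte(res$frequency, sv$frequency)

  flat <- structure(list(freqs = 0:9, psd = rep(2, 10), ps_avg = 2),
                    class = "band_spectrum")
  res_flat <- compute_csv(flat, fpa_config(rng_seed = 1))
  expect_false(res_flat$valid)
  expect_true(is.na(res_flat$frequency))

  hand <- structure(list(freqs = 0:4, psd = c(1, 1, 5, 1, 5), ps_avg = 2.6),
                    class = "band_spectrum")
  expect_equal(compute_csv(hand, fpa_config(rng_seed = 2))$frequency, 4)
})

test_that("compute_csv is reproducible under a fixed seed and stays in bounds", {
  sp <- random_spectrum(48, seed = 77)
  r1 <- compute_csv(sp, fpa_config(rng_seed = 123))
  r2 <- compute_csv(sp, fpa_config(rng_seed = 123))
  expect_identical(r1$frequency, r2$frequency)
  expect_identical(r1$fpa$history, r2$fpa$history)
  for (s in 1:25) {
    sp <- random_spectrum(sample(3:64, 1), seed = 1000 + s)
    res <- compute_csv(sp, fpa_config(rng_seed = s))
    if (res$valid) {
      expect_true(res$frequency >= min(sp$freqs) && res$frequency <= max(sp$freqs))
    }
  }
})
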