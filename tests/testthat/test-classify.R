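test_that("classifiers fit and predict on separable data", {
  blobs <- make_blobs(seed = 2)
  m_svm <- train_classifier(blobs$x, blobs$y, "svm")
  expect_equal(mean(predict(m_svm, blobs$x) == blobs$y), 1)

  m_knn <- train_classifier(blobs$x, blobs$y, "knn", params = list(k = 1))
  expect_equal(as.integer(as.character(predict(m_knn, blobs$x))), blobs$y)

  m_km <- train_classifier(blobs$x, blobs$y, "kmeans", seed = 3)
  expect_gte(mean(predict(m_km, blobs$x) == blobs$y), 0.95)

  expect_error(train_classifier(blobs$x, rep(1, nrow(blobs$x)), "svm"),
               "2 classes")
})

test_that("confusion metrics follow their defining ratios", {
  perfect <- evaluate(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$sen, 100)
  expect_equal(perfect$spe, 100)
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$adr, 100)

  labels <- c(rep(1, 8), rep(0, 92))
  preds <- c(rep(1, 7), 0, rep(0, 90), 1, 1)
  r <- evaluate(labels, preds)
  expect_equal(unname(r$counts), c(7, 2, 90, 1))  # TP FP TN FN
  expect_equal(r$sen, 87.5)
  expect_equal(r$spe, 100 * 90 / 92, tolerance = 1e-12)
  expect_equal(r$acc, 97.0)
  expect_equal(r$adr, (87.5 + 100 * 90 / 92) / 2)
  expect_equal(round(r$adr, 3), 92.663)

  expect_error(evaluate(c(1, 0), c(1)), "length mismatch")
  # undefined ratio flagged as NA
  expect_true(is.na(evaluate(c(0, 0), c(0, 1))$sen))
})

test_that("the average detection rate is the mean of printed Sen and Spe", {
  expect_equal(average_detection_rate(93.83, 97.94), 95.885)
  expect_lt(abs(average_detection_rate(93.83, 97.94) - 95.89), 0.01)
  expect_equal(average_detection_rate(100, 0), 50)
})

test_that("metrics obey permutation and label-swap symmetries", {
  mcsv:::with_seed(8, {
    labels <- rbinom(200, 1, 0.3)
    preds <- rbinom(200, 1, 0.4)
  })
  r <- evaluate(labels, preds)
  perm <- mcsv:::with_seed(9, sample.int(200))
  rp <- evaluate(labels[perm], preds[perm])
  expect_equal(r$counts, rp$counts)

  rs <- evaluate(1 - labels, 1 - preds)
  expect_equal(rs$sen, r$spe)
  expect_equal(rs$spe, r$sen)
  expect_equal(rs$acc, r$acc)

  expect_equal(r$adr, (r$sen + r$spe) / 2)
})

test_that("cross-validation is stratified, deterministic and exact on separable data", {
  blobs <- make_blobs(n_per_class = 50, seed = 4)
  r1 <- cross_validate(blobs$x, blobs$y, "svm", n_folds = 10, seed = 11)
  r2 <- cross_validate(blobs$x, blobs$y, "svm", n_folds = 10, seed = 11)
  expect_same_report(r1, r2)
  expect_equal(r1$acc, 100)
  expect_equal(r1$adr, 100)
  # stratification: every fold holds samples of both classes
  for (f in 1:10) expect_setequal(unique(blobs$y[r1$folds == f]), c(0, 1))
  # fold metrics average to the reported aggregate
  expect_equal(mean(vapply(r1$per_fold, `[[`, numeric(1), "acc")), r1$acc)

  r3 <- cross_validate(blobs$x, blobs$y, "svm", n_folds = 10, seed = 12)
  expect_false(identical(r1$folds, r3$folds))

  few <- c(1:6, 51:56)  # 6 samples per class
  expect_error(cross_validate(blobs$x[few, ], blobs$y[few], n_folds = 10),
               "at least 10")
})

test_that("uninformative features yield accuracy near the class prior", {
  mcsv:::with_seed(31, {
    x <- matrix(rnorm(200 * 4), ncol = 4)  # independent of the labels
    y <- rep(c(0L, 1L), each = 100)
  })
  r <- cross_validate(x, y, "knn", params = list(k = 5), n_folds = 10, seed = 13)
  expect_gt(r$acc, 35)
  expect_lt(r$acc, 65)
})

test_that("localization scores are per-channel seizure fractions with ranked output", {
  ft <- data.frame(channel = rep(c("T3", "Cz", "O1"), each = 4),
                   segment = rep(1:4, 3),
                   csv_alpha = 10, csv_beta = 20, csv_gamma = rep(c(130, 90, 95), each = 4),
                   csv_theta = 6, csv_delta = 2, csv_full = 15)
  pred <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  map <- localize(pred, ft)
  expect_equal(map$channel[1], "T3")
  expect_equal(map$score[map$channel == "T3"], 1.0)
  expect_equal(map$score[map$channel == "Cz"], 0.25)
  expect_equal(map$score[map$channel == "O1"], 0)
  expect_equal(map$rank, 1:3)
  expect_equal(map$mean_csv_gamma[map$channel == "T3"], 130)

  map0 <- localize(rep(0, 12), ft)
  expect_true(all(map0$score == 0))
  expect_error(localize(c(1, 0), ft), "align")
})
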