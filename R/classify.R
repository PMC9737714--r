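#' Train a seizure/non-seizure classifier
#'
#' Fits one of three classifiers on labeled feature vectors: an RBF-kernel
#' SVM, k-nearest neighbours, or 2-class K-Means (unsupervised; clusters are
#' mapped to labels by majority vote on the training labels and prediction is
#' by nearest centroid).
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y binary labels (0/1 or factor with 2 levels).
#' @param kind one of `"svm"`, `"knn"`, `"kmeans"`.
#' @param params named list of hyperparameters. SVM: `cost` (default 1),
#'   `gamma` (default `1/ncol(x)`), `class_weights` (`"balanced"` [default],
#'   `"none"`, or a named numeric vector). k-NN: `k` (default 5). K-Means:
#'   `centers` (default 2), `nstart` (default 10).
#' @param seed optional RNG seed (K-Means restarts).
#' @return an object of class `mcsv_model` with a [predict()] method.
#' @export
train_classifier <- function(x, y, kind = c("svm", "knn", "kmeans"),
                             params = list(), seed = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- factor(y)
  if (kind != "kmeans" && nlevels(droplevels(y)) < 2) {
    stop("supervised training requires at least 2 classes")
  }
  fit <- switch(kind,
    svm = {
      cw <- params$class_weights %||% "balanced"
      weights <- if (identical(cw, "balanced")) {
        tab <- table(y)
        w <- as.numeric(sum(tab) / (length(tab) * tab))
        setNames(w, names(tab))
      } else if (identical(cw, "none")) NULL else cw
      e1071::svm(x, y, kernel = "radial",
                 cost = params$cost %||% 1,
                 gamma = params$gamma %||% (1 / ncol(x)),
                 class.weights = weights, scale = FALSE)
    },
    knn = list(train = x, cl = y, k = params$k %||% 5L),
    kmeans = with_seed(seed, {
      km <- stats::kmeans(x, centers = params$centers %||% 2L,
                          nstart = params$nstart %||% 10L)
      # majority-vote mapping cluster -> label
      map <- vapply(seq_len(nrow(km$centers)), function(cl) {
        members <- y[km$cluster == cl]
        if (length(members) == 0) levels(y)[1]
        else names(which.max(table(members)))
      }, character(1))
      list(centers = km$centers, map = map)
    })
  )
  structure(list(kind = kind, fit = fit, levels = levels(y)),
            class = "mcsv_model")
}

#' @export
predict.mcsv_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- switch(object$kind,
    svm = as.character(predict(object$fit, newdata)),
    knn = as.character(class::knn(object$fit$train, newdata, object$fit$cl,
                                  k = object$fit$k)),
    kmeans = {
      d2 <- vapply(seq_len(nrow(object$fit$centers)), function(cl) {
        rowSums(sweep(newdata, 2, object$fit$centers[cl, ])^2)
      }, numeric(nrow(newdata)))
      if (is.vector(d2)) d2 <- matrix(d2, nrow = 1)
      object$fit$map[max.col(-d2)]
    }
  )
  factor(out, levels = object$levels)
}

#' Confusion counts and detection metrics
#'
#' Compares binary predictions with reference labels, treating 1 as seizure.
#' Sensitivity is the percentage of seizure segments detected, specificity
#' the percentage of non-seizure segments kept, accuracy the overall
#' percentage correct, and the average detection rate (ADR) the mean of
#' sensitivity and specificity. A metric whose denominator is zero is `NA`.
#'
#' @param labels reference 0/1 labels.
#' @param predictions predicted 0/1 labels, same length.
#' @return An object of class `eval_report`: `counts` (TP, FP, TN, FN),
#'   `sen`, `spe`, `acc`, `adr` (percentages).
#' @export
#' @examples
#' evaluate(c(1, 1, 0, 0), c(1, 0, 0, 0))
evaluate <- function(labels, predictions) {
  labels <- as.integer(as.character(labels))
  predictions <- as.integer(as.character(predictions))
  if (length(labels) != length(predictions)) stop("length mismatch")
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / length(labels)
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sen = sen, spe = spe, acc = acc,
                 adr = average_detection_rate(sen, spe)),
            class = "eval_report")
}

#' Average detection rate
#'
#' The mean of sensitivity and specificity, on the percentage scale.
#'
#' @param sen sensitivity in percent.
#' @param spe specificity in percent.
#' @return ADR in percent (`NA` if either input is `NA`).
#' @export
#' @examples
#' average_detection_rate(93.83, 97.94)
average_detection_rate <- function(sen, spe) (sen + spe) / 2

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> Sen %.2f%%  Spe %.2f%%  Acc %.2f%%  ADR %.2f%%\n",
              x$sen, x$spe, x$acc, x$adr))
  cat(sprintf("  counts: TP %d  FP %d  TN %d  FN %d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(y, n_folds, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < n_folds) {
        stop("need at least ", n_folds, " samples per class (class ", cl,
             " has ", length(idx), ")")
      }
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Cross-validated evaluation of a classifier on CSV features
#'
#' Stratified k-fold cross-validation. Features are standardized (z-score)
#' using each training fold's statistics before fitting; zero-variance
#' columns are left unscaled. Reported aggregate metrics are the means of
#' the per-fold metrics (folds whose denominator is empty are skipped);
#' pooled confusion counts over all held-out predictions are also returned.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (0/1).
#' @param kind classifier kind, see [train_classifier()].
#' @param params hyperparameters, see [train_classifier()].
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed controlling fold assignment (and K-Means restarts).
#' @return An object of class `eval_report` with additional fields
#'   `per_fold` (list of fold reports), `folds` (assignment vector) and
#'   `predictions` (out-of-fold predicted labels, aligned with rows of `x`).
#' @export
cross_validate <- function(x, y, kind = "svm", params = list(),
                           n_folds = 10L, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(as.character(factor(y)))
  fold <- stratified_folds(y, n_folds, seed)
  oof <- integer(length(y))
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    mu_ <- colMeans(x[tr, , drop = FALSE])
    sd_ <- apply(x[tr, , drop = FALSE], 2, sd)
    sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, mu_), 2, sd_, "/")
    model <- train_classifier(xs[tr, , drop = FALSE], y[tr], kind, params,
                              seed = if (is.null(seed)) NULL else seed + f)
    pred <- predict(model, xs[!tr, , drop = FALSE])
    oof[!tr] <- as.integer(as.character(pred))
    per_fold[[f]] <- evaluate(y[!tr], oof[!tr])
  }
  agg <- function(field) {
    v <- vapply(per_fold, `[[`, numeric(1), field)
    mean(v, na.rm = TRUE)
  }
  pooled <- evaluate(y, oof)
  sen <- agg("sen"); spe <- agg("spe")
  structure(list(counts = pooled$counts, sen = sen, spe = spe,
                 acc = agg("acc"), adr = average_detection_rate(sen, spe),
                 per_fold = per_fold, folds = fold, predictions = oof),
            class = "eval_report")
}
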