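# Prognostic classifiers and single-metric baselines.
#
# Two-class problem: good prognosis (GP, no evidence of disease >= 4 years
# after surgery) versus poor prognosis (PP, relapse and death of disease
# within 4 years). PP is the positive class for sensitivity and precision.
# Models are evaluated by repeated stratified 5-fold cross-validation;
# z-scoring is computed on each training fold and applied to its test fold.

POSITIVE_CLASS <- "PP"

#' Weighted 3-NN prediction
#'
#' Euclidean distance on z-scored features (training statistics), squared
#' inverse distance weighting, exhaustive search. A test point coinciding
#' with a training point adopts that neighbour's label; weight ties break
#' toward the nearest neighbour's class.
#'
#' @param train_x,train_y training matrix and labels.
#' @param test_x test matrix.
#' @param k neighbour count (default 3).
#' @param standardize z-score by training statistics (default TRUE).
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 3, standardize = TRUE) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (nrow(train_x) < k) stop("fewer training samples than k")
  train_y <- as.character(train_y)
  if (standardize) {
    z <- .zscore(train_x)
    train_x <- z$x
    test_x <- sweep(sweep(test_x, 2, z$center), 2, z$scale, "/")
  }
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d2 <- colSums((t(train_x) - test_x[i, ])^2)
    ord <- order(d2)
    nn <- ord[seq_len(k)]
    if (d2[nn[1]] == 0) { out[i] <- train_y[nn[1]]; next }
    wts <- 1 / d2[nn]
    sc <- tapply(wts, train_y[nn], sum)
    best <- names(sc)[sc == max(sc)]
    out[i] <- if (length(best) == 1L) best else train_y[nn[1]]
  }
  out
}

#' Fit a polynomial-kernel soft-margin SVM
#'
#' Kernel `(1 + <u, v>)^degree` with box constraint `C`, trained by
#' iterative single-data coordinate ascent on the (bias-free) dual until the
#' largest KKT violation drops below `tol`. The kernel's constant term
#' plays the role of the bias.
#'
#' @param X training matrix (z-scored internally).
#' @param y two-level labels.
#' @param C box constraint (default 1).
#' @param degree polynomial order (default 3).
#' @param tol KKT tolerance (default 1e-6).
#' @param max_passes iteration cap.
#' @return list of class `svm_fit`.
#' @export
svm_fit <- function(X, y, C = 1, degree = 3, tol = 1e-6, max_passes = 2000) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) == 1L) {
    warning("single-class training data; constant predictor")
    return(structure(list(constant = lev, levels = lev), class = "svm_fit"))
  }
  stopifnot(length(lev) == 2L)
  ypm <- ifelse(y == POSITIVE_CLASS, 1, -1)
  if (!POSITIVE_CLASS %in% lev) ypm <- ifelse(y == lev[2], 1, -1)
  z <- .zscore(X)
  K <- (1 + tcrossprod(z$x))^degree
  n <- nrow(X)
  alpha <- numeric(n)
  f <- numeric(n)                     # f_i = sum_j alpha_j y_j K_ij
  for (pass in seq_len(max_passes)) {
    viol <- 0
    for (i in seq_len(n)) {
      g <- 1 - ypm[i] * f[i]          # gradient of dual wrt alpha_i
      a_new <- min(max(alpha[i] + g / K[i, i], 0), C)
      if (a_new != alpha[i]) {
        f <- f + (a_new - alpha[i]) * ypm[i] * K[, i]
        alpha[i] <- a_new
      }
      # KKT violation measure
      if (alpha[i] <= 0) viol <- max(viol, g)
      else if (alpha[i] >= C) viol <- max(viol, -g)
      else viol <- max(viol, abs(g))
    }
    if (viol < tol) break
  }
  dual <- sum(alpha) - 0.5 * sum((alpha * ypm) * (K %*% (alpha * ypm)))
  structure(list(alpha = alpha, y = ypm, X = z$x, center = z$center,
                 scale = z$scale, degree = degree, C = C, dual = dual,
                 levels = lev, converged = pass < max_passes),
            class = "svm_fit")
}

#' Predict with a fitted SVM
#' @param fit `svm_fit`.
#' @param test_x test matrix.
#' @return character labels.
#' @export
svm_predict <- function(fit, test_x) {
  test_x <- as.matrix(test_x)
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(test_x)))
  Xte <- sweep(sweep(test_x, 2, fit$center), 2, fit$scale, "/")
  Kte <- (1 + tcrossprod(Xte, fit$X))^fit$degree
  sc <- as.numeric(Kte %*% (fit$alpha * fit$y))
  pos <- if (POSITIVE_CLASS %in% fit$levels) POSITIVE_CLASS else fit$levels[2]
  neg <- setdiff(fit$levels, pos)
  ifelse(sc >= 0, pos, neg)
}

#' Fit and predict in one call
#' @inheritParams svm_fit
#' @param test_x test matrix.
#' @param ... passed to [svm_fit()].
#' @export
svm_fit_predict <- function(X, y, test_x, ...) {
  svm_predict(svm_fit(X, y, ...), test_x)
}

.confusion_metrics <- function(truth, pred, positive = POSITIVE_CLASS) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Repeated stratified cross-validation of a prognostic model
#'
#' Per repetition a fresh stratified fold split is drawn; fold predictions
#' are pooled into one confusion matrix per repetition and the four metrics
#' are averaged over repetitions. PP is the positive class.
#'
#' @param X samples x features matrix, columns already ordered by relevance
#'   when `n_features` is used.
#' @param y labels (GP/PP).
#' @param model `"knn"` or `"svm"`.
#' @param n_features use only the first `n_features` columns (default all).
#' @param reps,folds protocol (default 100 x 5).
#' @param seed RNG seed; fixed seed gives bit-reproducible reports.
#' @param histology optional covariate for per-histology accuracies.
#' @param k,C,degree model hyper-parameters.
#' @return list of class `cv_report` with mean metrics, their standard
#'   errors across repetitions, per-histology accuracy and
#'   `n_features_used`.
#' @export
repeated_cv <- function(X, y, model = c("knn", "svm"), n_features = NULL,
                        reps = 100, folds = 5, seed = 1, histology = NULL,
                        k = 3, C = 1, degree = 3) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (!is.null(n_features)) X <- X[, seq_len(n_features), drop = FALSE]
  y <- as.character(y)
  if (min(table(y)) < folds)
    stop("stratification impossible: a class has fewer samples than folds")
  set.seed(seed)
  mets <- matrix(NA_real_, reps, 4)
  hist_acc <- NULL
  if (!is.null(histology)) {
    histology <- as.character(histology)
    hist_acc <- matrix(NA_real_, reps, length(unique(histology)),
                       dimnames = list(NULL, sort(unique(histology))))
  }
  for (r in seq_len(reps)) {
    fold_id <- .stratified_folds(y, folds)
    pred <- character(length(y))
    for (fd in seq_len(folds)) {
      te <- fold_id == fd
      pred[te] <- if (model == "knn")
        knn_predict(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                    k = k)
      else
        suppressWarnings(
          svm_fit_predict(X[!te, , drop = FALSE], y[!te],
                          X[te, , drop = FALSE], C = C, degree = degree))
    }
    mets[r, ] <- .confusion_metrics(y, pred)
    if (!is.null(hist_acc))
      for (h in colnames(hist_acc))
        hist_acc[r, h] <- mean(pred[histology == h] == y[histology == h])
  }
  mm <- colMeans(mets, na.rm = TRUE)
  se <- apply(mets, 2, function(v) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  names(mm) <- names(se) <- c("accuracy", "sensitivity", "specificity",
                              "precision")
  structure(list(metrics = mm, se = se,
                 per_histology_accuracy = if (is.null(hist_acc)) NULL
                 else colMeans(hist_acc, na.rm = TRUE),
                 n_features_used = ncol(X), model = model, reps = reps,
                 folds = folds, per_rep = mets),
            class = "cv_report")
}

#' Single-metric threshold baseline
#'
#' Scans thresholds at midpoints between consecutive sorted unique values
#' (plus the two infinities) under the rule `value >= threshold -> PP` and
#' returns the accuracy-maximising threshold (ties: lowest threshold) with
#' the full metric report on the data.
#'
#' @param values numeric metric (Ki-67 LI or cells/mm^2 density).
#' @param labels GP/PP labels.
#' @param positive positive class (default PP).
#' @return list of class `threshold_baseline` with `optimal_threshold`,
#'   `accuracy` and `report`.
#' @export
threshold_baseline <- function(values, labels, positive = POSITIVE_CLASS) {
  labels <- as.character(labels)
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  acc <- vapply(cand, function(th)
    mean(ifelse(values >= th, positive, "GP") == labels), numeric(1))
  best <- cand[which.max(acc)]          # which.max takes the first (lowest)
  pred <- ifelse(values >= best, positive, setdiff(unique(c(labels, "GP")),
                                                   positive)[1])
  structure(list(optimal_threshold = best,
                 accuracy = max(acc),
                 report = .confusion_metrics(labels, pred, positive)),
            class = "threshold_baseline")
}
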