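# Three-stage feature selection: constant filter, perfect-correlation
# filter, then neighbourhood component analysis (NCA) feature weighting
# with a 0.01 cut-off.
#
# NCA (feature-weighting form): with squared weights w_l^2 scaling
# per-feature absolute differences, the soft nearest-neighbour
# leave-one-out probability of sample i being classified correctly is
#   p_i = sum_{j != i, y_j = y_i} p_ij,
#   p_ij = exp(-d_w(i, j)) / sum_{k != i} exp(-d_w(i, k)),
#   d_w(i, j) = sum_l w_l^2 |x_il - x_jl|.
# The objective maximised is mean_i p_i - lambda * sum_l w_l^2.

#' Drop zero-variance features
#'
#' Removes features with literally the same value in every sample (strict
#' equality); survivor order preserved.
#'
#' @param table data.frame or matrix, samples x features.
#' @return the filtered table.
#' @export
drop_constant <- function(table) {
  x <- as.data.frame(table, check.names = FALSE)
  keep <- vapply(x, function(col) length(unique(col)) > 1L, logical(1))
  x[, keep, drop = FALSE]
}

#' Drop perfectly correlated features
#'
#' For each pair with |Pearson r| = 1 (within `tol`), the lower-variance
#' member is dropped. Pairs are processed in column order, so of several
#' mutually collinear columns exactly one (the highest-variance) survives.
#'
#' @param table data.frame or matrix, samples x features.
#' @param tol tolerance on `1 - |r|`.
#' @return the filtered table.
#' @export
drop_perfectly_correlated <- function(table, tol = 1e-12) {
  x <- as.data.frame(table, check.names = FALSE)
  if (ncol(x) < 2L) return(x)
  m <- as.matrix(x)
  v <- apply(m, 2, var)
  r <- suppressWarnings(cor(m))
  r[!is.finite(r)] <- 0
  drop <- rep(FALSE, ncol(m))
  for (i in seq_len(ncol(m) - 1L)) {
    if (drop[i]) next
    for (j in (i + 1L):ncol(m)) {
      if (drop[j]) next
      if (abs(r[i, j]) >= 1 - tol) {
        if (v[j] > v[i]) { drop[i] <- TRUE; break } else drop[j] <- TRUE
      }
    }
  }
  x[, !drop, drop = FALSE]
}

# z-score columns; zero-spread columns get scale 1
.zscore <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- apply(m, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(m, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# per-feature absolute-difference array, reshaped (n*n) x p for fast
# distance evaluation: dist vector = Dflat %*% w^2
.nca_diffs <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Dflat <- matrix(0, n * n, p)
  for (l in seq_len(p))
    Dflat[, l] <- abs(outer(X[, l], X[, l], "-"))
  Dflat
}

# objective and gradient of the full-batch NCA objective at w
.nca_objgrad <- function(w, Dflat, same, n, lambda) {
  dm <- matrix(Dflat %*% (w^2), n, n)
  P <- exp(-dm)
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / rs
  p_i <- rowSums(P * same)
  obj <- mean(p_i) - lambda * sum(w^2)
  Wmat <- P * p_i - P * same            # n x n, rows scaled
  grad <- as.numeric(2 * w * (crossprod(Dflat, as.vector(Wmat)) / n)) -
    2 * lambda * w
  list(obj = obj, grad = grad, p = P)
}

#' Fit NCA feature weights
#'
#' @param X samples x features matrix (z-scored internally when
#'   `standardize`).
#' @param y two-level factor or vector of class labels.
#' @param lambda regularisation parameter.
#' @param solver `"lbfgs"` (full-batch, final fits) or `"sgd"` (per-sample
#'   updates capped at `sgd_iter` passes, used during lambda tuning).
#' @param standardize z-score features first (default TRUE).
#' @param sgd_iter SGD pass cap (default 30).
#' @param seed RNG seed for the SGD shuffle.
#' @return list of class `nca_fit` with non-negative `weights`, `objective`,
#'   `converged`, and the fitted standardisation.
#' @export
nca_fit <- function(X, y, lambda = 0, solver = c("lbfgs", "sgd"),
                    standardize = TRUE, sgd_iter = 30, seed = 1) {
  solver <- match.arg(solver)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 4)
  y <- as.factor(y)
  z <- if (standardize) .zscore(X) else list(x = X, center = rep(0, p),
                                             scale = rep(1, p))
  Dflat <- .nca_diffs(z$x)
  same <- outer(y, y, "==") * 1
  diag(same) <- 0
  w0 <- rep(1, p)
  converged <- TRUE
  if (solver == "lbfgs") {
    fn <- function(w) -.nca_objgrad(w, Dflat, same, n, lambda)$obj
    gr <- function(w) -.nca_objgrad(w, Dflat, same, n, lambda)$grad
    opt <- optim(w0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = 200, factr = 1e5))
    w <- abs(opt$par)
    converged <- opt$convergence == 0
    obj <- -opt$value
  } else {
    set.seed(seed)
    ord <- t(vapply(seq_len(sgd_iter), function(i) sample.int(n),
                    integer(n)))
    w <- cpp_nca_sgd(Dflat, same, n, ord, lambda, 0.1)
    obj <- .nca_objgrad(w, Dflat, same, n, lambda)$obj
  }
  structure(list(weights = w, lambda = lambda, objective = obj,
                 converged = converged, center = z$center, scale = z$scale,
                 feature_names = colnames(X)),
            class = "nca_fit")
}

# NCA soft-classifier prediction error of test rows given a fitted weight
# vector (reference set = training rows)
.nca_cv_error <- function(w, Xtr, ytr, Xte, yte) {
  lev <- levels(as.factor(ytr))
  w2 <- w^2
  D <- matrix(0, nrow(Xte), nrow(Xtr))
  for (l in which(w2 > 0))
    D <- D + abs(outer(Xte[, l], Xtr[, l], "-")) * w2[l]
  K <- exp(-D)
  zero <- rowSums(K) == 0
  K[zero, ] <- 1
  sc <- vapply(lev, function(cl)
    rowSums(K[, ytr == cl, drop = FALSE]), numeric(nrow(Xte)))
  pred <- lev[max.col(matrix(sc, nrow(Xte)), ties.method = "first")]
  mean(pred != as.character(yte))
}

# stratified fold assignment: per class, shuffled round-robin
.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  f
}

#' Full NCA selection stage
#'
#' Lambda is chosen from a grid (by default 20 values linearly spaced in
#' [0, 2] divided by the sample count) by minimum mean classification error
#' of the NCA soft classifier over `cv_reps` repetitions of `folds`-fold
#' stratified cross-validation, each model fitted by SGD capped at 30
#' passes. The final fit on all data uses L-BFGS. Features with final
#' weight below `cutoff` are discarded.
#'
#' @param table samples x features data.frame/matrix (already passed through
#'   the constant and perfect-correlation filters).
#' @param y class labels.
#' @param lambda_grid candidate lambdas; default `seq(0, 2, length.out =
#'   20) / n`.
#' @param cv_reps repetitions of cross-validation per lambda (paper
#'   protocol: 100; reduce for desk-scale runs).
#' @param folds folds per repetition.
#' @param cutoff weight cut-off (default 0.01).
#' @param seed RNG seed.
#' @return list of class `nca_result`: `weights` (named), `lambda`,
#'   `ranking` (feature names by decreasing weight), `retained` (names with
#'   weight >= cutoff), `cv_losses`.
#' @export
nca_select <- function(table, y, lambda_grid = NULL, cv_reps = 100,
                       folds = 5, cutoff = 0.01, seed = 1) {
  X <- as.matrix(as.data.frame(table, check.names = FALSE))
  n <- nrow(X)
  y <- as.factor(y)
  if (is.null(lambda_grid)) lambda_grid <- seq(0, 2, length.out = 20) / n
  set.seed(seed)
  # every lambda is evaluated on the same fold draws (paired comparison):
  # the fold-to-fold noise cancels in the between-lambda differences, which
  # stabilises the argmin at small repetition counts
  errs <- matrix(NA_real_, length(lambda_grid), cv_reps * folds)
  col <- 0L
  for (rep in seq_len(cv_reps)) {
    fold_id <- .stratified_folds(y, folds)
    for (fd in seq_len(folds)) {
      col <- col + 1L
      tr <- fold_id != fd
      if (length(unique(y[tr])) < 2L || sum(!tr) == 0L) next
      z <- .zscore(X[tr, , drop = FALSE])
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, z$center), 2,
                   z$scale, "/")
      for (li in seq_along(lambda_grid)) {
        fit <- nca_fit(z$x, y[tr], lambda = lambda_grid[li], solver = "sgd",
                       standardize = FALSE,
                       seed = seed + 1000L * li + rep)
        errs[li, col] <- .nca_cv_error(fit$weights, z$x, y[tr], Xte, y[!tr])
      }
    }
  }
  losses <- rowMeans(errs, na.rm = TRUE)
  loss_se <- apply(errs, 1, function(v) sd(v, na.rm = TRUE) /
                     sqrt(sum(!is.na(v))))
  lambda <- lambda_grid[which.min(losses)]
  final <- nca_fit(X, y, lambda = lambda, solver = "lbfgs")
  w <- final$weights
  names(w) <- colnames(X)
  ord <- order(w, decreasing = TRUE)
  structure(list(weights = w, lambda = lambda,
                 ranking = colnames(X)[ord],
                 retained = colnames(X)[ord][w[ord] >= cutoff],
                 cv_losses = data.frame(lambda = lambda_grid, loss = losses),
                 fit = final),
            class = "nca_result")
}
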