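make_two_clusters <- function(n_per = 20, gap = 6, p = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = gap), n_per, p))
  list(X = X, y = rep(c("GP", "PP"), each = n_per))
}

test_that("knn follows the d = 0 rule, inverse-square weights and ties", {
  tr <- rbind(c(0, 0), c(1, 0), c(0, 2))
  ty <- c("PP", "PP", "GP")
  # exact duplicate adopts that neighbour's label
  expect_equal(knn_predict(tr, ty, rbind(c(0, 2)), k = 3,
                           standardize = FALSE), "GP")
  # neighbours at distances 1,1,2 with PP,PP,GP: weights 1+1 vs 0.25
  tr2 <- rbind(c(1, 0), c(-1, 0), c(0, 2))
  ty2 <- c("PP", "PP", "GP")
  expect_equal(knn_predict(tr2, ty2, rbind(c(0, 0)), k = 3,
                           standardize = FALSE), "PP")
  # weight tie broken toward the nearest neighbour's class
  tr3 <- rbind(c(1, 0), c(-2, 0))
  ty3 <- c("PP", "GP")
  expect_equal(knn_predict(tr3, ty3, rbind(c(0, 0)), k = 2,
                           standardize = FALSE), "PP")
  expect_error(knn_predict(tr3, ty3, rbind(c(0, 0)), k = 5), "fewer")
})

test_that("knn separates a symmetric two-cluster fixture perfectly", {
  d <- make_two_clusters(gap = 8, seed = 3)
  te <- make_two_clusters(gap = 8, seed = 4)
  pred <- knn_predict(d$X, d$y, te$X)
  expect_equal(mean(pred == te$y), 1)
})

test_that("svm separates margins and solves XOR with the cubic kernel", {
  d <- make_two_clusters(gap = 8, seed = 5)
  te <- make_two_clusters(gap = 8, seed = 6)
  fit <- svm_fit(d$X, d$y)
  expect_true(fit$converged)
  expect_equal(mean(svm_predict(fit, te$X) == te$y), 1)

  # XOR-like fixture: not linearly separable
  set.seed(7)
  n <- 120
  x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
  keep <- abs(x1) > 0.15 & abs(x2) > 0.15
  x1 <- x1[keep]; x2 <- x2[keep]
  yx <- ifelse(x1 * x2 > 0, "PP", "GP")
  X <- cbind(x1, x2)
  tr <- seq_along(yx) %% 2 == 0
  pred <- svm_fit_predict(X[tr, ], yx[tr], X[!tr, ])
  expect_gt(mean(pred == yx[!tr]), 0.9)

  # training-set accuracy at least matches CV accuracy (optimism)
  dtr <- make_two_clusters(gap = 2, n_per = 15, seed = 8)
  fit2 <- svm_fit(dtr$X, dtr$y)
  train_acc <- mean(svm_predict(fit2, dtr$X) == dtr$y)
  cv <- repeated_cv(dtr$X, dtr$y, model = "svm", reps = 10, seed = 1)
  expect_gte(train_acc + 1e-9, cv$metrics[["accuracy"]])

  # degenerate single-class training data
  expect_warning(f1 <- svm_fit(dtr$X[1:10, ], rep("GP", 10)))
  expect_equal(svm_predict(f1, dtr$X[1:3, ]), rep("GP", 3))
})

test_that("repeated_cv is reproducible, calibrated and null-safe", {
  d <- make_two_clusters(gap = 8, seed = 9)
  r1 <- repeated_cv(d$X, d$y, model = "knn", reps = 10, seed = 42)
  r2 <- repeated_cv(d$X, d$y, model = "knn", reps = 10, seed = 42)
  expect_identical(r1$per_rep, r2$per_rep)     # bit-reproducible
  expect_equal(r1$metrics[["accuracy"]], 1)

  # permuted labels give chance accuracy
  set.seed(10)
  yperm <- sample(d$y)
  rp <- repeated_cv(d$X, yperm, model = "knn", reps = 25, seed = 2)
  expect_lt(abs(rp$metrics[["accuracy"]] - 0.5), 0.1)

  # doubling repetitions moves the mean accuracy by < 1 SE
  ra <- repeated_cv(d$X, yperm, model = "knn", reps = 25, seed = 3)
  rb <- repeated_cv(d$X, yperm, model = "knn", reps = 50, seed = 3)
  expect_lt(abs(ra$metrics[["accuracy"]] - rb$metrics[["accuracy"]]),
            ra$se[["accuracy"]] + rb$se[["accuracy"]])

  idx <- c(1:4, 21:22)      # 4 GP, 2 PP: cannot stratify into 5 folds
  expect_error(repeated_cv(d$X[idx, ], d$y[idx], reps = 2, folds = 5),
               "stratification")
})

test_that("sensitivity/specificity of an all-PP predictor behave as defined", {
  truth <- c("PP", "PP", "GP", "GP", "GP")
  m <- ki67spatial:::.confusion_metrics(truth, rep("PP", 5))
  expect_equal(m[["sensitivity"]], 1)
  expect_equal(m[["specificity"]], 0)
})

test_that("threshold baseline scans midpoints and breaks ties low", {
  tb <- threshold_baseline(c(1, 2, 8, 12), c("GP", "GP", "PP", "PP"))
  expect_equal(tb$optimal_threshold, 5)
  expect_equal(tb$accuracy, 1)

  tb2 <- threshold_baseline(c(1, 2, 3), c("GP", "GP", "GP"))
  expect_equal(tb2$optimal_threshold, Inf)
  expect_equal(tb2$accuracy, 1)

  # anti-ordered values: >= rule cannot reach 1; equals an exhaustive scan
  vals <- c(10, 8, 3, 1); labs <- c("GP", "GP", "PP", "PP")
  tb3 <- threshold_baseline(vals, labs)
  cand <- c(-Inf, sort(vals)[-1] - diff(sort(vals)) / 2, Inf)
  accs <- vapply(cand, function(th)
    mean(ifelse(vals >= th, "PP", "GP") == labs), numeric(1))
  expect_equal(tb3$accuracy, max(accs))
  expect_lt(tb3$accuracy, 1)
})
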