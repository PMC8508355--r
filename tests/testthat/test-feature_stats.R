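test_that("pearson_test matches closed forms and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_test(x, x)$r, 1)
  expect_equal(pearson_test(x, x)$p, 0)
  # constructed orthogonal vectors
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(pearson_test(a, b)$r, 0)
  set.seed(3)
  for (i in 1:5) {
    u <- rnorm(20); v <- 0.5 * u + rnorm(20)
    ct <- cor.test(u, v)
    pt_ <- pearson_test(u, v)
    expect_equal(pt_$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pt_$p, ct$p.value, tolerance = 1e-12)
  }
  expect_true(pearson_test(rep(1, 5), rnorm(5))$degenerate)
  # sampling distribution: rho = 0.5, n = 1000
  set.seed(4)
  u <- rnorm(1000); v <- u + rnorm(1000, sd = sqrt(3))  # rho = 0.5
  expect_equal(pearson_test(u, v)$r, 0.5, tolerance = 0.12)
})

test_that("mannwhitney_test: exact enumeration and approximation vs wilcox", {
  r <- mannwhitney_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  w <- wilcox.test(c(1, 2), c(3, 4))
  expect_equal(r$p, w$p.value, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    mine <- mannwhitney_test(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  # tied/large samples: normal approximation with tie + continuity correction
  for (i in 1:5) {
    a <- sample(1:6, 30, replace = TRUE); b <- sample(2:7, 25, replace = TRUE)
    mine <- mannwhitney_test(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  # clearly shifted groups are detected
  set.seed(6)
  expect_lt(mannwhitney_test(rnorm(50), rnorm(50, 1.2))$p, 0.01)
  # identical groups sit at the null centre
  expect_gt(mannwhitney_test(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
})

test_that("benjamini_hochberg reproduces the step-up and stays monotone", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 4)), rep(1, 4))
  set.seed(7)
  p <- runif(50)
  q <- benjamini_hochberg(p)
  expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("feature_set_report classifies features against the covariates", {
  set.seed(8)
  n <- 40
  li <- runif(n, 1, 40)
  density <- li * 20 + rnorm(n, 0, 30)
  histology <- rep(c("AC", "LCNEC"), n / 2)
  tab <- data.frame(
    li_copy = li + rnorm(n, 0, 0.01),          # correlated with LI
    hist_feature = ifelse(histology == "AC", 0, 5) + rnorm(n, 0, 0.5),
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  rep_ <- feature_set_report(tab, ranking = names(tab), ki67_li = li,
                             density = density, histology = histology,
                             top_k = 3)
  per <- rep_$per_feature
  expect_false(per$uncorrelated_li[per$feature == "li_copy"])
  expect_false(per$histology_independent[per$feature == "hist_feature"])
  expect_true(all(per$all_three[per$feature %in% c("noise1", "noise2",
                                                   "noise3")]))
  # venn counts equal brute-force set algebra
  expect_equal(unname(rep_$venn_counts["all_three"]),
               sum(per$uncorrelated_li & per$uncorrelated_density &
                     per$histology_independent))
})
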