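test_that("build_graph reproduces forced small configurations", {
  p <- cell_pattern(c(0, 20, 40), c(0, 0, 0), frame_um = c(100, 100))
  g25 <- build_graph(p, 25)
  expect_equal(igraph::ecount(g25), 2)   # path
  g50 <- build_graph(p, 50)
  expect_equal(igraph::ecount(g50), 3)   # triangle
  expect_equal(igraph::ecount(build_graph(cell_pattern(numeric(0),
                                                       numeric(0)), 25)), 0)
})

test_that("build_graph equals the all-pairs brute-force oracle", {
  set.seed(31)
  p <- gen_pattern("csr", list(n = 200), c(500, 500), seed = 31)
  for (thr in c(25, 50, 75)) {
    g <- build_graph(p, thr)
    el <- igraph::as_edgelist(g)
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    # oracle: literal double loop
    oe <- NULL
    for (i in 1:199) for (j in (i + 1):200) {
      d <- sqrt((p$x_um[i] - p$x_um[j])^2 + (p$y_um[i] - p$y_um[j])^2)
      if (d <= thr) oe <- rbind(oe, c(i, j))
    }
    expect_equal(unname(el), unname(oe))
  }
})

test_that("edge count is monotone in the threshold", {
  p <- gen_pattern("thomas", list(kappa_per_mm2 = 30, mu = 10, sigma_um = 20),
                   c(800, 800), seed = 4)
  ec <- vapply(c(25, 50, 75), function(t) igraph::ecount(build_graph(p, t)),
               numeric(1))
  expect_true(all(diff(ec) >= 0))
})

test_that("local metrics match hand-computable cases", {
  tri <- igraph::make_full_graph(3)
  lm <- local_metrics(tri)
  expect_equal(lm$clustering, rep(1, 3))
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  lms <- local_metrics(star)
  expect_equal(lms$betweenness, c(6, 0, 0, 0, 0))   # 6 leaf pairs
  expect_equal(lms$degree, c(4, 1, 1, 1, 1))
  expect_equal(lms$eccentricity, c(1, 2, 2, 2, 2))
})

test_that("all nine local and three global metrics match the exhaustive oracle", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    adj <- random_adj(n, runif(1, 0.15, 0.7))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    lm <- local_metrics(g)
    om <- oracle_local_metrics(adj)
    for (col in names(om))
      expect_equal(lm[[col]], om[[col]], tolerance = 1e-9,
                   label = paste("metric", col, "rep", rep))
    expect_equal(global_metrics(g), oracle_global_metrics(adj),
                 tolerance = 1e-9)
  }
})

test_that("summarize_values follows the pinned conventions", {
  s <- summarize_values(c(2, 2, 2))
  expect_equal(unname(s[c("mean", "gmean", "hmean")]), c(2, 2, 2))
  expect_equal(unname(s[c("sd", "range", "m2", "m3", "m4", "skewness",
                          "kurtosis")]), rep(0, 7))

  s2 <- summarize_values(c(1, 2, 3, 4))
  expect_equal(unname(s2["mean"]), 2.5)
  expect_equal(unname(s2["q2"]), 2.5)
  expect_equal(unname(s2["range"]), 3)
  expect_equal(unname(s2["q1"]), 1.75)   # type-7 linear interpolation
  expect_equal(unname(s2["sd"]), sd(1:4))
  expect_equal(unname(s2["m2"]), mean((1:4 - 2.5)^2))

  s3 <- summarize_values(c(0, 1, 2))
  expect_equal(unname(s3[c("gmean", "hmean")]), c(0, 0))

  # mode: ties resolved to the smallest value
  expect_equal(unname(summarize_values(c(1, 1, 3, 3, 2))["mode"]), 1)

  expect_warning(s4 <- summarize_values(numeric(0)))
  expect_equal(unname(s4), rep(0, 16))
})

test_that("graph_feature_block has the contracted shape and names", {
  p <- gen_pattern("csr", list(n = 60), c(400, 400), seed = 8)
  b <- graph_feature_block(p)
  expect_length(b, 441)
  expect_equal(sum(startsWith(names(b), "g25_")), 147)
  expect_true(all(c("g25_degree_mean", "g50_pagerank_q3", "g75_assortativity")
                  %in% names(b)))
  expect_warning(b0 <- graph_feature_block(cell_pattern(numeric(0),
                                                        numeric(0))))
  expect_length(b0, 441)
  expect_true(all(b0 == 0))
})

test_that("graph features are invariant under rigid motions", {
  p <- gen_pattern("thomas", list(kappa_per_mm2 = 40, mu = 8, sigma_um = 15),
                   c(600, 600), seed = 21)
  b1 <- graph_feature_block(p)
  th <- 0.6
  xr <- p$x_um * cos(th) - p$y_um * sin(th) + 300
  yr <- p$x_um * sin(th) + p$y_um * cos(th) + 120
  pr <- cell_pattern(xr - min(xr), yr - min(yr),
                     frame_um = c(diff(range(xr)), diff(range(yr))))
  b2 <- graph_feature_block(pr)
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("eigcentrality display transform matches its definition", {
  expect_equal(eigcentrality_display_transform(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(eigcentrality_display_transform(c(0.25, 0.5, 1)), c(0, 1, 2))
  set.seed(2)
  v <- runif(20, 0.01, 5)
  expect_equal(min(eigcentrality_display_transform(v)), 0)
  expect_error(eigcentrality_display_transform(c(1, 0, 2)))
})
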