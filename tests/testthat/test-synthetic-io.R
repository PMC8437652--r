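test_that("load_table parses UCI-style files and reports parse errors", {
  ir <- load_builtin("iris")
  expect_identical(ir$features$n, 150L)
  expect_identical(ir$features$d, 4L)
  expect_identical(length(unique(ir$labels)), 3L)

  wi <- load_builtin("wine")
  expect_identical(wi$features$n, 178L)
  expect_identical(wi$features$d, 13L)
  expect_identical(sort(unique(wi$labels)), c(1L, 2L, 3L))

  # single-row CSV, no label column
  f <- tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1.5,2,3"), f)
  t1 <- load_table(f, "csv")
  expect_identical(t1$features$n, 1L)
  expect_null(t1$labels)

  # zoo-shaped file: leading name column, trailing class label
  f2 <- tempfile(fileext = ".data")
  writeLines(c("aardvark,1,0,1,4,1", "bass,0,0,1,0,4",
               "crow,0,1,1,2,2"), f2)
  t2 <- load_table(f2, "uci_data", label_column = "last",
                   name_column = "first")
  expect_identical(t2$features$n, 3L)
  expect_identical(t2$features$d, 4L)
  expect_identical(t2$names, c("aardvark", "bass", "crow"))
  expect_identical(t2$labels, c(1L, 4L, 2L))

  # non-numeric feature cell -> coordinates in the error
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "3,oops"), f3)
  expect_error(load_table(f3, "csv"), "row 2, column 2")
  expect_error(load_table(tempfile(), "csv"), "no such file")
})

test_that("write/load round-trip preserves features exactly", {
  set.seed(10)
  tab <- labeled_table(matrix(rnorm(30), 10, 3), labels = rep(1:2, 5))
  f <- tempfile(fileext = ".csv")
  write_table_csv(tab, f)
  back <- load_table(f, "csv", label_column = 4)
  expect_equal(back$features$values, tab$features$values,
               ignore_attr = TRUE)
  expect_identical(as.integer(back$labels), tab$labels)
})

test_that("gaussian mixture generator: reproducibility, separation, CLT", {
  a <- gen_gaussian_mixture(3, 90, 4, separation = 8, seed = 5)
  b <- gen_gaussian_mixture(3, 90, 4, separation = 8, seed = 5)
  expect_identical(a$features$values, b$features$values)

  tc <- attr(a, "true_centers")
  expect_identical(dim(tc), c(3L, 4L))
  # pairwise center distances >= separation * sigma
  dists <- as.matrix(dist(tc))
  expect_true(all(dists[upper.tri(dists)] >= 8 - 1e-9))

  # strong separation: nearest-true-center assignment = true labels
  big <- gen_gaussian_mixture(3, 120, 3, separation = 30, seed = 6)
  asg <- assign_nearest(big$features, attr(big, "true_centers"))
  expect_identical(asg$labels, big$labels)

  # component sample means near the true centers (CLT bound)
  m <- 40  # per component
  lim <- 4 / sqrt(m)
  for (t in 1:3) {
    sm <- colMeans(big$features$values[big$labels == t, ])
    expect_true(all(abs(sm - attr(big, "true_centers")[t, ]) < lim))
  }
  expect_error(gen_gaussian_mixture(3, 90, 2, separation = 0), "separation")
})

test_that("prescription generator plants recoverable binary blocks", {
  # deterministic extreme: p_in = 1, p_out = 0 -> exact block indicators
  hard <- gen_prescription_matrix(k = 4, n = 40, d = 20, p_in = 1,
                                  p_out = 0.001, seed = 3)
  X <- hard$features$values
  expect_true(all(X %in% c(0, 1)))
  blocks <- attr(hard, "blocks")
  for (i in seq_len(40)) {
    expect_true(all(X[i, blocks[[hard$labels[i]]]] == 1))
  }

  a <- gen_prescription_matrix(seed = 9)
  b <- gen_prescription_matrix(seed = 9)
  expect_identical(a$features$values, b$features$values)
  expect_identical(dim(a$features$values), c(270L, 40L))
  expect_error(gen_prescription_matrix(k = 8, n = 10, d = 5), "k <= d")
})

test_that("cluster_profile ranks attributes and conserves frequencies", {
  # a cluster whose rows all share one active drug puts it on top at 1.0
  X <- rbind(matrix(rep(c(1, 0, 0, 0), 5), 5, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 1), 5), 5, 4, byrow = TRUE))
  tab <- labeled_table(X)
  res <- run_improved(tab$features, 2,
                      de_config(NP = 16, max_generations = 150,
                                stagnation_limit = 50, seed = 2))
  prof <- cluster_profile(res, tab, top_m = 2)
  top1 <- prof[[which(attr(prof, "sizes") > 0)[1]]]
  expect_equal(top1$frequency[1], 1.0)

  # weighted within-cluster frequencies aggregate to the global frequency
  set.seed(12)
  Xr <- matrix(rbinom(200, 1, 0.4), 20, 10)
  tabr <- labeled_table(Xr)
  resr <- run_improved(tabr$features, 3,
                       de_config(NP = 20, max_generations = 100,
                                 stagnation_limit = 40, seed = 6))
  pr <- cluster_profile(resr, tabr, top_m = 10)
  means <- attr(pr, "means")
  sizes <- attr(pr, "sizes")
  occupied <- sizes > 0
  glob <- colSums(means[occupied, , drop = FALSE] * sizes[occupied]) / sum(sizes)
  expect_equal(unname(glob), unname(colMeans(Xr)), tolerance = 1e-12)

  # per-cluster means match a loop-based counting oracle
  for (t in which(occupied)) {
    rows <- resr$assignment$labels == t
    oracle <- apply(Xr[rows, , drop = FALSE], 2, function(col) sum(col) / sum(rows))
    expect_equal(unname(means[t, ]), unname(oracle))
  }
})

test_that("adjusted_rand_index matches frozen external-oracle values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3, 3), c(1, 1, 2, 3, 3, 3)),
               0.4444444444444444, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 2, 2, 2), c(2, 2, 2, 1, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 2, 3, 1, 2, 3, 1, 2),
                                   c(1, 1, 2, 2, 3, 3, 1, 2)),
               -0.14285714285714285, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5,
               tolerance = 1e-12)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("history export writes the two-column convergence CSV", {
  tab <- gen_gaussian_mixture(2, 30, 2, separation = 6, seed = 1)
  res <- run_improved(tab$features, 2,
                      de_config(NP = 16, max_generations = 40, seed = 1))
  f <- tempfile(fileext = ".csv")
  write_history_csv(res, f)
  df <- read.csv(f)
  expect_identical(names(df), c("generation", "best_wcd"))
  expect_equal(df$best_wcd, res$history)
  expect_identical(nrow(df), res$iterations)
})
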