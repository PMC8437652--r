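make_pop <- function(NP = 8, D = 4, seed = 3, lo = -2, hi = 2) {
  set.seed(seed)
  bounds <- cbind(rep(lo, D), rep(hi, D))
  pop <- init_population(bounds, NP)
  pop$fitness <- rowSums(pop$genes^2)  # arbitrary evaluated fitness
  pop
}

test_that("init_population respects bounds, determinism and uniformity", {
  bounds <- cbind(c(0, -1, 5), c(1, -1, 10))  # middle gene degenerate
  set.seed(1)
  p <- init_population(bounds, 6)
  expect_true(all(p$genes[, 2] == -1))
  expect_true(all(p$genes[, 1] >= 0 & p$genes[, 1] <= 1))
  expect_true(all(p$genes[, 3] >= 5 & p$genes[, 3] <= 10))
  expect_identical(p$generation, 0L)

  set.seed(99); a <- init_population(bounds, 10)
  set.seed(99); b <- init_population(bounds, 10)
  expect_identical(a$genes, b$genes)

  expect_error(init_population(cbind(1, 0), 5), "inverted")
  expect_error(init_population(cbind(0, 1), 3), ">= 4")

  # empirical mean of a gene ~ interval midpoint within 3 standard errors
  set.seed(42)
  big <- init_population(cbind(c(2), c(8)), 10000)
  se <- (8 - 2) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(big$genes[, 1]) - 5), 3 * se)
})

test_that("mutation strategies reproduce their defining arithmetic", {
  pop <- make_pop()
  # all individuals identical -> mutants collapse to that individual
  clone <- pop
  clone$genes <- matrix(rep(clone$genes[1, ], each = 8), 8)
  clone$fitness <- rep(1, 8)
  set.seed(5)
  expect_equal(as.numeric(mutate_rand_1(clone, 2, 0.6)), clone$genes[1, ])
  expect_equal(as.numeric(mutate_best_1(clone, 2, 0.6)), clone$genes[1, ])
  expect_equal(as.numeric(mutate_current_to_best_1(clone, 2, 0.6)),
               clone$genes[1, ])

  # F = 0 degenerates to the base vector
  set.seed(6)
  v <- mutate_rand_1(pop, 1, 0)
  expect_equal(as.numeric(v), pop$genes[attr(v, "idx")[1], ])
  set.seed(6)
  vb <- mutate_best_1(pop, 1, 0)
  expect_equal(as.numeric(vb), pop$genes[which.min(pop$fitness), ])
  set.seed(6)
  vc <- mutate_current_to_best_1(pop, 3, 0)
  expect_equal(as.numeric(vc), pop$genes[3, ])

  # logged indices replay the formulas exactly, for every strategy
  for (seed in 1:10) {
    set.seed(seed)
    v <- mutate_rand_1(pop, 4, 0.7)
    r <- attr(v, "idx")
    expect_false(4 %in% r)
    expect_identical(length(unique(r)), 3L)
    expect_equal(as.numeric(v),
                 pop$genes[r[1], ] + 0.7 * (pop$genes[r[2], ] - pop$genes[r[3], ]))

    set.seed(seed + 50)
    v <- mutate_best_1(pop, 4, 0.7)
    r <- attr(v, "idx")
    b <- which.min(pop$fitness)
    expect_equal(as.numeric(v),
                 pop$genes[b, ] + 0.7 * (pop$genes[r[1], ] - pop$genes[r[2], ]))

    set.seed(seed + 100)
    v <- mutate_current_to_best_1(pop, 4, 0.7)
    r <- attr(v, "idx")
    expect_equal(as.numeric(v),
                 pop$genes[4, ] + 0.7 * (pop$genes[b, ] - pop$genes[4, ]) +
                   0.7 * (pop$genes[r[1], ] - pop$genes[r[2], ]))
  }

  tiny <- make_pop()
  tiny$genes <- tiny$genes[1:3, ]
  tiny$fitness <- tiny$fitness[1:3]
  expect_error(mutate_rand_1(tiny, 1, 0.5), ">= 4")
})

test_that("binomial crossover honors CR limits and inherits only real genes", {
  parent <- 1:10 * 1.0
  mutant <- -(1:10) * 1.0
  set.seed(4)
  expect_equal(as.numeric(binomial_crossover(parent, mutant, 1)), mutant)
  for (rep in 1:20) {
    tr <- binomial_crossover(parent, mutant, 0)
    expect_identical(sum(as.numeric(tr) != parent), 1L)  # exactly j_rand
    expect_identical(which(as.numeric(tr) != parent), attr(tr, "j_rand"))
  }
  # every output gene comes from parent or mutant
  for (rep in 1:20) {
    tr <- as.numeric(binomial_crossover(parent, mutant, 0.5))
    expect_true(all(tr == parent | tr == mutant))
    expect_true(any(tr == mutant))  # at least one mutant gene
  }
  expect_error(binomial_crossover(1:3, 1:4, 0.5), "length")
})

test_that("mutant-gene inheritance frequency matches CR + (1-CR)/D", {
  D <- 10; CR <- 0.5; n <- 10000
  parent <- rep(0, D); mutant <- rep(1, D)
  set.seed(314)
  freq <- rowMeans(vapply(seq_len(n), function(i)
    as.numeric(binomial_crossover(parent, mutant, CR)), numeric(D)))
  p <- CR + (1 - CR) / D
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3.5 * se))
})

test_that("greedy selection is strict and never increases fitness", {
  a <- list(genes = 1, fitness = 2.0)
  b <- list(genes = 2, fitness = 1.0)
  expect_identical(de_select(a, b), b)
  expect_identical(de_select(a, list(genes = 3, fitness = 2.0)), a)  # tie
  set.seed(8)
  for (rep in 1:50) {
    fp <- runif(1); ft <- runif(1)
    keep <- de_select(list(genes = 0, fitness = fp),
                      list(genes = 1, fitness = ft))
    expect_identical(keep$fitness, if (ft < fp) ft else fp)
    expect_lte(keep$fitness, fp)
  }
  expect_error(de_select(list(genes = 1, fitness = NA_real_), b), "evaluated")
})

test_that("diversity indicator: closed forms, oracle, invariances", {
  # identical nonzero individuals -> sigma = 0, lambda = 0
  pop <- matrix(rep(c(1, 2), each = 5), 5)
  dv <- diversity_lambda(pop)
  expect_identical(dv$sigma, 0)
  expect_identical(dv$lambda, 0)

  # forced arithmetic: (0,2) and (0,4)
  dv2 <- diversity_lambda(rbind(c(0, 2), c(0, 4)))
  expect_equal(dv2$mu, c(0, 3))
  expect_equal(dv2$sigma, 1)
  expect_equal(dv2$lambda, 1 / 3)

  # centroid at the origin -> flagged +Inf sentinel
  dv3 <- diversity_lambda(rbind(c(-1, 0), c(1, 0)))
  expect_identical(dv3$lambda, Inf)

  set.seed(17)
  G <- matrix(rnorm(60, mean = 2), 10, 6)
  dv4 <- diversity_lambda(G)
  mu_o <- apply(G, 2, mean)
  sig_o <- mean(apply(G, 1, function(r) sqrt(sum((r - mu_o)^2))))
  expect_equal(dv4$mu, mu_o, tolerance = 1e-12)
  expect_equal(dv4$sigma, sig_o, tolerance = 1e-12)
  expect_equal(dv4$lambda, sig_o / sqrt(sum(mu_o^2)), tolerance = 1e-12)

  # permutation invariance and scale invariance (lambda is scale-free)
  for (rep in 1:5) {
    expect_equal(diversity_lambda(G[sample(10), ])$lambda, dv4$lambda)
    c0 <- runif(1, 0.1, 10)
    expect_equal(diversity_lambda(c0 * G)$lambda, dv4$lambda,
                 tolerance = 1e-12)
  }

  # RMS variant is the quadratic mean of the same distances
  dv5 <- diversity_lambda(G, rms = TRUE)
  d_o <- apply(G, 1, function(r) sqrt(sum((r - mu_o)^2)))
  expect_equal(dv5$sigma, sqrt(mean(d_o^2)), tolerance = 1e-12)
  expect_gte(dv5$sigma, dv4$sigma)  # QM >= AM
})
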