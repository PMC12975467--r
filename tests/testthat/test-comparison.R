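test_that("gen_data_matched preserves marginals exactly and hits targets", {
  set.seed(21)
  # identity target, normal marginals: achieved off-diagonals near 0
  marg <- replicate(3, rnorm(500), simplify = FALSE)
  x <- gen_data_matched(diag(3), marg, seed = 1)
  ach <- cor(x)
  expect_true(all(abs(ach[lower.tri(ach)]) < 0.1))

  # exact multiset equality per column, for an arbitrary target
  target <- matrix(0.4, 3, 3); diag(target) <- 1
  x2 <- gen_data_matched(target, marg, seed = 2)
  for (j in 1:3) expect_equal(sort(x2[, j]), sort(marg[[j]]))

  # skewed marginals, r = 0.6: correlation RMSR within tolerance
  skewed <- replicate(3, exp(0.5 * rnorm(1000)), simplify = FALSE)
  target6 <- matrix(0.6, 3, 3); diag(target6) <- 1
  x3 <- gen_data_matched(target6, skewed, max_iter = 50, seed = 3)
  expect_lte(cor_rmsr(target6, cor(x3)), 0.05)
  expect_lte(attr(x3, "rmsr"), 0.05)

  expect_error(gen_data_matched(matrix(0.5, 2, 3), marg[1:2]), "square")
  bad <- diag(3); bad[1, 2] <- 0.9
  expect_error(gen_data_matched(bad, marg), "symmetric")
})

test_that("dimensional ensembles match empirical moments and structure", {
  set.seed(31)
  sim <- simulate_taxonic(synthetic_spec(seed = 31, n = 300L))
  m <- sim$matrix
  ens <- generate_dimensional_comparison(m, n_sets = 12L,
                                         settings = small_settings(),
                                         seed = 5, keep_data = TRUE)
  expect_s3_class(ens, "comparison_ensemble")
  expect_equal(ens$n_sets, 12L)
  expect_length(ens$curves$mambac, 12L)

  # mean curve is the pointwise mean of the per-set curves
  for (mtd in names(ens$curves)) {
    ys <- vapply(ens$curves[[mtd]], `[[`,
                 numeric(length(ens$mean_curve[[mtd]]$y)), "y")
    expect_equal(ens$mean_curve[[mtd]]$y, rowMeans(ys))
    expect_true(all(ens$envelope[[mtd]]$lo <= ens$mean_curve[[mtd]]$y))
    expect_true(all(ens$envelope[[mtd]]$hi >= ens$mean_curve[[mtd]]$y))
  }

  # bootstrap marginals: simulated column means within 3 SE of empirical
  se <- apply(as.matrix(m), 2L, sd) / sqrt(nrow(m))
  for (x in ens$datasets) {
    expect_true(all(abs(colMeans(x) - colMeans(as.matrix(m))) < 3.5 * se))
  }
})

test_that("taxonic ensembles reproduce the putative group structure", {
  expect_equal(round(547 * 0.25), 137L)  # fixed-rate group size contract
  set.seed(41)
  sim <- simulate_taxonic(synthetic_spec(seed = 41, n = 300L))
  m <- sim$matrix
  g <- classify_putative_groups(m, 0.25)
  expect_equal(g$taxon_count, round(300 * 0.25))

  ens <- generate_taxonic_comparison(m, base_rate = 0.25, n_sets = 10L,
                                     settings = small_settings(),
                                     seed = 6, keep_data = TRUE)
  expect_equal(ens$base_rate, 0.25)
  putative_d <- mean(cohens_d(m, g))
  # simulated between-group separation matches the putative-group d:
  # the taxon block is the last round(n * p) rows by construction
  sim_d <- vapply(ens$datasets, function(x) {
    flags <- c(rep(0L, 300L - g$taxon_count), rep(1L, g$taxon_count))
    mean(cohens_d(indicator_matrix(x), flags))
  }, numeric(1L))
  expect_lt(abs(mean(sim_d) - putative_d), 0.3)

  # a group smaller than k + 2 cases cannot be matched
  expect_error(generate_taxonic_comparison(m, base_rate = 0.01,
                                           settings = small_settings()),
               "within-group")
})

test_that("ensembles are reproducible from the seed", {
  set.seed(51)
  m <- simulate_taxonic(synthetic_spec(seed = 51, n = 200L))$matrix
  e1 <- generate_dimensional_comparison(m, n_sets = 5L,
                                        settings = small_settings(),
                                        seed = 9)
  e2 <- generate_dimensional_comparison(m, n_sets = 5L,
                                        settings = small_settings(),
                                        seed = 9)
  expect_identical(e1$mean_curve, e2$mean_curve)
  expect_identical(e1$rmsr, e2$rmsr)
})
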