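test_that("descriptives use n-1 sd, moment skewness and excess kurtosis", {
  m <- indicator_matrix(cbind(a = c(1, 2, 3), b = c(-1, 0, 1)))
  d <- descriptives(m)
  expect_equal(d$mean, c(2, 0))
  expect_equal(d$sd, c(1, 1))
  expect_equal(d$skewness[2L], 0)  # symmetric sample

  # Monte-Carlo: standard normal excess kurtosis near 0
  set.seed(7)
  mc <- indicator_matrix(cbind(x = rnorm(10000), y = rnorm(10000),
                               z = rnorm(10000)))
  dk <- descriptives(mc)
  expect_true(all(abs(dk$kurtosis) < 0.2))

  cm <- indicator_matrix(cbind(a = rep(5, 5), b = 1:5))
  expect_warning(dc <- descriptives(cm), "constant")
  expect_true(is.na(dc$skewness[1L]) && is.na(dc$kurtosis[1L]))
  expect_true(dc$degenerate[1L])
})

test_that("putative classification flags exactly round(n * P) top cases", {
  set.seed(11)
  m <- indicator_matrix(matrix(rnorm(8 * 3), 8, 3))
  g <- classify_putative_groups(m, 0.25)
  expect_equal(g$taxon_count, 2L)
  tot <- rowSums(scale(as.matrix(m)))
  expect_setequal(which(g$flags == 1L), order(-tot)[1:2])

  # sort-and-cut oracle on known totals
  m2 <- indicator_matrix(cbind(a = 1:10, b = 1:10, c = 1:10))
  g2 <- classify_putative_groups(m2, 0.5)
  expect_equal(which(g2$flags == 1L), 6:10)

  # exact count across a base-rate grid (profile precondition)
  set.seed(12)
  m3 <- indicator_matrix(matrix(rnorm(201 * 3), 201, 3))
  for (p in seq(0.025, 0.975, by = 0.05)) {
    expect_equal(classify_putative_groups(m3, p)$taxon_count,
                 round(201 * p))
  }

  # degenerate all-tied totals: first round(n*P) cases, with a warning
  m4 <- indicator_matrix(matrix(1, 10, 3) + 0)
  expect_warning(g4 <- classify_putative_groups(m4, 0.3), "ties")
  expect_equal(which(g4$flags == 1L), 1:3)

  expect_error(classify_putative_groups(m2, 1.2), "between 0 and 1")
})

test_that("Cohen's d uses the pooled sd and keeps its sign", {
  m <- indicator_matrix(cbind(x = c(1, 2, 3, 3, 4, 5)))
  flags <- c(0, 0, 0, 1, 1, 1)
  expect_equal(unname(cohens_d(m, flags)), 2)          # pooled sd = 1
  expect_equal(unname(cohens_d(m, 1 - flags)), -2)     # antisymmetry
  # identical group means
  m2 <- indicator_matrix(cbind(x = c(1, 3, 1, 3)))
  expect_equal(unname(cohens_d(m2, c(0, 0, 1, 1))), 0)
  # location and scale invariance
  set.seed(3)
  m3 <- indicator_matrix(cbind(x = rnorm(40)))
  fl <- rep(c(0, 1), 20)
  d0 <- cohens_d(m3, fl)
  expect_equal(cohens_d(indicator_matrix(as.matrix(m3) + 7), fl), d0)
  expect_equal(cohens_d(indicator_matrix(as.matrix(m3) * 3), fl), d0)
  # zero pooled sd flagged undefined
  m4 <- indicator_matrix(cbind(x = rep(2, 6)))
  expect_warning(d4 <- cohens_d(m4, flags), "pooled sd")
  expect_true(is.na(d4))
})

test_that("validity gate retains d >= 1.25 indicators and needs three", {
  sidas_d <- c(sidas1 = 0.31, sidas2 = -0.01, sidas3 = 2.75,
               sidas4 = 2.25, sidas5 = 3.67)
  expect_equal(filter_valid_indicators(sidas_d),
               c("sidas3", "sidas4", "sidas5"))
  bss_d <- c(wish = 2.07, prep = 2.36, active = 2.57)
  expect_equal(filter_valid_indicators(bss_d), c("wish", "prep", "active"))
  # threshold is inclusive
  expect_equal(filter_valid_indicators(c(a = 1.25, b = 2, c = 3)),
               c("a", "b", "c"))
  expect_error(filter_valid_indicators(c(a = 1.0, b = 2, c = 3)),
               "a \\(d = 1.00\\)")
})

test_that("putative-group d on taxonic data lands in the expected band", {
  # true separation 2, within-group sd 1: the total-score classification
  # at the generating base rate gives mean estimated d near the truth
  ds <- vapply(1:20, function(seed) {
    sim <- simulate_taxonic(synthetic_spec("taxonic", n = 600L, k = 3L,
                                           base_rate = 0.25, separation = 2,
                                           within_r = 0, seed = seed))
    g <- classify_putative_groups(sim$matrix, 0.25)
    mean(cohens_d(sim$matrix, g))
  }, numeric(1L))
  expect_gt(mean(ds), 1.5)
  expect_lt(mean(ds), 2.6)
})
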