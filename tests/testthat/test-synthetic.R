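test_that("generators are deterministic in the seed with exact group counts", {
  s <- synthetic_spec("taxonic", n = 600L, seed = 5)
  a <- simulate_taxonic(s)
  b <- simulate_taxonic(s)
  expect_identical(as.matrix(a$matrix), as.matrix(b$matrix))
  expect_identical(a$membership, b$membership)
  expect_equal(sum(a$membership), 150L)  # round(600 * 0.25), never Bernoulli

  d <- simulate_dimensional(synthetic_spec("dimensional", n = 200L, seed = 5))
  expect_identical(as.matrix(d$matrix),
                   as.matrix(simulate_dimensional(
                     synthetic_spec("dimensional", n = 200L, seed = 5))$matrix))
  expect_error(synthetic_spec(n = 10), "at least 50")
  expect_error(synthetic_spec(k = 2), "at least 3")
  expect_error(synthetic_spec(base_rate = 1.5), "in \\(0, 1\\)")
})

test_that("taxonic generator realizes the requested separation", {
  ds <- vapply(1:20, function(seed) {
    sim <- simulate_taxonic(synthetic_spec("taxonic", n = 2000L,
                                           separation = 2, within_r = 0,
                                           seed = seed))
    mean(cohens_d(sim$matrix, sim$membership))
  }, numeric(1L))
  expect_lt(abs(mean(ds) - 2), 0.2)

  # zero separation: the two groups are indistinguishable
  pvals <- vapply(1:20, function(seed) {
    sim <- simulate_taxonic(synthetic_spec("taxonic", n = 600L,
                                           separation = 0, seed = seed))
    min(vapply(1:3, function(j) {
      t.test(as.matrix(sim$matrix)[sim$membership == 1L, j],
             as.matrix(sim$matrix)[sim$membership == 0L, j])$p.value
    }, numeric(1L)))
  }, numeric(1L))
  expect_gte(sum(pvals > 0.01), 18L)
})

test_that("strong separation without nuisance correlation yields bimodality", {
  # sample bimodality coefficient against the uniform reference 5/9
  bimod <- function(x) {
    n <- length(x)
    cx <- x - mean(x)
    g1 <- mean(cx^3) / mean(cx^2)^1.5
    g2 <- mean(cx^4) / mean(cx^2)^2 - 3
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  }
  # moment oracle: the separated mixture's coefficient must exceed the
  # same seed's zero-separation (unimodal normal) control on every column
  hits <- vapply(1:20, function(seed) {
    sep <- simulate_taxonic(synthetic_spec("taxonic", n = 600L,
                                           base_rate = 0.5, separation = 2,
                                           within_r = 0, seed = seed))
    ctl <- simulate_taxonic(synthetic_spec("taxonic", n = 600L,
                                           base_rate = 0.5, separation = 0,
                                           within_r = 0, seed = seed))
    all(apply(as.matrix(sep$matrix), 2L, bimod) >
          apply(as.matrix(ctl$matrix), 2L, bimod))
  }, logical(1L))
  expect_gte(sum(hits), 18L)
})

test_that("dimensional generator matches its loading structure", {
  z <- simulate_dimensional(synthetic_spec("dimensional", n = 1000L,
                                           loadings = 0, seed = 7))
  cz <- cor(as.matrix(z$matrix))
  expect_true(all(abs(cz[lower.tri(cz)]) < 0.1))

  s7 <- simulate_dimensional(synthetic_spec("dimensional", n = 2000L,
                                            loadings = 0.7, seed = 8))
  c7 <- cor(as.matrix(s7$matrix))
  expect_true(all(abs(c7[lower.tri(c7)] - 0.49) < 0.08))
})

test_that("matched pairs share population correlations across structures", {
  # mixture covariance algebra: p = 0.25, d = 2, w = 0 gives r = 3/7
  expect_equal(mixture_correlation(0.25, 2, 2, 0), 3 / 7)
  expect_equal(mixture_correlation(0.25, 0, 0, 0.3), 0.3)  # d = 0 case
  spec <- synthetic_spec("taxonic", n = 2000L, separation = 2,
                         within_r = 0, seed = 9)
  pair <- matched_pair(spec)
  expect_equal(pair$loadings, rep(sqrt(3 / 7), 3L))
  ct <- cor(as.matrix(pair$taxonic$matrix))
  cd <- cor(as.matrix(pair$dimensional$matrix))
  expect_lte(cor_rmsr(ct, cd), 0.05)
  # large-sample brute-force check of the population identity itself
  big <- matched_pair(synthetic_spec("taxonic", n = 10000L, separation = 2,
                                     within_r = 0, seed = 10))
  cb <- cor(as.matrix(big$taxonic$matrix))
  expect_true(all(abs(cb[lower.tri(cb)] - 3 / 7) < 0.05))
})

test_that("presets reproduce the published indicator shapes approximately", {
  b <- preset_spec("bss_like", seed = 1)
  expect_equal(b$n, 547L)
  expect_equal(b$k, 3L)
  mb <- simulate_taxonic(b)$matrix
  expect_true(all(abs(colMeans(as.matrix(mb)) -
                        c(7.12, 2.68, 2.00)) < 0.75))

  s <- preset_spec("sidas_like", seed = 1)
  expect_equal(s$n, 989L)
  ms <- simulate_taxonic(s)$matrix
  expect_true(all(abs(colMeans(as.matrix(ms)) -
                        c(2.15, 4.01, 3.19)) < 0.75))
  expect_true(all(as.matrix(ms) >= 0 & as.matrix(ms) <= 10))
  expect_error(preset_spec("nope"), "arg")

  # dimensional preset variant carries matched loadings
  sd <- preset_spec("sidas_like", structure = "dimensional", seed = 1)
  expect_equal(sd$structure, "dimensional")
  expect_true(all(sd$loadings > 0 & sd$loadings < 1))
})
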