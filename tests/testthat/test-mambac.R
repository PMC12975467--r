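test_that("mambac_curve computes mean-above-minus-below at each cut", {
  # cut between ranks 3 and 4 separates the two output blocks exactly
  cv <- mambac_curve(1:6, c(0, 0, 0, 1, 1, 1), n_cuts = 5L, end_offset = 1L)
  expect_equal(cv$x, 1:5)
  expect_equal(cv$y[3L], 1)
  # and the closed form holds at every cut
  expect_equal(cv$y, vapply(1:5, function(c) {
    mean(c(0, 0, 0, 1, 1, 1)[(c + 1):6]) - mean(c(0, 0, 0, 1, 1, 1)[1:c])
  }, numeric(1L)))

  # constant output: zero everywhere
  cv0 <- mambac_curve(rnorm(100), rep(3, 100), n_cuts = 10L, end_offset = 5L)
  expect_equal(cv0$y, rep(0, 10L))

  # linearity: shifting the output is a no-op, scaling scales y
  set.seed(2)
  inp <- rnorm(120); out <- rnorm(120)
  a <- mambac_curve(inp, out, n_cuts = 10L, end_offset = 5L)
  b <- mambac_curve(inp, out + 5, n_cuts = 10L, end_offset = 5L)
  d <- mambac_curve(inp, out * 3, n_cuts = 10L, end_offset = 5L)
  expect_equal(a$y, b$y)
  expect_equal(d$y, a$y * 3)

  expect_error(mambac_curve(1:30, 1:30, n_cuts = 50L, end_offset = 25L),
               "too small")
})

test_that("mambac builds k(k-1) panels and is deterministic without ties", {
  set.seed(8)
  m <- indicator_matrix(matrix(rnorm(150 * 3), 150, 3))
  cs <- mambac(m, n_cuts = 15L, end_offset = 10L, replications = 7L, seed = 1)
  expect_equal(length(cs$panel_curves), 6L)
  expect_equal(cs$averaged_curve$y,
               rowMeans(vapply(cs$panel_curves, `[[`,
                               numeric(15L), "y")))
  # tie-free input: replications are a no-op
  cs1 <- mambac(m, n_cuts = 15L, end_offset = 10L, replications = 1L, seed = 2)
  expect_equal(cs$averaged_curve$y, cs1$averaged_curve$y)
})

test_that("averaged curve order-invariance up to panel relabeling", {
  set.seed(9)
  m <- indicator_matrix(matrix(rnorm(150 * 3), 150, 3,
                               dimnames = list(NULL, c("a", "b", "c"))))
  perm <- indicator_matrix(as.matrix(m)[, c(3, 1, 2)])
  c1 <- mambac(m, n_cuts = 15L, end_offset = 10L)
  c2 <- mambac(perm, n_cuts = 15L, end_offset = 10L)
  expect_equal(c1$averaged_curve$y, c2$averaged_curve$y)
  m1 <- maxeig(m, n_windows = 10L)
  m2 <- maxeig(perm, n_windows = 10L)
  expect_equal(m1$averaged_curve$y, m2$averaged_curve$y)
})

test_that("taxonic data peak the curve near the class boundary", {
  # taxon = high-scoring minority at p = 0.25: the mean-difference peak
  # sits near sorted rank n(1-p), i.e. right of the midpoint cut
  hits <- vapply(1:20, function(seed) {
    sim <- simulate_taxonic(synthetic_spec("taxonic", n = 600L, k = 3L,
                                           base_rate = 0.25, separation = 2,
                                           within_r = 0.1, seed = seed))
    cs <- mambac(sim$matrix, seed = seed)
    peak_at <- cs$averaged_curve$x[which.max(cs$averaged_curve$y)]
    peak_at > 300
  }, logical(1L))
  expect_gte(sum(hits), 16L)
})

test_that("mambac base-rate heuristic recovers a low taxon base rate", {
  est <- vapply(1:10, function(seed) {
    sim <- simulate_taxonic(synthetic_spec("taxonic", n = 600L, k = 3L,
                                           base_rate = 0.25, separation = 2,
                                           within_r = 0.1, seed = seed))
    mambac(sim$matrix, seed = seed)$base_rate_estimate
  }, numeric(1L))
  expect_lt(abs(mean(est) - 0.25), 0.12)
})
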