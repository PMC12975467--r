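test_that("loading selects and orders the requested columns", {
  path <- write_csv_fixture(data.frame(a = 1:3, b = 4:6, c = 7:9))
  m <- load_indicator_matrix(path, columns = c("a", "c"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(indicator_names(m), c("a", "c"))
  expect_equal(as.numeric(m[, "c"]), c(7, 8, 9))
  expect_error(load_indicator_matrix(path, columns = c("a", "zz")), "zz")
  expect_error(load_indicator_matrix(tempfile(), columns = "a"),
               "not found")
})

test_that("missing-value policy drops cases or fails with location info", {
  df <- data.frame(a = c(1, NA, 3), b = c(4, 5, 6))
  path <- write_csv_fixture(df)
  expect_message(m <- load_indicator_matrix(path, missing_policy = "drop_case"),
                 "1 case")
  expect_equal(n_cases(m), 2L)
  expect_equal(case_ids(m), c("1", "3"))
  expect_error(load_indicator_matrix(path, missing_policy = "fail"),
               "column 'a', row 2")
})

test_that("screening filter removes exactly the all-zero rows in place", {
  tab <- rbind(c(0, 0, 5), c(0, 1, 2), c(1, 0, 3))
  colnames(tab) <- c("s1", "s2", "y")
  res <- apply_screening_filter(tab, c("s1", "s2"))
  expect_equal(res$n_removed, 1L)
  expect_equal(unname(res$data[, "y"]), c(2, 3))

  # no qualifying row: identity with count 0
  res2 <- apply_screening_filter(tab[2:3, , drop = FALSE], c("s1", "s2"))
  expect_equal(res2$n_removed, 0L)
  expect_identical(res2$data, tab[2:3, , drop = FALSE])

  # enumeration oracle: 10 rows, 4 all-zero on the screening columns
  set.seed(42)
  big <- cbind(s1 = c(rep(0, 4), rpois(6, 2) + 1),
               s2 = rep(0, 10), y = rnorm(10))
  res3 <- apply_screening_filter(big, c("s1", "s2"))
  expect_equal(res3$n_removed, 4L)
  expect_equal(nrow(res3$data), 6L)
  # retained rows unmodified and in original order
  expect_equal(res3$data, big[big[, "s1"] != 0, , drop = FALSE])

  expect_error(apply_screening_filter(tab, "nope"), "unknown screening")
})

test_that("subscale scoring sums items per factor and is additive", {
  tab <- cbind(i1 = c(1, 0, 2), i2 = c(0, 0, 2), i3 = c(2, 0, 1),
               i4 = c(1, 0, 0))
  m <- score_subscales(tab, list(f1 = c("i1", "i2", "i3"), f2 = "i4"))
  expect_equal(indicator_names(m), c("f1", "f2"))
  expect_equal(as.numeric(m[, "f1"]), c(3, 0, 5))
  expect_equal(as.numeric(m[2, ]), c(0, 0))  # all-zero case scores zero

  # additivity: scoring a factor equals the sum of scoring its blocks
  whole <- score_subscales(tab, list(f = c("i1", "i2", "i3", "i4")))
  parts <- score_subscales(tab, list(a = c("i1", "i2"), b = c("i3", "i4")))
  expect_equal(as.numeric(whole[, "f"]),
               as.numeric(parts[, "a"] + parts[, "b"]))

  expect_error(score_subscales(tab, list(f1 = "i1", f2 = "i1")),
               "more than one factor")
  expect_error(score_subscales(tab, list(f1 = "i9")), "unknown item")
})

test_that("log10 transform is zero-safe, exact on decades, and monotone", {
  m <- indicator_matrix(cbind(a = c(0, 9, 99), b = c(1, 4, 9)))
  out <- log10_transform(m)
  expect_equal(as.numeric(out[, "a"]), c(0, 1, 2))
  expect_equal(dim(out), dim(m))
  expect_equal(indicator_names(out), indicator_names(m))
  # strict monotonicity on a random non-negative grid
  x <- sort(abs(rnorm(50)) * 10)
  y <- log10(x + 1)
  expect_true(all(diff(y) >= 0))
  expect_true(all(diff(y)[diff(x) > 0] > 0))
  expect_error(log10_transform(indicator_matrix(cbind(a = c(-1, 2, 3)))),
               "non-negative")
})

test_that("indicator matrix enforces its invariants", {
  expect_error(indicator_matrix(cbind(a = c(1, NA))), "missing")
  expect_error(indicator_matrix(matrix(1, 1, 2)), "two cases")
  m <- matrix(1:6, 3, 2)
  colnames(m) <- c("x", "x")
  expect_error(indicator_matrix(m), "unique")
})
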