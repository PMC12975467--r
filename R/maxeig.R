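#' MAXEIG curve for one input indicator
#'
#' Maximum-eigenvalue (generalized maximum-covariance) analysis: cases are
#' sorted on the input indicator and grouped into overlapping windows of
#' equal case count; within each window the covariance matrix of the
#' remaining indicators is computed, its diagonal set to zero, and the
#' statistic is the largest eigenvalue.  Under a taxonic structure the
#' mixture of classes inflates between-indicator covariance only in the
#' windows that straddle the class boundary, peaking the curve; a
#' dimensional structure gives a comparatively flat curve.
#'
#' With two output indicators the zero-diagonal covariance matrix has
#' eigenvalues `+|cov|` and `-|cov|`, so y reduces to the absolute
#' within-window covariance.  y is always non-negative (the matrix has zero
#' trace).
#'
#' @param input Numeric vector of length `n`.
#' @param outputs Numeric matrix, `n` rows and at least 2 columns.
#' @param n_windows Number of windows (default 50).
#' @param overlap Fractional overlap of consecutive windows (default 0.9).
#' @return A `taxo_curve`; x = mean of `input` within each window.
#' @export
maxeig_curve <- function(input, outputs, n_windows = 50L, overlap = 0.9) {
  outputs <- as.matrix(outputs)
  n <- length(input)
  if (nrow(outputs) != n) stop("input and outputs must have equal case count")
  if (ncol(outputs) < 2L) stop("MAXEIG needs at least 2 output indicators")
  size <- floor(n / (1 + (n_windows - 1) * (1 - overlap)))
  k <- ncol(outputs) + 1L
  if (size < k + 2L) {
    stop(sprintf("window of %d cases is below the minimum %d; lower n_windows",
                 size, k + 2L))
  }
  ord <- order(input)
  inp <- input[ord]
  out <- outputs[ord, , drop = FALSE]
  starts <- round(seq(1L, n - size + 1L, length.out = n_windows))
  xy <- vapply(starts, function(s) {
    idx <- s:(s + size - 1L)
    cv <- stats::cov(out[idx, , drop = FALSE])
    diag(cv) <- 0
    c(mean(inp[idx]), max(eigen(cv, symmetric = TRUE,
                                only.values = TRUE)$values))
  }, numeric(2L))
  x <- xy[1L, ]
  # ties in the input can make consecutive window means equal; nudge the
  # grid minimally so the curve keeps a strictly increasing x
  eps <- max(diff(range(x)), 1) * 1e-9
  x <- x + seq_along(x) * eps
  taxo_curve(x, xy[2L, ])
}

#' MAXEIG over all input indicators
#'
#' Runs [maxeig_curve()] once per indicator used as the sorting input, with
#' the remaining indicators as outputs (`k` panels), and averages the
#' panels pointwise.  The base-rate estimate is the proportion of cases
#' lying above the midpoint rank of the averaged curve's peak window — a
#' documented heuristic (windows are defined by case count, so the midpoint
#' rank is panel-invariant).
#'
#' @param matrix An [indicator_matrix()] with `k >= 3` columns.
#' @param n_windows,overlap Passed to [maxeig_curve()].
#' @return A `curve_set` with method `"MAXEIG"`.
#' @export
maxeig <- function(matrix, n_windows = 50L, overlap = 0.9) {
  m <- as.matrix(matrix)
  k <- ncol(m)
  if (k < 3L) stop("MAXEIG needs at least 3 indicators")
  n <- nrow(m)
  panels <- lapply(seq_len(k), function(i) {
    maxeig_curve(m[, i], m[, -i, drop = FALSE],
                 n_windows = n_windows, overlap = overlap)
  })
  names(panels) <- colnames(m)
  avg <- average_curves(panels)
  size <- floor(n / (1 + (n_windows - 1) * (1 - overlap)))
  starts <- round(seq(1L, n - size + 1L, length.out = n_windows))
  peak <- which.max(avg$y)
  mid_rank <- starts[peak] + size / 2
  p <- (n - mid_rank) / n
  curve_set("MAXEIG", panels, avg,
            base_rate_estimate = min(max(p, 1e-3), 1 - 1e-3))
}
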