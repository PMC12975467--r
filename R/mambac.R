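#' MAMBAC curve for one input/output indicator pair
#'
#' Mean Above Minus Below A Cut: cases are sorted on the input indicator and
#' a series of cuts is slid along the sorted order; at each cut the statistic
#' is the output indicator's mean above the cut minus its mean below.  A
#' latent class boundary produces a peaked curve, a continuous latent trait
#' a shallow dish.
#'
#' Cut positions are `n_cuts` evenly spaced ranks between case `end_offset`
#' and case `n - end_offset`; a cut at rank `c` puts cases `1..c` below and
#' `c+1..n` above.  Ties on the input are broken by a random permutation
#' (seed the caller's RNG; [mambac()] averages over replications).
#'
#' @param input,output Numeric vectors of equal length `n`.
#' @param n_cuts Number of cuts (default 50).
#' @param end_offset Cases left beyond the extreme cuts at each end
#'   (default 25), so every cut has stable means on both sides.
#' @return A `taxo_curve` with x = cut rank position, y = mean difference.
#' @export
mambac_curve <- function(input, output, n_cuts = 50L, end_offset = 25L) {
  n <- length(input)
  if (length(output) != n) stop("input and output must have equal length")
  if (n - 2L * end_offset + 1L < n_cuts) {
    stop(sprintf(
      "n = %d is too small for %d cuts with end offset %d; lower n_cuts",
      n, n_cuts, end_offset))
  }
  tie_break <- if (anyDuplicated(input)) stats::runif(n) else seq_len(n)
  ord <- order(input, tie_break)
  out_sorted <- output[ord]
  cuts <- unique(round(seq(end_offset, n - end_offset, length.out = n_cuts)))
  cs <- cumsum(out_sorted)
  tot <- cs[n]
  y <- (tot - cs[cuts]) / (n - cuts) - cs[cuts] / cuts
  taxo_curve(cuts, y)
}

#' MAMBAC over all ordered indicator pairs
#'
#' Runs [mambac_curve()] with every indicator as input against every other
#' indicator as output (`k(k-1)` panels).  When the input contains ties,
#' each panel is the mean over `replications` re-randomized tie orders;
#' tie-free panels are deterministic and computed once.  The averaged curve
#' is the pointwise mean over panels and the base-rate estimate is read
#' from the averaged curve's end heights (see Details).
#'
#' @details With the taxon as the high-scoring minority at base rate p, the
#' curve's left-end height approaches `delta * p` and its right-end height
#' `delta * (1 - p)` (delta the group separation), so after shifting the
#' averaged curve to be non-negative the end-height estimator is
#' `p_hat = y_first / (y_first + y_last)`.  This is a conventional
#' curve-end heuristic; it is reported, not used in the CCFI.
#'
#' @param matrix An [indicator_matrix()] with `k >= 2` columns.
#' @param n_cuts,end_offset Passed to [mambac_curve()].
#' @param replications Tie-order replications (default 10; ignored for
#'   tie-free inputs).
#' @param seed Optional integer seed for the tie-breaking RNG.
#' @return A `curve_set` with method `"MAMBAC"`.
#' @export
mambac <- function(matrix, n_cuts = 50L, end_offset = 25L,
                   replications = 10L, seed = NULL) {
  m <- as.matrix(matrix)
  k <- ncol(m)
  if (k < 2L) stop("MAMBAC needs at least 2 indicators")
  if (!is.null(seed)) set.seed(seed)
  panels <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      reps <- if (anyDuplicated(m[, i])) replications else 1L
      cvs <- lapply(seq_len(reps), function(r) {
        mambac_curve(m[, i], m[, j], n_cuts = n_cuts,
                     end_offset = end_offset)
      })
      panels[[sprintf("%s|%s", colnames(m)[i], colnames(m)[j])]] <-
        average_curves(cvs)
    }
  }
  avg <- average_curves(panels)
  curve_set("MAMBAC", panels, avg,
            base_rate_estimate = mambac_base_rate(avg))
}

# end-height heuristic on the averaged curve, shifted just enough to be
# non-negative (an already non-negative curve is left untouched)
mambac_base_rate <- function(curve) {
  y <- curve$y - min(0, min(curve$y))
  denom <- y[1L] + y[length(y)]
  if (denom <= 0) return(NA_real_)
  p <- y[1L] / denom
  min(max(p, 1e-3), 1 - 1e-3)
}
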