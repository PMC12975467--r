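#' Per-indicator descriptive statistics
#'
#' Mean, standard deviation (n - 1 denominator), skewness (standardized
#' third moment) and excess kurtosis (standardized fourth moment minus 3)
#' for each indicator, used to screen indicator shape before the taxometric
#' procedures.  A constant indicator yields `NA` skewness/kurtosis and is
#' flagged, never silently zeroed.
#'
#' @param matrix An [indicator_matrix()], `n >= 3`.
#' @return A data frame with columns `indicator`, `mean`, `sd`, `skewness`,
#'   `kurtosis` (excess), `degenerate` (logical; `TRUE` for sd = 0).
#' @export
descriptives <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 3L) stop("descriptives need at least 3 cases")
  one <- function(x) {
    mu <- mean(x)
    s <- stats::sd(x)
    cx <- x - mu
    m2 <- mean(cx^2)
    if (m2 <= 0) {
      return(c(mean = mu, sd = s, skewness = NA_real_,
               kurtosis = NA_real_, degenerate = 1))
    }
    c(mean = mu, sd = s,
      skewness = mean(cx^3) / m2^1.5,
      kurtosis = mean(cx^4) / m2^2 - 3,
      degenerate = 0)
  }
  stats <- t(apply(m, 2L, one))
  out <- data.frame(indicator = colnames(m), stats, row.names = NULL)
  out$degenerate <- out$degenerate == 1
  if (any(out$degenerate)) {
    warning("constant indicator(s): skewness/kurtosis undefined for ",
            paste(out$indicator[out$degenerate], collapse = ", "))
  }
  out
}

#' Putative taxon/complement classification at an assumed base rate
#'
#' Operationalizes "the extremes of the sample": each indicator is
#' standardized, the per-case standardized total is ranked, and the top
#' `round(n * base_rate)` cases are flagged as the putative taxon.  Ties at
#' the classification boundary are broken by stable original case order
#' (reproducibility over randomness) with a warning.
#'
#' @param matrix An [indicator_matrix()].
#' @param base_rate Assumed taxon base rate, in (0, 1).
#' @return A list of class `"taxo_membership"` with `flags` (integer 0/1
#'   vector, 1 = putative taxon), `taxon_count`, and `base_rate`.
#' @export
classify_putative_groups <- function(matrix, base_rate) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (!is.numeric(base_rate) || base_rate <= 0 || base_rate >= 1) {
    stop("base_rate must lie strictly between 0 and 1")
  }
  taxon_count <- round(n * base_rate)
  if (taxon_count < 1L || taxon_count > n - 1L) {
    stop(sprintf("base rate %.3f gives a group of size %d outside [1, n-1]",
                 base_rate, taxon_count))
  }
  z <- scale(m)
  z[is.nan(z)] <- 0  # constant column: contributes nothing to the ranking
  total <- unname(rowSums(z))
  ord <- order(-total, seq_len(n))  # stable: original order breaks ties
  top <- ord[seq_len(taxon_count)]
  if (taxon_count < n &&
      isTRUE(all.equal(total[ord[taxon_count]], total[ord[taxon_count + 1L]]))) {
    warning("ties at the classification boundary broken by case order")
  }
  flags <- integer(n)
  flags[top] <- 1L
  structure(list(flags = flags, taxon_count = taxon_count,
                 base_rate = base_rate),
            class = "taxo_membership")
}

#' Cohen's d between putative groups, per indicator
#'
#' `d = (mean_taxon - mean_complement) / pooled sd`, with the pooled sd
#' `sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`.  The sign is preserved:
#' an indicator on which the putative taxon scores *lower* yields a negative
#' d.  A zero pooled sd yields `NA` with a warning (undefined d).
#'
#' @param matrix An [indicator_matrix()].
#' @param groups A `"taxo_membership"` from [classify_putative_groups()],
#'   or a 0/1 vector of length `n`.
#' @return Named numeric vector of d values, one per indicator.
#' @export
cohens_d <- function(matrix, groups) {
  m <- as.matrix(matrix)
  flags <- if (inherits(groups, "taxo_membership")) groups$flags else groups
  flags <- as.integer(flags)
  if (length(flags) != nrow(m)) stop("group flags must match the case count")
  n1 <- sum(flags == 1L)
  n2 <- sum(flags == 0L)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 cases")
  d <- vapply(seq_len(ncol(m)), function(j) {
    x1 <- m[flags == 1L, j]
    x2 <- m[flags == 0L, j]
    sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
      (n1 + n2 - 2)
    if (sp2 <= 0) return(NA_real_)
    (mean(x1) - mean(x2)) / sqrt(sp2)
  }, numeric(1L))
  names(d) <- colnames(m)
  if (anyNA(d)) {
    warning("pooled sd is zero for: ",
            paste(names(d)[is.na(d)], collapse = ", "))
  }
  d
}

#' Indicator validity gate
#'
#' Retains the indicators whose Cohen's d against the putative-group split
#' meets the validity threshold (inclusive: `d >= threshold`), preserving
#' input order.  Taxometric analysis requires a minimum of three valid
#' indicators; fewer is a structural error naming the offenders.
#'
#' @param d_values Named numeric vector of per-indicator d values.
#' @param threshold Validity cutoff, 1.25 by default.
#' @param min_valid Minimum surviving indicators before the gate aborts
#'   (default 3).
#' @return Character vector of valid indicator names, in input order.
#' @export
#' @examples
#' d <- c(s1 = 0.31, s2 = -0.01, s3 = 2.75, s4 = 2.25, s5 = 3.67)
#' filter_valid_indicators(d)  # s3, s4, s5
filter_valid_indicators <- function(d_values, threshold = 1.25,
                                    min_valid = 3L) {
  if (is.null(names(d_values))) {
    names(d_values) <- paste0("ind", seq_along(d_values))
  }
  valid <- !is.na(d_values) & d_values >= threshold
  keep <- names(d_values)[valid]
  if (length(keep) < min_valid) {
    stop(sprintf(
      "only %d indicator(s) reach d >= %.2f (need %d); invalid: %s",
      length(keep), threshold, min_valid,
      paste(sprintf("%s (d = %.2f)", names(d_values)[!valid],
                    d_values[!valid]), collapse = ", ")),
      call. = FALSE)
  }
  keep
}

#' Full validity report for an indicator set
#'
#' Combines [descriptives()], the putative classification and [cohens_d()]
#' into the per-indicator screening table (the analysis report's validity
#' block): mean, sd, skewness, excess kurtosis, d, and the valid flag.
#'
#' @inheritParams classify_putative_groups
#' @param threshold Validity cutoff on d (inclusive), default 1.25.
#' @return A data frame of class `"validity_report"`; attributes `threshold`
#'   and `base_rate` record the gate settings.
#' @export
validity_report <- function(matrix, base_rate = 0.25, threshold = 1.25) {
  desc <- descriptives(matrix)
  groups <- classify_putative_groups(matrix, base_rate)
  d <- cohens_d(matrix, groups)
  desc$d <- unname(d)
  desc$valid <- !is.na(d) & d >= threshold
  desc$degenerate <- NULL
  attr(desc, "threshold") <- threshold
  attr(desc, "base_rate") <- base_rate
  class(desc) <- c("validity_report", "data.frame")
  desc
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("Indicator validity (d >= %.2f at assumed base rate %.3f)\n",
              attr(x, "threshold"), attr(x, "base_rate")))
  print.data.frame(cbind(x[1L],
                         round(as.data.frame(x[2:6]), 2L),
                         x["valid"]), row.names = FALSE)
  invisible(x)
}
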