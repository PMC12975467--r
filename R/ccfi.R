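#' Root-mean-square residual between two curves
#'
#' The fit measure feeding the comparison curve fit index: the square root
#' of the mean squared pointwise difference between the empirical curve and
#' a comparison ensemble's mean curve.  Curves must share one length (and,
#' for grid-based methods, one x grid); comparison is pointwise by index.
#'
#' @param empirical,simulated_mean `taxo_curve` objects (or x/y lists) of
#'   equal length.
#' @return Non-negative scalar.
#' @export
curve_rmsr <- function(empirical, simulated_mean) {
  if (length(empirical$y) != length(simulated_mean$y)) {
    stop("curves differ in length; empirical and comparison runs must use identical settings")
  }
  sqrt(mean((empirical$y - simulated_mean$y)^2))
}

#' Comparison curve fit index
#'
#' `CCFI = fit_dim / (fit_dim + fit_tax)` where each fit is the RMSR of the
#' empirical curve against the corresponding comparison ensemble's mean
#' curve.  0 indicates a dimensional structure, 1 a taxonic one; swapping
#' the two fits maps c to 1 - c.  If both fits are exactly 0 (degenerate)
#' the index is reported as 0.5 with a warning.
#'
#' @param fit_dim,fit_tax Non-negative fit (RMSR) values.
#' @return Scalar in \[0, 1\].
#' @export
compute_ccfi <- function(fit_dim, fit_tax) {
  if (fit_dim < 0 || fit_tax < 0) stop("fit values must be non-negative")
  if (fit_dim + fit_tax == 0) {
    warning("both fits are zero; CCFI undefined, reporting 0.5")
    return(0.5)
  }
  fit_dim / (fit_dim + fit_tax)
}

#' Interpret a CCFI value against the ambiguity band
#'
#' Values below 0.40 support a dimensional structure, above 0.60 a taxonic
#' one; values in \[0.40, 0.60\] (bounds included) are ambiguous.
#'
#' @param ccfi Scalar in \[0, 1\].
#' @return `"dimensional"`, `"ambiguous"` or `"taxonic"`.
#' @export
interpret_ccfi <- function(ccfi) {
  if (is.na(ccfi)) return(NA_character_)
  if (ccfi < 0.40) "dimensional" else if (ccfi > 0.60) "taxonic" else "ambiguous"
}

#' Summarize per-method CCFIs
#'
#' Computes the unweighted mean CCFI across methods — the quantity the
#' analysis is interpreted on — and its band label.  Aggregation uses full
#' precision; rounding to 2 decimals happens only in reports.
#'
#' @param results Either a named numeric vector of per-method CCFI values,
#'   or a list of per-method result lists each carrying `ccfi`, `fit_dim`,
#'   `fit_tax`.
#' @return A list of class `"ccfi_summary"`: `per_method` (data frame),
#'   `mean_ccfi`, `interpretation`.
#' @export
#' @examples
#' summarize_ccfi(c(mambac = 0.58, maxeig = 0.36, lmode = 0.44))
summarize_ccfi <- function(results) {
  if (is.numeric(results)) {
    per_method <- data.frame(method = names(results),
                             fit_tax = NA_real_, fit_dim = NA_real_,
                             ccfi = unname(results))
  } else {
    per_method <- data.frame(
      method = names(results),
      fit_tax = vapply(results, function(r) r$fit_tax %||% NA_real_, 1),
      fit_dim = vapply(results, function(r) r$fit_dim %||% NA_real_, 1),
      ccfi = vapply(results, `[[`, numeric(1L), "ccfi"))
  }
  if (nrow(per_method) < 1L) stop("need at least one method result")
  mean_ccfi <- mean(per_method$ccfi, na.rm = TRUE)
  structure(list(per_method = per_method, mean_ccfi = mean_ccfi,
                 interpretation = interpret_ccfi(mean_ccfi)),
            class = "ccfi_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ccfi_summary <- function(x, ...) {
  df <- x$per_method
  df$ccfi <- round(df$ccfi, 2L)
  print.data.frame(df[, c("method", "ccfi")], row.names = FALSE)
  cat(sprintf("mean CCFI = %.2f (%s)\n", x$mean_ccfi, x$interpretation))
  invisible(x)
}

#' Per-method mean of base-rate estimates
#'
#' Collects each method's base-rate estimate from its curve set and returns
#' them with their unweighted mean; undefined estimates are omitted from
#' the mean with a warning.
#'
#' @param curve_sets Named list of `curve_set` objects (or a named numeric
#'   vector of estimates).
#' @return List with `per_method` (named numeric) and `mean`.
#' @export
#' @examples
#' estimate_base_rates(c(mambac = 0.31, maxeig = 0.15, lmode = 0.62))$mean
estimate_base_rates <- function(curve_sets) {
  est <- if (is.numeric(curve_sets)) curve_sets else
    vapply(curve_sets, `[[`, numeric(1L), "base_rate_estimate")
  if (all(is.na(est))) stop("no method produced a defined base-rate estimate")
  if (anyNA(est)) {
    warning("undefined base-rate estimate(s) omitted from the mean: ",
            paste(names(est)[is.na(est)], collapse = ", "))
  }
  list(per_method = est, mean = mean(est, na.rm = TRUE))
}

#' CCFI profile across assumed taxon base rates
#'
#' Recomputes the per-method CCFI over a grid of assumed taxon base rates
#' (default 0.025 to 0.975 in steps of 0.025), relaxing the single fixed
#' base-rate assumption.  The dimensional ensemble does not depend on the
#' base rate and is generated once; the taxonic ensemble is regenerated at
#' every feasible grid rate.  Rates whose putative groups are too small to
#' estimate within-group correlations are skipped with a warning, never
#' clamped.
#'
#' @param matrix An [indicator_matrix()] of valid indicators.
#' @param grid Base-rate grid (strictly increasing, inside (0, 1)).
#' @param methods Methods to run.
#' @param n_sets Simulated datasets per structure and rate.
#' @param settings [taxo_settings()].
#' @param seed Integer seed.
#' @return A list of class `"ccfi_profile"`: `grid` (feasible rates),
#'   `ccfi` (rate x method matrix), `aggregate_curve` (mean over methods
#'   per rate), `per_method_aggregate` (mean over rates per method),
#'   `overall_mean` (mean of the per-method aggregates), `skipped` (the
#'   infeasible rates).
#' @export
ccfi_profile <- function(matrix,
                         grid = seq(0.025, 0.975, by = 0.025),
                         methods = c("mambac", "maxeig", "lmode"),
                         n_sets = 100L,
                         settings = taxo_settings(),
                         seed = NULL) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  k <- ncol(m)
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid >= 1)) {
    stop("base-rate grid must be strictly increasing inside (0, 1)")
  }
  sizes <- round(n * grid)
  feasible <- pmin(sizes, n - sizes) >= (k + 2L)
  if (!any(feasible)) stop("no feasible base rate on the grid")
  if (any(!feasible)) {
    warning("skipping infeasible base rate(s): ",
            paste(format(grid[!feasible]), collapse = ", "))
  }
  rates <- grid[feasible]
  if (!is.null(seed)) set.seed(seed)
  seed_emp <- sample.int(.Machine$integer.max - 1L, 1L)
  seed_dim <- sample.int(.Machine$integer.max - 1L, 1L)
  seed_tax <- sample.int(.Machine$integer.max - 1L, length(rates))

  set.seed(seed_emp)
  empirical <- compute_method_curves(m, methods, settings)
  settings <- lock_lmode_grid(settings, empirical)
  dim_ens <- generate_dimensional_comparison(m, n_sets = n_sets,
                                             settings = settings,
                                             methods = methods,
                                             seed = seed_dim)
  ccfi_mat <- matrix(NA_real_, length(rates), length(methods),
                     dimnames = list(format(rates), methods))
  for (i in seq_along(rates)) {
    tax_ens <- generate_taxonic_comparison(m, base_rate = rates[i],
                                           n_sets = n_sets,
                                           settings = settings,
                                           methods = methods,
                                           seed = seed_tax[i])
    for (mtd in methods) {
      fit_tax <- curve_rmsr(empirical[[mtd]]$averaged_curve,
                            tax_ens$mean_curve[[mtd]])
      fit_dim <- curve_rmsr(empirical[[mtd]]$averaged_curve,
                            dim_ens$mean_curve[[mtd]])
      ccfi_mat[i, mtd] <- compute_ccfi(fit_dim, fit_tax)
    }
  }
  aggregate_curve <- rowMeans(ccfi_mat)
  per_method_aggregate <- colMeans(ccfi_mat)
  structure(list(grid = rates, ccfi = ccfi_mat,
                 aggregate_curve = aggregate_curve,
                 per_method_aggregate = per_method_aggregate,
                 overall_mean = mean(per_method_aggregate),
                 skipped = grid[!feasible]),
            class = "ccfi_profile")
}

#' @export
print.ccfi_profile <- function(x, ...) {
  cat(sprintf("<ccfi_profile: %d base rates x %d methods>\n",
              length(x$grid), ncol(x$ccfi)))
  cat("per-method aggregates:",
      paste(sprintf("%s = %.2f", names(x$per_method_aggregate),
                    x$per_method_aggregate), collapse = ", "), "\n")
  cat(sprintf("overall mean = %.2f\n", x$overall_mean))
  invisible(x)
}
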