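#' Method settings for a taxometric run
#'
#' Bundles the tuning parameters shared by the empirical run and every
#' comparison-data run (the curve-length contract requires identical
#' settings on both sides).
#'
#' @param n_cuts,end_offset MAMBAC cuts and end offset ([mambac()]).
#' @param replications MAMBAC tie-order replications.
#' @param n_windows,overlap MAXEIG windows ([maxeig()]).
#' @param grid_points,bandwidth L-Mode density grid and bandwidth rule
#'   ([lmode()]).
#' @param lmode_range Optional fixed density grid range; when `NULL` the
#'   pipeline locks it to the empirical run's range so simulated curves
#'   share the grid.
#' @param max_iter,corr_tol Comparison-data generator controls
#'   ([gen_data_matched()]).
#' @return A list of class `"taxo_settings"`.
#' @export
taxo_settings <- function(n_cuts = 50L, end_offset = 25L, replications = 10L,
                          n_windows = 50L, overlap = 0.9,
                          grid_points = 512L, bandwidth = "nrd0",
                          lmode_range = NULL,
                          max_iter = 100L, corr_tol = 0.01) {
  structure(list(n_cuts = n_cuts, end_offset = end_offset,
                 replications = replications, n_windows = n_windows,
                 overlap = overlap, grid_points = grid_points,
                 bandwidth = bandwidth, lmode_range = lmode_range,
                 max_iter = max_iter, corr_tol = corr_tol),
            class = "taxo_settings")
}

# run the requested methods on one dataset; returns a named list of
# curve_set objects (uses the caller's RNG stream for MAMBAC tie-breaking)
compute_method_curves <- function(matrix, methods, settings) {
  m <- as.matrix(matrix)
  out <- list()
  if ("mambac" %in% methods) {
    out$mambac <- mambac(m, n_cuts = settings$n_cuts,
                         end_offset = settings$end_offset,
                         replications = settings$replications)
  }
  if ("maxeig" %in% methods) {
    out$maxeig <- maxeig(m, n_windows = settings$n_windows,
                         overlap = settings$overlap)
  }
  if ("lmode" %in% methods) {
    res <- suppressWarnings(
      lmode(m, grid_points = settings$grid_points,
            bandwidth = settings$bandwidth,
            grid_range = settings$lmode_range))
    out$lmode <- lmode_curve_set(res)
  }
  out
}

# after the empirical run, freeze the L-Mode density grid so every
# comparison dataset is evaluated on the same x grid
lock_lmode_grid <- function(settings, empirical_curves) {
  if (is.null(settings$lmode_range) && !is.null(empirical_curves$lmode)) {
    g <- empirical_curves$lmode$averaged_curve$x
    settings$lmode_range <- range(g)
  }
  settings
}

#' Analysis run configuration
#'
#' Collects every knob of the end-to-end analysis into one validated
#' object, echoed verbatim into the report for reproducibility.
#'
#' @param input Path to a delimited input file, or an [indicator_matrix()]
#'   / numeric matrix supplied directly.
#' @param columns Indicator columns to load (`NULL` = all).
#' @param screening_columns Optional screening-item columns: cases scoring
#'   0 on *all* of them are excluded before analysis.
#' @param scoring_map Optional named list mapping factor names to item
#'   columns; items are sum-scored into the analysis indicators.
#' @param log10 Apply the zero-safe base-10 log transform
#'   ([log10_transform()]) before analysis.
#' @param base_rate Assumed taxon base rate (default 0.25).
#' @param methods Subset of `c("mambac", "maxeig", "lmode")`.
#' @param n_sets Simulated comparison datasets per structure (default 100).
#' @param validity_threshold Cohen's d validity cutoff (default 1.25).
#' @param enforce_validity Abort when fewer than 3 indicators pass the
#'   gate (default `TRUE`); `FALSE` analyses all indicators and only
#'   reports validity.
#' @param profile Also compute the CCFI profile.
#' @param profile_grid Base-rate grid for the profile.
#' @param profile_n_sets Simulated sets per profile rate (defaults to
#'   `n_sets`).
#' @param settings [taxo_settings()].
#' @param seed Master integer seed; per-stage child seeds are derived by
#'   fixed offsets so toggling one stage never perturbs another.
#' @param out_dir Optional output directory for [write_report()].
#' @param missing_policy,delimiter Passed to [load_indicator_matrix()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input, columns = NULL, screening_columns = NULL,
                       scoring_map = NULL, log10 = FALSE,
                       base_rate = 0.25,
                       methods = c("mambac", "maxeig", "lmode"),
                       n_sets = 100L, validity_threshold = 1.25,
                       enforce_validity = TRUE,
                       profile = FALSE,
                       profile_grid = seq(0.025, 0.975, by = 0.025),
                       profile_n_sets = n_sets,
                       settings = taxo_settings(), seed = 1L,
                       out_dir = NULL,
                       missing_policy = "fail", delimiter = ",") {
  methods <- match.arg(methods, several.ok = TRUE)
  if (base_rate <= 0 || base_rate >= 1) {
    stop("base_rate must lie strictly between 0 and 1")
  }
  structure(list(input = input, columns = columns,
                 screening_columns = screening_columns,
                 scoring_map = scoring_map, log10 = log10,
                 base_rate = base_rate, methods = methods,
                 n_sets = as.integer(n_sets),
                 validity_threshold = validity_threshold,
                 enforce_validity = enforce_validity,
                 profile = profile, profile_grid = profile_grid,
                 profile_n_sets = as.integer(profile_n_sets),
                 settings = settings, seed = as.integer(seed),
                 out_dir = out_dir, missing_policy = missing_policy,
                 delimiter = delimiter),
            class = "run_config")
}

# fixed per-stage seed offsets (kept far apart; all < 2^31 for any small
# master seed)
stage_seed <- function(seed, stage) {
  offsets <- c(load = 0L, empirical = 11001L, dimensional = 22002L,
               taxonic = 33003L, profile = 44004L)
  (seed + offsets[[stage]]) %% (.Machine$integer.max - 1L)
}

#' Run the full taxometric analysis
#'
#' Executes, in order: load (or accept) the indicator data, optional
#' screening filter, optional subscale scoring, optional log transform,
#' descriptive screening and the Cohen's d validity gate, dimensional and
#' taxonic comparison-data ensembles at the assumed base rate, the three
#' curve procedures on the empirical and all simulated datasets, the
#' per-method CCFIs, their mean and band interpretation, base-rate
#' estimates, and (optionally) the CCFI profile.  With `out_dir` set the
#' full report file set is written via [write_report()].  Identical config
#' and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `"taxo_result"`: `validity`
#'   (a [validity_report()]), `valid_indicators`, `curve_sets` (empirical,
#'   per method), `ensembles` (`taxonic`, `dimensional`), `ccfi`
#'   (a `ccfi_summary`), `base_rates`, `profile` (or `NULL`), `n_cases`,
#'   `n_removed`, `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # --- load ------------------------------------------------------------
  if (is.character(config$input)) {
    m <- load_indicator_matrix(config$input, columns = NULL,
                               missing_policy = config$missing_policy,
                               delimiter = config$delimiter)
  } else {
    m <- as.matrix(config$input)
    if (is.null(colnames(m))) colnames(m) <- paste0("ind", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  }
  n_removed <- 0L
  if (!is.null(config$screening_columns)) {
    flt <- apply_screening_filter(m, config$screening_columns)
    m <- flt$data
    n_removed <- flt$n_removed
  }
  if (!is.null(config$scoring_map)) {
    m <- score_subscales(m, config$scoring_map)
  } else if (!is.null(config$columns)) {
    missing_cols <- setdiff(config$columns, colnames(m))
    if (length(missing_cols)) {
      stop("unknown indicator column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    m <- m[, config$columns, drop = FALSE]
  }
  m <- indicator_matrix(m)
  if (config$log10) m <- log10_transform(m)

  # --- validity gate ---------------------------------------------------
  validity <- validity_report(m, base_rate = config$base_rate,
                              threshold = config$validity_threshold)
  if (config$enforce_validity) {
    valid <- filter_valid_indicators(
      stats::setNames(validity$d, validity$indicator),
      threshold = config$validity_threshold)
  } else {
    valid <- validity$indicator
  }
  mv <- indicator_matrix(as.matrix(m)[, valid, drop = FALSE])

  # --- empirical curves ------------------------------------------------
  set.seed(stage_seed(config$seed, "empirical"))
  empirical <- compute_method_curves(mv, config$methods, config$settings)
  settings <- lock_lmode_grid(config$settings, empirical)

  # --- comparison ensembles -------------------------------------------
  dim_ens <- generate_dimensional_comparison(
    mv, n_sets = config$n_sets, settings = settings,
    methods = config$methods, seed = stage_seed(config$seed, "dimensional"))
  tax_ens <- generate_taxonic_comparison(
    mv, base_rate = config$base_rate, n_sets = config$n_sets,
    settings = settings, methods = config$methods,
    seed = stage_seed(config$seed, "taxonic"))

  # --- CCFI ------------------------------------------------------------
  per_method <- lapply(config$methods, function(mtd) {
    fit_tax <- curve_rmsr(empirical[[mtd]]$averaged_curve,
                          tax_ens$mean_curve[[mtd]])
    fit_dim <- curve_rmsr(empirical[[mtd]]$averaged_curve,
                          dim_ens$mean_curve[[mtd]])
    list(fit_tax = fit_tax, fit_dim = fit_dim,
         ccfi = compute_ccfi(fit_dim, fit_tax))
  })
  names(per_method) <- config$methods
  ccfi <- summarize_ccfi(per_method)
  base_rates <- suppressWarnings(estimate_base_rates(empirical))

  # --- profile ---------------------------------------------------------
  profile <- NULL
  if (config$profile) {
    profile <- ccfi_profile(mv, grid = config$profile_grid,
                            methods = config$methods,
                            n_sets = config$profile_n_sets,
                            settings = settings,
                            seed = stage_seed(config$seed, "profile"))
  }

  result <- structure(
    list(validity = validity, valid_indicators = valid,
         curve_sets = empirical,
         ensembles = list(taxonic = tax_ens, dimensional = dim_ens),
         ccfi = ccfi, base_rates = base_rates, profile = profile,
         n_cases = nrow(mv), n_removed = n_removed, config = config),
    class = "taxo_result")
  if (!is.null(config$out_dir)) write_report(result, config$out_dir)
  result
}

#' @export
print.taxo_result <- function(x, ...) {
  cat(sprintf("Taxometric analysis: %d cases, %d valid indicator(s) [%s]\n",
              x$n_cases, length(x$valid_indicators),
              paste(x$valid_indicators, collapse = ", ")))
  print(x$ccfi)
  cat(sprintf("base-rate estimates: %s; mean = %.2f\n",
              paste(sprintf("%s = %.2f", names(x$base_rates$per_method),
                            x$base_rates$per_method), collapse = ", "),
              x$base_rates$mean))
  if (!is.null(x$profile)) print(x$profile)
  invisible(x)
}

#' Sensitivity re-analysis over configuration variants
#'
#' Re-runs the pipeline under a list of configuration deltas (e.g. with and
#' without the screening filter, with and without the log transform) using
#' a shared master seed, and tabulates the per-method CCFIs and mean per
#' variant.  A variant that errors is reported in the table and does not
#' stop the remaining variants.
#'
#' @param config Baseline [run_config()].
#' @param variants Named list of lists; each inner list overrides fields of
#'   the baseline config.
#' @return A list of class `"sensitivity_table"`: `table` (variant x
#'   method CCFI + mean + interpretation data frame), `results` (full
#'   per-variant results or error conditions).
#' @export
run_sensitivity <- function(config, variants) {
  stopifnot(inherits(config, "run_config"))
  if (!length(variants)) stop("variant list must not be empty")
  if (is.null(names(variants)) || any(names(variants) == "")) {
    stop("variants must be named")
  }
  results <- lapply(names(variants), function(vn) {
    cfg <- config
    for (field in names(variants[[vn]])) {
      cfg[[field]] <- variants[[vn]][[field]]
    }
    cfg$out_dir <- NULL
    tryCatch(run_full_analysis(cfg), error = function(e) e)
  })
  names(results) <- names(variants)
  rows <- lapply(names(results), function(vn) {
    r <- results[[vn]]
    if (inherits(r, "error")) {
      return(data.frame(variant = vn, mean_ccfi = NA_real_,
                        interpretation = paste("error:", conditionMessage(r))))
    }
    row <- data.frame(variant = vn, mean_ccfi = r$ccfi$mean_ccfi,
                      interpretation = r$ccfi$interpretation)
    for (i in seq_len(nrow(r$ccfi$per_method))) {
      row[[paste0("ccfi_", r$ccfi$per_method$method[i])]] <-
        r$ccfi$per_method$ccfi[i]
    }
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  structure(list(table = do.call(rbind, rows), results = results),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  df <- x$table
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, 2L)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
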