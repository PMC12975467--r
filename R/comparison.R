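#' RMSR between two correlation matrices
#'
#' Root mean squared residual over the below-diagonal elements — the
#' convergence and quality metric of the comparison-data generator.
#'
#' @param a,b Square symmetric matrices of equal dimension.
#' @return Non-negative scalar.
#' @export
cor_rmsr <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("correlation matrices differ in dimension")
  lt <- lower.tri(a)
  sqrt(mean((a[lt] - b[lt])^2))
}

# repair a symmetric matrix into a positive semi-definite correlation
# matrix: clip eigenvalues at `floor`, rebuild, renormalize the diagonal
repair_correlation <- function(R, floor = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < floor) {
    vals <- pmax(e$values, floor)
    R <- e$vectors %*% (vals * t(e$vectors))
    R <- stats::cov2cor(R)
  }
  R
}

#' Generate one dataset matching target correlations and exact marginals
#'
#' The simulated-comparison-data primitive: produces an `n x k` dataset
#' whose columns are *exactly* permutations of the supplied marginal value
#' vectors and whose correlation matrix approximates `target_corr`.  The
#' algorithm iterates: (1) draw a latent multivariate normal sample from an
#' intermediate correlation matrix (initialized at the target), (2) replace
#' each column by its marginal vector reordered to the latent column's
#' ranks, (3) measure the achieved correlations, (4) add the residual
#' (target minus achieved) to the intermediate matrix and repair it to a
#' valid correlation matrix, keeping the best iterate by correlation RMSR.
#'
#' @param target_corr Symmetric k x k correlation matrix (unit diagonal;
#'   marginally indefinite inputs are repaired by eigenvalue clipping).
#' @param marginals List of k numeric vectors, each of length `n` — the
#'   values each output column must reproduce exactly (typically bootstrap
#'   resamples of the empirical columns).
#' @param max_iter Iteration cap (default 100); the search also stops after
#'   10 non-improving iterations or once RMSR falls below `tol`.
#' @param tol Early-exit RMSR (default 0.01).
#' @param seed Optional integer seed.
#' @return The best `n x k` matrix found, with attributes `rmsr` (achieved
#'   correlation RMSR) and `iterations`.
#' @export
gen_data_matched <- function(target_corr, marginals, max_iter = 100L,
                             tol = 0.01, seed = NULL) {
  target_corr <- as.matrix(target_corr)
  k <- ncol(target_corr)
  if (k < 2L) stop("need at least 2 indicators")
  if (nrow(target_corr) != k) stop("target correlation matrix must be square")
  if (max(abs(target_corr - t(target_corr))) > 1e-8) {
    stop("target correlation matrix must be symmetric")
  }
  if (length(marginals) != k) stop("need one marginal vector per indicator")
  n <- length(marginals[[1L]])
  if (any(lengths(marginals) != n)) stop("marginal vectors differ in length")
  if (!is.null(seed)) set.seed(seed)

  sorted_marg <- lapply(marginals, sort)
  R_int <- repair_correlation(target_corr)
  best <- NULL
  best_rmsr <- Inf
  stall <- 0L
  iter_used <- 0L
  for (iter in seq_len(max_iter)) {
    iter_used <- iter
    e <- eigen(R_int, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 1e-6)), k)
    Z <- matrix(stats::rnorm(n * k), n, k) %*% t(L)
    X <- matrix(0, n, k)
    for (j in seq_len(k)) {
      X[order(Z[, j]), j] <- sorted_marg[[j]]
    }
    achieved <- suppressWarnings(stats::cor(X))
    achieved[!is.finite(achieved)] <- 0  # constant marginal: no correlation
    diag(achieved) <- 1
    rmsr <- cor_rmsr(target_corr, achieved)
    if (rmsr < best_rmsr) {
      best <- X
      best_rmsr <- rmsr
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (best_rmsr < tol || stall >= 10L) break
    R_int <- repair_correlation(R_int + (target_corr - achieved))
  }
  colnames(best) <- colnames(target_corr)
  attr(best, "rmsr") <- best_rmsr
  attr(best, "iterations") <- iter_used
  best
}

# draw the per-set bootstrap (or exact) marginals for a block of cases
draw_marginals <- function(block, exact) {
  lapply(seq_len(ncol(block)), function(j) {
    col <- block[, j]
    if (exact) col else sample(col, length(col), replace = TRUE)
  })
}

#' Comparison-data ensembles
#'
#' Generate `n_sets` simulated datasets that reproduce the empirical data's
#' marginal distributions and correlation structure under one candidate
#' latent structure, compute the taxometric curves on each with the same
#' settings as the empirical run, and summarize them as a mean curve plus a
#' pointwise variability envelope per method.
#'
#' `generate_dimensional_comparison()` matches the whole-sample correlation
#' matrix and marginals — one continuous latent structure.
#' `generate_taxonic_comparison()` first splits the sample into putative
#' taxon and complement via [classify_putative_groups()] at `base_rate`,
#' matches each group's own correlations and marginals, and concatenates
#' the groups (taxon count = `round(n * base_rate)`) — a two-class latent
#' structure with the same observable characteristics.
#'
#' @param matrix An [indicator_matrix()] with at least 3 indicators.
#' @param n_sets Number of simulated datasets (default 100).
#' @param settings Method settings from [taxo_settings()].
#' @param methods Character subset of `c("mambac", "maxeig", "lmode")`.
#' @param seed Integer seed; each simulated set draws from an independent
#'   child stream so the ensemble reproduces exactly.
#' @param exact_marginals If `TRUE`, reuse the empirical column values
#'   verbatim instead of bootstrap-resampling them (debugging aid).
#' @return A list of class `"comparison_ensemble"`: `structure`, `n_sets`,
#'   `curves` (per method, list of per-set averaged curves), `mean_curve`,
#'   `envelope` (`lo`/`hi` pointwise range), `rmsr` (per-set achieved
#'   correlation RMSRs), `datasets` (kept only when `keep_data = TRUE`).
#' @param keep_data Retain the simulated matrices (default `FALSE`).
#' @name comparison_ensembles
NULL

#' @rdname comparison_ensembles
#' @export
generate_dimensional_comparison <- function(matrix, n_sets = 100L,
                                            settings = taxo_settings(),
                                            methods = c("mambac", "maxeig", "lmode"),
                                            seed = NULL,
                                            exact_marginals = FALSE,
                                            keep_data = FALSE) {
  m <- as.matrix(matrix)
  if (ncol(m) < 3L) stop("comparison data need at least 3 valid indicators")
  target <- stats::cor(m)
  gen_one <- function() {
    marg <- draw_marginals(m, exact_marginals)
    gen_data_matched(target, marg, max_iter = settings$max_iter,
                     tol = settings$corr_tol)
  }
  build_ensemble("dimensional", gen_one, n_sets, settings, methods, seed,
                 keep_data)
}

#' @rdname comparison_ensembles
#' @param base_rate Assumed taxon base rate in (0, 1).
#' @export
generate_taxonic_comparison <- function(matrix, base_rate = 0.25,
                                        n_sets = 100L,
                                        settings = taxo_settings(),
                                        methods = c("mambac", "maxeig", "lmode"),
                                        seed = NULL,
                                        exact_marginals = FALSE,
                                        keep_data = FALSE) {
  m <- as.matrix(matrix)
  k <- ncol(m)
  if (k < 3L) stop("comparison data need at least 3 valid indicators")
  groups <- classify_putative_groups(m, base_rate)
  tax <- m[groups$flags == 1L, , drop = FALSE]
  comp <- m[groups$flags == 0L, , drop = FALSE]
  if (nrow(tax) < k + 2L || nrow(comp) < k + 2L) {
    stop(sprintf(
      "base rate %.3f gives a group of %d cases; need at least %d to estimate within-group correlations",
      base_rate, min(nrow(tax), nrow(comp)), k + 2L))
  }
  target_tax <- stats::cor(tax)
  target_comp <- stats::cor(comp)
  target_tax[!is.finite(target_tax)] <- 0; diag(target_tax) <- 1
  target_comp[!is.finite(target_comp)] <- 0; diag(target_comp) <- 1
  gen_one <- function() {
    sim_tax <- gen_data_matched(target_tax,
                                draw_marginals(tax, exact_marginals),
                                max_iter = settings$max_iter,
                                tol = settings$corr_tol)
    sim_comp <- gen_data_matched(target_comp,
                                 draw_marginals(comp, exact_marginals),
                                 max_iter = settings$max_iter,
                                 tol = settings$corr_tol)
    rmsr <- max(attr(sim_tax, "rmsr"), attr(sim_comp, "rmsr"))
    out <- rbind(sim_comp, sim_tax)
    attr(out, "rmsr") <- rmsr
    out
  }
  ens <- build_ensemble("taxonic", gen_one, n_sets, settings, methods, seed,
                        keep_data)
  ens$base_rate <- base_rate
  ens
}

# shared ensemble machinery: child seeds, curve computation, mean + envelope
build_ensemble <- function(structure_label, gen_one, n_sets, settings,
                           methods, seed, keep_data) {
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_sets)
  sets <- vector("list", n_sets)
  rmsrs <- numeric(n_sets)
  curves <- stats::setNames(vector("list", length(methods)), methods)
  for (mtd in methods) curves[[mtd]] <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(child_seeds[s])
    x <- gen_one()
    rmsrs[s] <- attr(x, "rmsr")
    cs <- compute_method_curves(x, methods, settings)
    for (mtd in methods) curves[[mtd]][[s]] <- cs[[mtd]]$averaged_curve
    if (keep_data) sets[[s]] <- x
  }
  mean_curve <- lapply(curves, average_curves)
  envelope <- lapply(curves, function(cvs) {
    ys <- vapply(cvs, `[[`, numeric(length(cvs[[1L]]$y)), "y")
    ys <- matrix(ys, ncol = length(cvs))
    list(lo = apply(ys, 1L, min), hi = apply(ys, 1L, max))
  })
  structure(list(structure = structure_label, n_sets = n_sets,
                 curves = curves, mean_curve = mean_curve,
                 envelope = envelope, rmsr = rmsrs,
                 datasets = if (keep_data) sets else NULL),
            class = "comparison_ensemble")
}

#' @export
print.comparison_ensemble <- function(x, ...) {
  cat(sprintf("<comparison_ensemble %s: %d sets, methods %s, median corr RMSR %.3f>\n",
              x$structure, x$n_sets,
              paste(names(x$curves), collapse = "/"),
              stats::median(x$rmsr)))
  invisible(x)
}
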