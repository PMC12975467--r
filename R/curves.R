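#' Taxometric curve and curve-set containers
#'
#' A `taxo_curve` is an x/y pair: x is the cut location, window midpoint or
#' factor-score grid point (strictly increasing), y the method statistic.
#' A `curve_set` bundles one method's panel curves (one per indicator pair,
#' per input indicator, or a single density panel), their pointwise average
#' and the method's base-rate estimate.
#'
#' @param x Strictly increasing numeric vector.
#' @param y Numeric vector of equal length, all finite.
#' @return `taxo_curve`: a list `(x, y)` of class `"taxo_curve"`.
#' @keywords internal
taxo_curve <- function(x, y) {
  if (length(x) != length(y)) stop("curve x and y must have equal length")
  if (any(diff(x) <= 0)) stop("curve x must be strictly increasing")
  if (!all(is.finite(y))) stop("curve y must be finite")
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "taxo_curve")
}

curve_set <- function(method, panel_curves, averaged_curve,
                      base_rate_estimate = NA_real_) {
  len <- unique(vapply(panel_curves, function(cv) length(cv$y), integer(1L)))
  if (length(len) != 1L) stop("panel curves must share one length")
  structure(list(method = method,
                 panel_curves = panel_curves,
                 averaged_curve = averaged_curve,
                 base_rate_estimate = base_rate_estimate),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set %s: %d panel(s), %d points, base-rate estimate %s>\n",
              x$method, length(x$panel_curves),
              length(x$averaged_curve$y),
              ifelse(is.na(x$base_rate_estimate), "undefined",
                     sprintf("%.3f", x$base_rate_estimate))))
  invisible(x)
}

# pointwise mean of a list of curves (shared length; x averaged too, which
# is a no-op when the panels share a grid)
average_curves <- function(curves) {
  xs <- vapply(curves, `[[`, numeric(length(curves[[1L]]$x)), "x")
  ys <- vapply(curves, `[[`, numeric(length(curves[[1L]]$y)), "y")
  if (length(curves) == 1L) return(curves[[1L]])
  taxo_curve(rowMeans(matrix(xs, ncol = length(curves))),
             rowMeans(matrix(ys, ncol = length(curves))))
}
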