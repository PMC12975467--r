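#' Construct an indicator matrix
#'
#' The central data container of the package: an `n` cases by `k` indicators
#' numeric matrix in questionnaire score units, carrying unique indicator
#' names and case identifiers.  All downstream stages (validity screening,
#' comparison-data generation, the curve procedures) consume this class.
#'
#' @param values Numeric matrix or data frame, cases in rows, indicators in
#'   columns.  Every entry must be finite; missing values are rejected here
#'   (handle them at load time via [load_indicator_matrix()]).
#' @param indicator_names Character vector of `k` unique column labels.
#'   Defaults to the column names of `values`.
#' @param case_ids Vector of `n` case identifiers.  Defaults to row names or
#'   `1:n`.
#'
#' @return A numeric matrix of class `"indicator_matrix"` with `dimnames`
#'   set from `case_ids` and `indicator_names`.
#' @export
#' @examples
#' m <- indicator_matrix(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' n_cases(m)
#' indicator_names(m)
indicator_matrix <- function(values, indicator_names = colnames(values),
                             case_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  k <- ncol(values)
  if (k < 1L) stop("indicator matrix needs at least one indicator column")
  if (n < 2L) stop("indicator matrix needs at least two cases")
  if (is.null(indicator_names)) {
    indicator_names <- paste0("ind", seq_len(k))
  }
  indicator_names <- as.character(indicator_names)
  if (length(indicator_names) != k) {
    stop("indicator_names must have one label per column")
  }
  if (anyDuplicated(indicator_names)) {
    stop("indicator names must be unique: ",
         paste(unique(indicator_names[duplicated(indicator_names)]),
               collapse = ", "))
  }
  if (is.null(case_ids)) case_ids <- as.character(seq_len(n))
  if (length(case_ids) != n) stop("case_ids must have one entry per row")
  if (anyNA(values) || !all(is.finite(values))) {
    stop("indicator matrix must not contain missing or non-finite values")
  }
  dimnames(values) <- list(as.character(case_ids), indicator_names)
  class(values) <- c("indicator_matrix", "matrix", "array")
  values
}

#' @rdname indicator_matrix
#' @param x An `indicator_matrix`.
#' @export
n_cases <- function(x) nrow(x)

#' @rdname indicator_matrix
#' @export
n_indicators <- function(x) ncol(x)

#' @rdname indicator_matrix
#' @export
indicator_names <- function(x) colnames(x)

#' @rdname indicator_matrix
#' @export
case_ids <- function(x) rownames(x)

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix: %d cases x %d indicators>\n",
              nrow(x), ncol(x)))
  cat("indicators:", paste(colnames(x), collapse = ", "), "\n")
  print(utils::head(unclass(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more cases\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
`[.indicator_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && ncol(out) >= 1L && nrow(out) >= 2L) {
    class(out) <- c("indicator_matrix", "matrix", "array")
  }
  out
}

#' Load an indicator matrix from a delimited text file
#'
#' Reads a header-rowed delimited file, restricts it to the requested
#' indicator columns (in the requested order) and packages the result as an
#' [indicator_matrix()].
#'
#' @param path Path to the file.
#' @param columns Character vector of column labels to keep, in output order.
#'   `NULL` keeps every column.
#' @param missing_policy Either `"fail"` (default; any missing or
#'   non-numeric cell in a requested column is an error naming the offending
#'   row and column) or `"drop_case"` (rows with a missing value in any
#'   requested column are removed, with a message giving the count).
#' @param delimiter Field delimiter, `","` by default.
#'
#' @return An `indicator_matrix`.  Row identifiers come from the original
#'   file row order (1-based, before any dropping).
#' @export
load_indicator_matrix <- function(path, columns = NULL,
                                  missing_policy = c("fail", "drop_case"),
                                  delimiter = ",") {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (is.null(columns)) columns <- names(tab)
  missing_cols <- setdiff(columns, names(tab))
  if (length(missing_cols)) {
    stop("columns not present in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, columns, drop = FALSE]
  for (cn in columns) {
    col <- tab[[cn]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) && missing_policy == "fail") {
        stop(sprintf("non-numeric value in column '%s', row %d", cn, bad[1L]))
      }
      tab[[cn]] <- num
    }
  }
  m <- as.matrix(tab)
  rownames(m) <- as.character(seq_len(nrow(m)))
  if (anyNA(m)) {
    if (missing_policy == "fail") {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value in column '%s', row %s",
                   colnames(m)[idx[["col"]]], rownames(m)[idx[["row"]]]))
    }
    keep <- stats::complete.cases(m)
    message(sum(!keep), " case(s) dropped for missing values")
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) stop("no cases left after dropping missing values")
  }
  indicator_matrix(m)
}

#' Screening-item case filter
#'
#' Removes exactly the rows where *every* screening column equals zero
#' (participants who endorse none of the screening items), leaving retained
#' rows untouched and in their original order.
#'
#' @param table A labelled numeric table (data frame, matrix or
#'   `indicator_matrix`).
#' @param screening_columns Character vector naming at least one screening
#'   column present in `table`.
#'
#' @return A list with `data` (the filtered table, same class as the input
#'   matrix/data frame), `n_removed`, and `removed_ids` (row identifiers of
#'   the dropped cases).
#' @export
#' @examples
#' tab <- cbind(s1 = c(0, 0, 1), s2 = c(0, 1, 0), y = c(5, 2, 3))
#' apply_screening_filter(tab, c("s1", "s2"))$n_removed  # 1
apply_screening_filter <- function(table, screening_columns) {
  if (length(screening_columns) < 1L) {
    stop("at least one screening column is required")
  }
  cn <- colnames(table)
  if (is.null(cn)) stop("table must have column labels")
  missing_cols <- setdiff(screening_columns, cn)
  if (length(missing_cols)) {
    stop("unknown screening column(s): ", paste(missing_cols, collapse = ", "))
  }
  sc <- as.matrix(table[, screening_columns, drop = FALSE])
  drop_row <- rowSums(sc != 0) == 0L
  removed_ids <- rownames(table)[drop_row]
  if (is.null(removed_ids)) removed_ids <- which(drop_row)
  out <- table[!drop_row, , drop = FALSE]
  list(data = out, n_removed = sum(drop_row), removed_ids = removed_ids)
}

#' Sum-score subscales from item columns
#'
#' Collapses item columns into factor (subscale) scores by row-wise
#' summation, e.g. forming the three Beck Scale for Suicide Ideation factor
#' scores from their member items.
#'
#' @param table Labelled numeric table of item responses.
#' @param map Named list: `factor_name -> character vector of item column
#'   labels`.  Factors must be non-empty, reference existing columns, and no
#'   item may appear in more than one factor.
#'
#' @return An [indicator_matrix()] with one column per factor, in `map`
#'   order.
#' @export
#' @examples
#' tab <- cbind(i1 = c(1, 0), i2 = c(0, 2), i3 = c(2, 2))
#' score_subscales(tab, list(f1 = c("i1", "i2"), f2 = "i3"))
score_subscales <- function(table, map) {
  if (!length(map) || is.null(names(map)) || any(names(map) == "")) {
    stop("scoring map must be a named list of factors")
  }
  items <- unlist(map, use.names = FALSE)
  if (!length(items) || any(lengths(map) == 0L)) {
    stop("every factor must contain at least one item")
  }
  if (anyDuplicated(items)) {
    stop("item(s) assigned to more than one factor: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  }
  cn <- colnames(table)
  missing_cols <- setdiff(items, cn)
  if (length(missing_cols)) {
    stop("unknown item column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- as.matrix(table)
  scores <- vapply(map, function(cols) {
    rowSums(tab[, cols, drop = FALSE])
  }, numeric(nrow(tab)))
  scores <- matrix(scores, nrow = nrow(tab),
                   dimnames = list(rownames(tab), names(map)))
  indicator_matrix(scores)
}

#' Zero-safe base-10 log transform
#'
#' Replaces every score `x` by `log10(x + 1)`.  The +1 offset admits the
#' zeros that bounded symptom scales produce while keeping the transform
#' strictly monotone with `0 -> 0`; it is recorded in the analysis report.
#'
#' @param matrix An [indicator_matrix()] with all values `>= 0`.
#' @return An `indicator_matrix` of the same shape and names.
#' @export
log10_transform <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(m < 0)) stop("log10 transform requires non-negative values")
  out <- log10(m + 1)
  dimnames(out) <- dimnames(m)
  indicator_matrix(out)
}
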