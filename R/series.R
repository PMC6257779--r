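#' Expression time series
#'
#' An `expression_series` holds a genes-by-time matrix of (log-)expression
#' values together with the gene identifiers and the sampling times in hours.
#' It is the raw input of the network estimator and of the time-point-deletion
#' experiment.
#'
#' @param values numeric matrix, one row per gene, one column per time point.
#'   No missing values are allowed.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @param time_labels_h strictly increasing numeric vector of sampling times in
#'   hours, one per column. Defaults to the column names of `values` parsed as
#'   numbers.
#'
#' @return An object of class `expression_series`: a list with elements
#'   `gene_ids`, `time_labels_h` and `values` (a named p x T matrix).
#' @export
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), NULL))
#' expression_series(m, time_labels_h = c(0, 1, 2, 4))
expression_series <- function(values, gene_ids = rownames(values),
                              time_labels_h = as.numeric(colnames(values))) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x time points)", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("g", seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("`gene_ids` must have one entry per row of `values`", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  time_labels_h <- as.numeric(time_labels_h)
  if (length(time_labels_h) != ncol(values) || anyNA(time_labels_h)) {
    stop("`time_labels_h` must be one numeric label per column", call. = FALSE)
  }
  if (ncol(values) < 2) {
    stop("an expression series needs at least 2 time points", call. = FALSE)
  }
  if (any(diff(time_labels_h) <= 0)) {
    stop("time labels must be strictly increasing", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite with no missing entries", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, format(time_labels_h, trim = TRUE))
  structure(list(gene_ids = gene_ids,
                 time_labels_h = time_labels_h,
                 values = values),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("Expression series: %d genes x %d time points (%s h)\n",
              length(x$gene_ids), length(x$time_labels_h),
              paste(format(x$time_labels_h, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.expression_series <- function(x, ...) x$values

#' @export
dim.expression_series <- function(x) dim(x$values)

#' Remove time points from a series
#'
#' Restricts a series to the columns not listed in `indices`, preserving the
#' original column order and time labels. This is the elementary move of the
#' deletion experiment: downstream inference treats the retained consecutive
#' columns as unit-lag transitions, ignoring the widened gaps.
#'
#' @param series an [expression_series()].
#' @param indices integer vector of 1-based time-point positions to drop
#'   (possibly empty).
#' @return An [expression_series()] over the retained time points.
#' @export
#' @examples
#' s <- expression_series(matrix(1:6, 1), gene_ids = "g1",
#'                        time_labels_h = c(0, 1, 2, 4, 8, 12))
#' delete_timepoints(s, c(1, 3))$time_labels_h
delete_timepoints <- function(series, indices) {
  stopifnot(inherits(series, "expression_series"))
  T <- length(series$time_labels_h)
  indices <- as.integer(indices)
  if (length(indices) == 0) return(series)
  if (anyNA(indices) || any(indices < 1L) || any(indices > T)) {
    stop("deletion indices must lie in [1, ", T, "]", call. = FALSE)
  }
  indices <- unique(indices)
  keep <- setdiff(seq_len(T), indices)
  if (length(keep) < 2) {
    stop("deleting these time points leaves fewer than 2, cannot form transitions",
         call. = FALSE)
  }
  expression_series(series$values[, keep, drop = FALSE],
                    gene_ids = series$gene_ids,
                    time_labels_h = series$time_labels_h[keep])
}
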