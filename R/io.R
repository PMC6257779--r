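#' Read an expression time series from TSV/CSV
#'
#' Expects a header row `gene_id` followed by numeric hour labels, then one
#' row per gene. The delimiter (tab or comma) is sniffed from the header
#' line. Duplicate gene identifiers, ragged rows, non-numeric cells and
#' fewer than two time columns are rejected with the offending line named.
#'
#' @param path file to read.
#' @return An [expression_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop(path, ": need a header row and at least one gene",
                              call. = FALSE)
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (length(header) < 3) {
    stop(path, ", line 1: need `gene_id` plus at least 2 time columns",
         call. = FALSE)
  }
  labels <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(labels)) {
    stop(path, ", line 1: time labels must be numeric hours", call. = FALSE)
  }
  body <- strsplit(lines[-1], sep, fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    stop(path, ", line ", which(widths != length(header))[1] + 1,
         ": ragged row", call. = FALSE)
  }
  ids <- vapply(body, `[`, character(1), 1)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(length(labels))))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    stop(path, ", line ", bad + 1, ": non-numeric expression value",
         call. = FALSE)
  }
  vals <- matrix(t(vals), nrow = length(ids))
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate gene identifier `",
         ids[duplicated(ids)][1], "`", call. = FALSE)
  }
  expression_series(vals, gene_ids = ids, time_labels_h = labels)
}

#' Write an expression time series as TSV
#'
#' Header cell `gene_id` followed by the hour labels; values written with 12
#' significant digits so a read/write round trip is exact at that precision.
#'
#' @param series an [expression_series()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "expression_series"))
  header <- paste(c("gene_id", format(series$time_labels_h, trim = TRUE)),
                  collapse = "\t")
  rows <- vapply(seq_along(series$gene_ids), function(i) {
    paste(c(series$gene_ids[i], sprintf("%.12g", series$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a directed edge list into a network
#'
#' Expects columns `predictor` and `target` (tab- or comma-separated, sniffed
#' from the header) and optionally `score`. Every referenced gene must be in
#' the supplied panel; duplicates are rejected.
#'
#' @param path file to read.
#' @param gene_panel character vector: the full ordered gene panel of the
#'   network (isolated genes matter for the statistics).
#' @return A [grn()].
#' @export
read_edges <- function(path, gene_panel) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("predictor", "target") %in% names(df))) {
    stop(path, ": need columns `predictor` and `target`", call. = FALSE)
  }
  if ("score" %in% names(df)) df$score <- as.numeric(df$score)
  grn(gene_panel, df)
}

#' Write a network's edge list as TSV
#'
#' Columns `predictor`, `target`, `score`, sorted by (predictor, target).
#'
#' @param net a [grn()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "grn"))
  ed <- net$edges
  lines <- c("predictor\ttarget\tscore",
             if (nrow(ed)) paste(ed$predictor, ed$target,
                                 sprintf("%.12g", ed$score), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ground-truth model's edge list as TSV
#'
#' Columns `predictor`, `target`, `coefficient`.
#'
#' @param model a [ground_truth_model()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(model, path) {
  stopifnot(inherits(model, "ground_truth_model"))
  net <- truth_network(model)
  ed <- net$edges
  lines <- c("predictor\ttarget\tcoefficient",
             if (nrow(ed)) paste(ed$predictor, ed$target,
                                 sprintf("%.12g", ed$score), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Published reference statistics for the NASCARRAYS-60 deletion analysis
#'
#' The per-network statistics panel reported for the 800-gene Arabidopsis
#' diurnal time course (NASCArrays experiment NASCARRAYS-60) under the
#' standard 11-point deletion design: rows G0 (all time points) through G11,
#' plus the reported `ave` and `d_score` bottom rows. These printed values
#' serve as an input for consistency checks of the panel arithmetic and the
#' diversity score; the raw microarray data themselves are not shipped.
#'
#' @return A list with `stats` (12-row data frame: `network`, `K`, `Dia`,
#'   `l`, `Ce`, `Rn`, `E`, `Vu`), `ave` and `d_score` (named numeric vectors
#'   as printed), and `full` (node count 800 and edge count 447 of the
#'   reference network, with its reported `CC` 0.0019 and `N0` 306).
#' @export
nasc60_reference_stats <- function() {
  path <- system.file("extdata", "nasc60_deletion_stats.csv",
                      package = "lagnet", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  stats <- df[!(df$network %in% c("ave", "d_score")), , drop = FALSE]
  rownames(stats) <- NULL
  pick <- function(lab) {
    v <- unlist(df[df$network == lab, -1])
    stats::setNames(as.numeric(v), names(df)[-1])
  }
  list(stats = stats, ave = pick("ave"), d_score = pick("d_score"),
       full = list(N = 800L, Rn = 447L, CC = 0.0019, N0 = 306L))
}
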