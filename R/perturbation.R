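#' Standard time-point-deletion design
#'
#' The systematic design of the deletion experiment: one reference entry G0
#' that keeps all T time points, one entry G_k per time point k deleting only
#' that point, and optionally adjacent-pair entries `G{a}_{b}` deleting two
#' points at once.
#'
#' @param T number of time points (at least 3).
#' @param pairs optional list of integer pairs (1-based time indices) to
#'   delete together, e.g. `list(c(2, 3), c(9, 10))`.
#' @return An object of class `deletion_design`: a list with `entries` (a
#'   named list mapping label -> integer vector of deleted indices) and
#'   `reference_label` (`"G0"`).
#' @export
#' @examples
#' standard_design(11, pairs = list(c(2, 3), c(9, 10)))
standard_design <- function(T, pairs = NULL) {
  if (!is.numeric(T) || length(T) != 1 || T < 3) {
    stop("`T` must be an integer >= 3", call. = FALSE)
  }
  T <- as.integer(T)
  entries <- c(list(G0 = integer()),
               stats::setNames(lapply(seq_len(T), function(k) k),
                               paste0("G", seq_len(T))))
  for (pr in pairs) {
    pr <- sort(as.integer(pr))
    if (length(pr) != 2 || any(pr < 1) || any(pr > T) || pr[1] == pr[2]) {
      stop("each pair must be two distinct indices in [1, T]", call. = FALSE)
    }
    entries[[paste0("G", pr[1], "_", pr[2])]] <- pr
  }
  structure(list(entries = entries, reference_label = "G0"),
            class = "deletion_design")
}

#' @export
print.deletion_design <- function(x, ...) {
  cat(sprintf("Deletion design: %d entries (reference %s)\n",
              length(x$entries), x$reference_label))
  cat(paste(names(x$entries), collapse = ", "), "\n")
  invisible(x)
}

#' Relative diversity score of a statistic across networks
#'
#' For the values Q_1..Q_m of one statistic over a collection of networks,
#' `d = sum(|Q_k - ave|) / ave` with `ave = mean(Q_k)`. A low score marks a
#' statistic that barely reacts to the perturbation (here: time-point
#' deletion). The score is invariant to rescaling the statistic by a positive
#' constant, which is why exactly proportional statistics (such as the
#' average degree and the edge count on a fixed panel) share one score.
#'
#' @param values numeric vector of length >= 2 with nonzero mean.
#' @return The diversity score (non-negative number).
#' @export
#' @examples
#' diversity_score(c(1, 3))    # ave 2, deviations 1 + 1 -> 1
diversity_score <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  ave <- mean(values)
  if (ave == 0) stop("diversity score undefined for zero-mean values",
                     call. = FALSE)
  sum(abs(values - ave)) / ave
}

#' Run the time-point-deletion experiment
#'
#' For every entry of the design: delete the entry's time points from the
#' series, refit the network with [grn_fit()] at the same thresholds, and
#' (optionally) compute the [network_summary()] statistics row. The
#' statistics table gains two bottom rows: `ave`, the per-column mean over
#' all successful entries, and `d_score`, the per-column
#' [diversity_score()].
#'
#' Entries whose deletion leaves fewer than 5 time points cannot support the
#' step-1 regressions and are recorded as failed rather than aborting the
#' sweep.
#'
#' @param series an [expression_series()].
#' @param design a [standard_design()] (or compatible `deletion_design`).
#' @param alpha1,alpha2 thresholds passed to [grn_fit()].
#' @param allow_self passed to [grn_fit()].
#' @param compute_stats compute the statistics panel per network (default
#'   `TRUE`)?
#' @return An object of class `grn_experiment`: a list with `networks` (named
#'   list of [grn_fit()] objects, `NULL` for failed entries), `stats_table`
#'   (data frame with one row per entry plus `ave` and `d_score` rows;
#'   `NULL` when `compute_stats = FALSE`), `design`, `failed` (character
#'   vector of failed labels) and the thresholds.
#' @export
run_experiment <- function(series, design = standard_design(length(series$time_labels_h)),
                           alpha1 = 0.5, alpha2 = 0.05, allow_self = FALSE,
                           compute_stats = TRUE) {
  stopifnot(inherits(series, "expression_series"),
            inherits(design, "deletion_design"))
  labels <- names(design$entries)
  networks <- stats::setNames(vector("list", length(labels)), labels)
  rows <- list()
  failed <- character()
  for (lab in labels) {
    del <- design$entries[[lab]]
    T_left <- length(series$time_labels_h) - length(del)
    if (T_left < 5) {
      failed <- c(failed, lab)
      next
    }
    sub <- delete_timepoints(series, del)
    fit <- grn_fit(sub, alpha1 = alpha1, alpha2 = alpha2,
                   allow_self = allow_self)
    networks[[lab]] <- fit
    if (compute_stats) rows[[lab]] <- as.data.frame(network_summary(fit, lab))
  }
  if (length(failed) == length(labels)) {
    stop("every design entry failed (too few time points left)", call. = FALSE)
  }
  stats_table <- NULL
  if (compute_stats) {
    stats_table <- do.call(rbind, rows)
    num <- setdiff(names(stats_table), "label")
    ave <- vapply(stats_table[num], mean, numeric(1))
    dsc <- vapply(stats_table[num], function(v) {
      if (mean(v) == 0) NA_real_ else diversity_score(v)
    }, numeric(1))
    stats_table <- rbind(stats_table,
                         data.frame(label = "ave", as.list(ave)),
                         data.frame(label = "d_score", as.list(dsc)))
    rownames(stats_table) <- NULL
  }
  structure(list(networks = networks, stats_table = stats_table,
                 design = design, failed = failed,
                 alpha1 = alpha1, alpha2 = alpha2, allow_self = allow_self),
            class = "grn_experiment")
}

#' @export
print.grn_experiment <- function(x, ...) {
  ok <- !vapply(x$networks, is.null, logical(1))
  cat(sprintf("Time-point-deletion experiment: %d entries (%d fitted, %d failed)\n",
              length(x$networks), sum(ok), length(x$failed)))
  if (!is.null(x$stats_table)) {
    cat("\nStatistics table:\n")
    print(x$stats_table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
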