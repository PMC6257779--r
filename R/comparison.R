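#' Confusion counts between two directed edge sets
#'
#' Classifies every admissible ordered gene pair: a true positive is an edge
#' present in both networks, a false positive an edge only in `predicted`, a
#' false negative an edge only in `reference`, and a true negative a pair in
#' neither. The pair universe is every ordered pair of distinct genes
#' (p * (p - 1)), or all p^2 pairs when `include_self = TRUE`; it must match
#' the convention the networks were fitted under.
#'
#' @param reference,predicted [grn()] objects over identical gene panels.
#' @param include_self count self-pairs in the universe? Default `FALSE`.
#' @return A list with integer fields `n_tp`, `n_fp`, `n_fn`, `n_tn`.
#' @export
#' @examples
#' ref <- grn(letters[1:4], data.frame(predictor = c("a", "b", "a"),
#'                                     target = c("b", "c", "c")))
#' prd <- grn(letters[1:4], data.frame(predictor = c("a", "c"),
#'                                     target = c("b", "a")))
#' edge_confusion(ref, prd)
edge_confusion <- function(reference, predicted, include_self = FALSE) {
  stopifnot(inherits(reference, "grn"), inherits(predicted, "grn"))
  if (!identical(sort(reference$gene_ids), sort(predicted$gene_ids))) {
    stop("gene panels differ between the two networks", call. = FALSE)
  }
  p <- length(reference$gene_ids)
  universe <- if (include_self) p * p else p * (p - 1L)
  ref <- edge_keys(reference)
  prd <- edge_keys(predicted)
  tp <- length(intersect(ref, prd))
  fp <- length(setdiff(prd, ref))
  fn <- length(setdiff(ref, prd))
  list(n_tp = tp, n_fp = fp, n_fn = fn,
       n_tn = universe - tp - fp - fn)
}

#' Sensitivity, precision and F-measure from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `precision = TP / (TP + FP)` and the
#' F-measure is their harmonic mean; each is defined as 0 when its
#' denominator vanishes, so sweep tables stay numeric.
#'
#' @param counts an [edge_confusion()] result.
#' @return A list with `sensitivity`, `precision`, `f_measure` in \[0, 1\].
#' @export
classification_metrics <- function(counts) {
  tp <- counts$n_tp
  s <- if (tp + counts$n_fn == 0) 0 else tp / (tp + counts$n_fn)
  p <- if (tp + counts$n_fp == 0) 0 else tp / (tp + counts$n_fp)
  f <- if (s + p == 0) 0 else 2 * s * p / (s + p)
  list(sensitivity = s, precision = p, f_measure = f)
}

#' Compare every network of an experiment against the reference
#'
#' Computes sensitivity, precision and F-measure of each deletion network
#' against the reference (full-data) network of the experiment; the reference
#' compared with itself reports (1, 1, 1).
#'
#' @param result a [run_experiment()] result (its reference label must have
#'   fitted successfully).
#' @param include_self passed to [edge_confusion()].
#' @return A data frame with columns `label`, `sensitivity`, `precision`,
#'   `f_measure`, one row per fitted entry.
#' @export
compare_collection <- function(result, include_self = FALSE) {
  stopifnot(inherits(result, "grn_experiment"))
  ref_lab <- result$design$reference_label
  ref <- result$networks[[ref_lab]]
  if (is.null(ref)) stop("reference network `", ref_lab, "` is missing",
                         call. = FALSE)
  rows <- lapply(names(result$networks), function(lab) {
    net <- result$networks[[lab]]
    if (is.null(net)) return(NULL)
    m <- classification_metrics(edge_confusion(ref, net, include_self))
    data.frame(label = lab, sensitivity = m$sensitivity,
               precision = m$precision, f_measure = m$f_measure,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Edge occurrence across a collection of networks
#'
#' For every directed edge present in at least one network of a labeled
#' collection, records which networks contain it and its occurrence count m;
#' aggregates the number of edges occurring in exactly m and in at least m
#' networks for m = 1..#networks.
#'
#' @param networks named list of [grn()] objects over a shared gene panel.
#' @return A list with `edges` (data frame `predictor`, `target`, `m`,
#'   `networks` — comma-separated sorted member labels) and `aggregate`
#'   (data frame `m`, `n_exact`, `n_at_least`).
#' @export
edge_overlap <- function(networks) {
  if (length(networks) < 2 || is.null(names(networks))) {
    stop("need a named list of at least 2 networks", call. = FALSE)
  }
  panels <- lapply(networks, function(n) sort(n$gene_ids))
  if (!all(vapply(panels, identical, logical(1), panels[[1]]))) {
    stop("networks cover different gene panels", call. = FALSE)
  }
  labels <- names(networks)
  membership <- lapply(labels, function(lab) edge_keys(networks[[lab]]))
  names(membership) <- labels
  all_keys <- sort(unique(unlist(membership)))
  inmat <- vapply(labels,
                  function(lab) all_keys %in% membership[[lab]],
                  logical(length(all_keys)))
  inmat <- matrix(inmat, nrow = length(all_keys),
                  dimnames = list(all_keys, labels))
  m <- rowSums(inmat)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  edges <- data.frame(
    predictor = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    m = as.integer(m),
    networks = apply(inmat, 1, function(r) paste(labels[r], collapse = ",")),
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$m, edges$predictor, edges$target), ]
  rownames(edges) <- NULL
  ms <- seq_len(length(labels))
  aggregate <- data.frame(
    m = ms,
    n_exact = vapply(ms, function(k) sum(m == k), integer(1)),
    n_at_least = vapply(ms, function(k) sum(m >= k), integer(1)))
  list(edges = edges, aggregate = aggregate)
}

#' Regulations common to exactly m networks
#'
#' Table of every directed regulation occurring in exactly `m` networks of
#' the collection, listing the networks that contain it and those that do
#' not — the "common regulations" view of an overlap analysis.
#'
#' @param networks named list of [grn()] objects over a shared gene panel.
#' @param m occurrence count of interest, in \[1, #networks\].
#' @return A data frame with columns `predictor`, `target`, `networks_with`,
#'   `networks_without` (comma-separated, in collection order).
#' @export
common_regulations <- function(networks, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > length(networks)) {
    stop("`m` must lie in [1, number of networks]", call. = FALSE)
  }
  ov <- edge_overlap(networks)
  sel <- ov$edges[ov$edges$m == as.integer(m), , drop = FALSE]
  labels <- names(networks)
  without <- vapply(sel$networks, function(w) {
    paste(setdiff(labels, strsplit(w, ",", fixed = TRUE)[[1]]),
          collapse = ",")
  }, character(1))
  out <- data.frame(predictor = sel$predictor, target = sel$target,
                    networks_with = sel$networks,
                    networks_without = unname(without),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
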