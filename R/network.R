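#' Directed regulatory network
#'
#' A `grn` is a directed graph over a fixed gene panel: the node set is always
#' the full panel (isolated genes count towards statistics such as N0 and the
#' average degree), and edges are ordered (predictor -> target) pairs with an
#' optional numeric score each.
#'
#' @param gene_ids character vector of unique gene identifiers (the panel).
#' @param edges data frame with character columns `predictor` and `target`
#'   (and optionally a numeric `score`), one row per directed edge. May have
#'   zero rows.
#'
#' @return An object of class `grn`: a list with elements `gene_ids` and
#'   `edges` (a data frame with columns `predictor`, `target`, `score`).
#' @export
#' @examples
#' grn(c("a", "b", "c"), data.frame(predictor = "a", target = "b"))
grn <- function(gene_ids, edges = NULL) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 1) stop("empty gene panel", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(predictor = character(), target = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("predictor", "target") %in% names(edges))) {
      stop("`edges` needs columns `predictor` and `target`", call. = FALSE)
    }
    edges <- data.frame(predictor = as.character(edges$predictor),
                        target = as.character(edges$target),
                        score = if ("score" %in% names(edges))
                          as.numeric(edges$score) else NA_real_,
                        stringsAsFactors = FALSE)
    unknown <- setdiff(c(edges$predictor, edges$target), gene_ids)
    if (length(unknown) > 0) {
      stop("edges reference genes outside the panel: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    key <- paste(edges$predictor, edges$target, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate directed edges", call. = FALSE)
    edges <- edges[order(edges$predictor, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(gene_ids = gene_ids, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("Directed regulatory network: %d genes, %d edges\n",
              length(x$gene_ids), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    print(utils::head(x$edges, 10))
    if (nrow(x$edges) > 10) cat("... and", nrow(x$edges) - 10, "more edges\n")
  }
  invisible(x)
}

# canonical "predictor -> target" keys, used for set algebra on edge sets
edge_keys <- function(net) {
  paste(net$edges$predictor, net$edges$target, sep = "\r")
}

# igraph view of a grn; keeps isolated genes as vertices
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("predictor", "target")],
                                directed = TRUE, vertices = net$gene_ids)
}
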