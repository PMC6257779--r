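#' Degree metrics and histogram
#'
#' Per-node indegree, outdegree and total degree, the average degree
#' K = 2 * Rn / N (total-degree convention), the isolated-node count N0, the
#' edge count Rn, and degree histograms.
#'
#' @param net a [grn()].
#' @return A list with `indegree`, `outdegree`, `degree` (named vectors),
#'   `K`, `N0`, `Rn` and `histogram` (a [degree_histogram()] result).
#' @export
#' @examples
#' net <- grn(letters[1:3], data.frame(predictor = c("a", "b", "c"),
#'                                     target = c("b", "c", "a")))
#' degree_metrics(net)$K
degree_metrics <- function(net) {
  stopifnot(inherits(net, "grn"))
  g <- as_igraph(net)
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  deg <- indeg + outdeg
  N <- length(net$gene_ids)
  list(indegree = indeg, outdegree = outdeg, degree = deg,
       K = sum(deg) / N,
       N0 = sum(deg == 0),
       Rn = nrow(net$edges),
       histogram = degree_histogram(net))
}

#' Degree histograms of a network
#'
#' Node counts by degree, for total degree and the in/out variants.
#'
#' @param net a [grn()].
#' @return A list of three data frames (`total`, `indegree`, `outdegree`)
#'   with columns `degree` and `count`; counts sum to the panel size.
#' @export
degree_histogram <- function(net) {
  stopifnot(inherits(net, "grn"))
  g <- as_igraph(net)
  one <- function(mode) {
    d <- igraph::degree(g, mode = mode)
    tab <- table(d)
    data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
  }
  list(total = one("all"), indegree = one("in"), outdegree = one("out"))
}

#' Directed path metrics: diameter, average path length, global efficiency
#'
#' Shortest directed path lengths between all ordered node pairs give the
#' diameter `Dia` (longest finite shortest path), the average path length `l`
#' (mean over ordered *reachable* pairs i != j) and the global efficiency
#' `E = mean over all ordered pairs of 1/d_ij`, with unreachable pairs
#' contributing zero. A network with no finite path at all reports
#' `Dia = 0`, `l = 0` and is flagged in `defined`.
#'
#' @param net a [grn()].
#' @return A list with `Dia`, `l`, `E` and logical `defined`.
#' @export
path_metrics <- function(net) {
  stopifnot(inherits(net, "grn"))
  N <- length(net$gene_ids)
  if (N < 2) return(list(Dia = 0, l = 0, E = 0, defined = FALSE))
  d <- igraph::distances(as_igraph(net), mode = "out")
  d <- d[row(d) != col(d)]                 # ordered pairs i != j
  finite <- is.finite(d)
  if (!any(finite)) return(list(Dia = 0, l = 0, E = 0, defined = FALSE))
  list(Dia = max(d[finite]),
       l = mean(d[finite]),
       E = sum(1 / d[finite]) / (N * (N - 1)),
       defined = TRUE)
}

#' Directed betweenness centrality
#'
#' For each node v, the sum over ordered pairs (i, j), i != v != j, of the
#' fraction of shortest directed i -> j paths that pass through v
#' (unnormalized Freeman betweenness on the directed graph).
#'
#' @param net a [grn()].
#' @return A named numeric vector, one value per gene.
#' @export
betweenness_scores <- function(net) {
  stopifnot(inherits(net, "grn"))
  igraph::betweenness(as_igraph(net), directed = TRUE)
}

#' Clustering coefficient (transitivity)
#'
#' Computed on the undirected projection (an undirected edge \{u, v\} exists
#' iff u -> v or v -> u): three times the number of triangles divided by the
#' number of connected triples; 0 when no connected triple exists.
#'
#' @param net a [grn()].
#' @return A number in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "grn"))
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc) || is.na(cc)) 0 else cc
}

#' Freeman degree centralization
#'
#' Total deviation of node degrees from the maximum degree, normalized by
#' (N - 1)(N - 2) so that a star scores 1 and a regular graph 0. Degrees are
#' taken on the undirected projection (the star/regular calibration is an
#' undirected construct).
#'
#' @param net a [grn()] with at least 3 genes; smaller panels return a
#'   flagged 0.
#' @return A list with `Ce` and logical `defined`.
#' @export
centralization <- function(net) {
  stopifnot(inherits(net, "grn"))
  N <- length(net$gene_ids)
  if (N < 3) return(list(Ce = 0, defined = FALSE))
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  d <- igraph::degree(g)
  list(Ce = sum(max(d) - d) / ((N - 1) * (N - 2)), defined = TRUE)
}

#' Maximum vulnerability
#'
#' The vulnerability of node i is the relative drop in global efficiency when
#' node i and all its incident edges are removed:
#' `(E - E_i) / E`. The network's maximum vulnerability `Vu` is the largest
#' drop over all nodes (0 when the network has no efficiency to lose).
#'
#' @param net a [grn()] with at least 2 genes.
#' @return A list with `Vu` and `most_vulnerable` (the gene whose removal
#'   causes the largest drop, `NA` when `Vu = 0` trivially).
#' @export
max_vulnerability <- function(net) {
  stopifnot(inherits(net, "grn"))
  N <- length(net$gene_ids)
  E <- path_metrics(net)$E
  if (N < 2 || E == 0) return(list(Vu = 0, most_vulnerable = NA_character_))
  g <- as_igraph(net)
  drops <- vapply(seq_len(N), function(i) {
    gi <- igraph::delete_vertices(g, i)
    Ni <- N - 1
    if (Ni < 2) return(1)
    di <- igraph::distances(gi, mode = "out")
    di <- di[row(di) != col(di)]
    Ei <- sum(1 / di[is.finite(di)]) / (Ni * (Ni - 1))
    (E - Ei) / E
  }, numeric(1))
  list(Vu = max(drops), most_vulnerable = net$gene_ids[which.max(drops)])
}

#' Network statistics panel
#'
#' Assembles the full statistics row for one network: average degree K,
#' diameter Dia, average path length l, isolated-node count N0, edge count
#' Rn, global efficiency E, maximum vulnerability Vu, clustering coefficient
#' CC and centralization Ce.
#'
#' @param net a [grn()].
#' @param label a name for the network (e.g. `"G0"`).
#' @return An object of class `stats_row`: a one-row list with fields
#'   `label`, `K`, `Dia`, `l`, `N0`, `Rn`, `E`, `Vu`, `CC`, `Ce`.
#' @export
#' @examples
#' net <- grn(letters[1:3], data.frame(predictor = c("a", "b"),
#'                                     target = c("b", "c")))
#' network_summary(net, "path")
network_summary <- function(net, label = "G0") {
  stopifnot(inherits(net, "grn"))
  deg <- degree_metrics(net)
  pm <- path_metrics(net)
  structure(list(label = label,
                 K = deg$K, Dia = pm$Dia, l = pm$l,
                 N0 = deg$N0, Rn = deg$Rn, E = pm$E,
                 Vu = max_vulnerability(net)$Vu,
                 CC = clustering_coefficient(net),
                 Ce = centralization(net)$Ce),
            class = "stats_row")
}

#' @export
print.stats_row <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.stats_row <- function(x, ...) {
  data.frame(label = x$label, K = x$K, Dia = x$Dia, l = x$l, N0 = x$N0,
             Rn = x$Rn, E = x$E, Vu = x$Vu, CC = x$CC, Ce = x$Ce,
             stringsAsFactors = FALSE)
}

#' Least-squares power-law fit to a degree histogram
#'
#' Fits a straight line to (log10 degree, log10 count) over degrees >= 1 with
#' count >= 1 — the conventional quick scale-free check for sparse regulatory
#' networks. The coefficient of determination serves as the goodness of fit
#' used to rank networks.
#'
#' @param hist a [degree_histogram()] result (or a data frame with columns
#'   `degree` and `count`).
#' @param which which histogram to fit: `"total"` (default), `"indegree"` or
#'   `"outdegree"`.
#' @return A list with `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
#' @examples
#' h <- data.frame(degree = 1:10, count = round(1000 * (1:10)^-2))
#' fit_power_law(h)$slope
fit_power_law <- function(hist, which = c("total", "indegree", "outdegree")) {
  if (is.data.frame(hist)) tab <- hist
  else tab <- hist[[match.arg(which)]]
  tab <- tab[tab$degree >= 1 & tab$count >= 1, , drop = FALSE]
  if (nrow(tab) < 2) {
    stop("need at least 2 distinct positive degrees with positive counts",
         call. = FALSE)
  }
  x <- log10(tab$degree)
  y <- log10(tab$count)
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  rss <- sum(stats::residuals(fit)^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss == 0) 1 else 1 - rss / tss,  # exact flat fits: 1
       n_points = nrow(tab))
}
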