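#' Ground-truth regulatory model
#'
#' A sparse linear lag-1 (VAR(1)) dynamical model with a known directed
#' regulation structure. Entry `(i, j)` of `coefficients` is the effect of
#' gene `j` at time t-1 on gene `i` at time t; the edge set of the model is
#' the set of ordered pairs `(j -> i)` with a nonzero coefficient.
#'
#' @param gene_ids character vector of unique gene identifiers (length p).
#' @param coefficients p x p numeric matrix of lag-1 effects.
#' @param noise_sd non-negative innovation standard deviation (expression
#'   units).
#' @param intercept length-p numeric vector of per-gene intercepts.
#'
#' @details Construction checks stationarity: the spectral radius of
#'   `coefficients` must be below 1, otherwise simulated trajectories diverge.
#'
#' @return An object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(gene_ids, coefficients, noise_sd,
                               intercept = rep(0, length(gene_ids))) {
  gene_ids <- as.character(gene_ids)
  p <- length(gene_ids)
  if (p < 1) stop("need at least one gene", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (!is.matrix(coefficients) || !identical(dim(coefficients), c(p, p))) {
    stop("`coefficients` must be a p x p matrix", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  }
  if (length(intercept) != p) stop("`intercept` must have length p", call. = FALSE)
  rho <- spectral_radius(coefficients)
  if (rho >= 1) {
    stop(sprintf("spectral radius %.3f >= 1: the model is not stationary", rho),
         call. = FALSE)
  }
  dimnames(coefficients) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, coefficients = coefficients,
                 noise_sd = noise_sd, intercept = as.numeric(intercept)),
            class = "ground_truth_model")
}

spectral_radius <- function(A) {
  if (all(A == 0)) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf(
    "Ground-truth VAR(1) model: %d genes, %d regulations, noise sd %.3g\n",
    length(x$gene_ids), sum(x$coefficients != 0), x$noise_sd))
  invisible(x)
}

#' Edge list of a ground-truth model
#'
#' @param model a [ground_truth_model()].
#' @return A [grn()] whose edges are the nonzero coefficients, scored by the
#'   coefficient value.
#' @export
truth_network <- function(model) {
  stopifnot(inherits(model, "ground_truth_model"))
  idx <- which(model$coefficients != 0, arr.ind = TRUE)
  grn(model$gene_ids,
      data.frame(predictor = model$gene_ids[idx[, 2]],
                 target = model$gene_ids[idx[, 1]],
                 score = model$coefficients[idx],
                 stringsAsFactors = FALSE))
}

#' Generate a random sparse ground-truth model
#'
#' Draws a directed Erdos-Renyi-style regulation structure: each ordered gene
#' pair carries an edge independently with probability
#' `expected_edges / n_allowed_pairs`, so the realised edge count is binomial
#' around `expected_edges`. Nonzero coefficients have magnitude uniform in
#' `coeff_range` with random sign. If the resulting matrix has spectral radius
#' above 0.95 it is rescaled to 0.95 so that simulated series stay stationary.
#'
#' The defaults mirror the shape of a sparse regulatory network observed on an
#' 800-gene diurnal leaf transcriptome panel (about 0.56 regulations per gene).
#'
#' @param p number of genes.
#' @param expected_edges expected number of regulations; defaults to
#'   `round(0.56 * p)`.
#' @param coeff_range length-2 positive interval for coefficient magnitudes.
#' @param noise_sd innovation standard deviation of the simulated dynamics.
#' @param allow_self should self-regulation (diagonal coefficients) be allowed?
#' @param seed integer seed; the same seed reproduces the model exactly.
#'
#' @return A [ground_truth_model()].
#' @export
#' @examples
#' m <- generate_ground_truth(p = 20, expected_edges = 40, seed = 1)
#' sum(m$coefficients != 0)
generate_ground_truth <- function(p, expected_edges = max(1L, round(0.56 * p)),
                                  coeff_range = c(0.5, 1.0),
                                  noise_sd = 0.5,
                                  allow_self = FALSE, seed = 1L) {
  if (!is.numeric(p) || length(p) != 1 || p < 1) {
    stop("`p` must be a positive integer", call. = FALSE)
  }
  p <- as.integer(p)
  n_pairs <- if (allow_self) p * p else p * (p - 1L)
  if (expected_edges < 0 || expected_edges > n_pairs) {
    stop(sprintf("`expected_edges` must lie in [0, %d] for p = %d", n_pairs, p),
         call. = FALSE)
  }
  coeff_range <- sort(abs(as.numeric(coeff_range)))
  if (length(coeff_range) != 2 || coeff_range[1] <= 0) {
    stop("`coeff_range` must be a positive interval excluding 0", call. = FALSE)
  }
  gene_ids <- sprintf("g%03d", seq_len(p))
  A <- matrix(0, p, p)
  if (n_pairs > 0 && expected_edges > 0) {
    prob <- expected_edges / n_pairs
    local_seed(seed, {
      present <- matrix(stats::runif(p * p) < prob, p, p)
      if (!allow_self) diag(present) <- FALSE
      k <- sum(present)
      mag <- stats::runif(k, coeff_range[1], coeff_range[2])
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      A[present] <- mag * sgn
    })
    rho <- spectral_radius(A)
    if (rho > 0.95) A <- A * (0.95 / rho)
  }
  ground_truth_model(gene_ids, A, noise_sd = noise_sd)
}

#' Simulate an expression time series from a ground-truth model
#'
#' Iterates the linear lag-1 map: the first column is standard Gaussian per
#' gene, and each subsequent column is
#' `intercept + coefficients %*% previous + noise`, with i.i.d. Gaussian noise
#' of standard deviation `noise_sd`. Successive observations are treated as
#' unit-lag transitions regardless of the spacing of the hour labels —
#' matching how the inference side handles irregular and deletion-shortened
#' designs.
#'
#' @param model a [ground_truth_model()].
#' @param time_labels_h strictly increasing sampling times in hours; defaults
#'   to the 11-point diurnal design `0, 1, 2, 4, 8, 12, 13, 14, 16, 20, 24`.
#' @param seed integer seed.
#' @param x0 optional length-p initial state; when supplied it replaces the
#'   random initial column.
#'
#' @return An [expression_series()] of dimension p x T.
#' @export
#' @examples
#' m <- generate_ground_truth(p = 5, seed = 2)
#' s <- simulate_expression(m, seed = 3)
#' dim(s)
simulate_expression <- function(model, time_labels_h = default_timepoints(),
                                seed = 1L, x0 = NULL) {
  stopifnot(inherits(model, "ground_truth_model"))
  time_labels_h <- as.numeric(time_labels_h)
  T <- length(time_labels_h)
  if (T < 2) stop("need at least 2 time points", call. = FALSE)
  if (any(diff(time_labels_h) <= 0)) {
    stop("time labels must be strictly increasing", call. = FALSE)
  }
  p <- length(model$gene_ids)
  X <- matrix(0, p, T)
  local_seed(seed, {
    X[, 1] <- if (is.null(x0)) stats::rnorm(p) else as.numeric(x0)
    for (k in 2:T) {
      eps <- if (model$noise_sd > 0) stats::rnorm(p, sd = model$noise_sd) else 0
      X[, k] <- model$intercept + model$coefficients %*% X[, k - 1] + eps
    }
  })
  expression_series(X, gene_ids = model$gene_ids, time_labels_h = time_labels_h)
}

#' The 11-point diurnal sampling design
#'
#' Hour labels of the leaf-harvest time course emulated by the simulator:
#' dense sampling around the dark/light transition, 24 h repeating 0 h.
#'
#' @return Numeric vector `c(0, 1, 2, 4, 8, 12, 13, 14, 16, 20, 24)`.
#' @export
default_timepoints <- function() c(0, 1, 2, 4, 8, 12, 13, 14, 16, 20, 24)
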