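#' Fit a lag-1 regulatory network to an expression time series
#'
#' The central estimator of the package. A directed gene regulatory network
#' is reconstructed in two stages, following the dependence-based route to
#' dynamic-Bayesian-network structure learning for first-order linear models:
#'
#' 1. **Conditional-dependence screening** ([score_step1()]): every ordered
#'    gene pair j -> i is scored by the largest p-value of j's lagged
#'    coefficient across bivariate regressions that condition on one other
#'    lagged gene; pairs with score at most `alpha1` become candidate edges
#'    ([threshold_step1()]).
#' 2. **Joint pruning** ([prune_step2()]): each target is regressed on all
#'    its candidate parents at once and edges with coefficient p-value above
#'    `alpha2` are removed.
#'
#' After pruning, one ordinary least-squares fit per target on its surviving
#' parents provides the coefficient matrix, fitted values, residuals and
#' per-gene innovation scale used by [predict.grn_fit()],
#' [residuals.grn_fit()] and [simulate.grn_fit()].
#'
#' Successive observations are treated as unit-lag transitions regardless of
#' the spacing of the hour labels; this is a deliberate modelling
#' approximation (see the package vignette) and is what makes networks fitted
#' to deletion-shortened series comparable to the full-data fit.
#'
#' @param series an [expression_series()] with at least 5 time points.
#' @param alpha1 screening threshold in (0, 1]; permissive by default (0.5).
#' @param alpha2 pruning threshold in (0, 1]; strict by default (0.05).
#' @param allow_self allow self-regulation edges g -> g? Default `FALSE`.
#'
#' @return An object of class `c("grn_fit", "grn")` with elements `gene_ids`,
#'   `edges` (data frame `predictor`, `target`, `score` = step-2 p-value),
#'   `scores` (the step-1 [score_step1()] matrix), `coefficients` (p x p
#'   estimated lag-1 effects, zero off the edge set), `intercept`, `fitted`,
#'   `residuals`, `sigma` (per-gene residual standard deviation), `alpha1`,
#'   `alpha2`, `allow_self`, `series` and `call`.
#' @seealso [network_summary()] for the statistics panel,
#'   [run_experiment()] for the time-point-deletion sweep.
#' @export
#' @examples
#' truth <- generate_ground_truth(p = 10, expected_edges = 12,
#'                                noise_sd = 0.1, seed = 1)
#' series <- simulate_expression(truth, time_labels_h = 0:19, seed = 2)
#' fit <- grn_fit(series)
#' fit
#' coef(fit)[1:3, 1:3]
grn_fit <- function(series, alpha1 = 0.5, alpha2 = 0.05, allow_self = FALSE) {
  stopifnot(inherits(series, "expression_series"))
  check_alpha(alpha1, "alpha1")
  check_alpha(alpha2, "alpha2")
  cl <- match.call()
  trans <- build_transitions(series)
  scores <- score_step1(trans, exclude_self = !allow_self)
  candidate <- threshold_step1(scores, alpha1)
  net <- prune_step2(trans, candidate, alpha2)

  p <- length(net$gene_ids)
  n <- trans$n_transitions
  A <- matrix(0, p, p, dimnames = list(net$gene_ids, net$gene_ids))
  b0 <- stats::setNames(rep(0, p), net$gene_ids)
  fitted <- matrix(0, p, n, dimnames = dimnames(trans$responses))
  for (i in seq_len(p)) {
    parents <- match(net$edges$predictor[net$edges$target == net$gene_ids[i]],
                     net$gene_ids)
    X <- cbind(1, t(trans$predictors[parents, , drop = FALSE]))
    fit <- .ols_fit(X, matrix(trans$responses[i, ], nrow = 1))
    if (is.null(fit)) {                       # collinear survivors: intercept only
      X <- matrix(1, n, 1)
      parents <- integer()
      fit <- .ols_fit(X, matrix(trans$responses[i, ], nrow = 1))
    }
    beta <- fit$beta[, 1]
    b0[i] <- beta[1]
    if (length(parents)) A[i, parents] <- beta[-1]
    fitted[i, ] <- as.numeric(X %*% beta)
  }
  res <- trans$responses - fitted
  dfree <- pmax(1, n - 1 - tabulate(match(net$edges$target, net$gene_ids), p))
  sigma <- sqrt(rowSums(res^2) / dfree)

  structure(list(gene_ids = net$gene_ids, edges = net$edges, scores = scores,
                 coefficients = A, intercept = b0, fitted = fitted,
                 residuals = res, sigma = sigma,
                 alpha1 = alpha1, alpha2 = alpha2, allow_self = allow_self,
                 series = series, call = cl),
            class = c("grn_fit", "grn"))
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("Lag-1 regulatory network fit\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d genes, %d time points, alpha1 = %g, alpha2 = %g\n",
              length(x$gene_ids), length(x$series$time_labels_h),
              x$alpha1, x$alpha2))
  cat(sprintf("Inferred regulations: %d\n", nrow(x$edges)))
  invisible(x)
}

#' @export
#' @rdname grn_fit
#' @param object,x a `grn_fit` object.
#' @param ... unused.
summary.grn_fit <- function(object, ...) {
  out <- list(call = object$call, n_genes = length(object$gene_ids),
              n_edges = nrow(object$edges),
              stats = network_summary(object, label = "fit"),
              alpha1 = object$alpha1, alpha2 = object$alpha2)
  class(out) <- "summary.grn_fit"
  out
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  cat("Lag-1 regulatory network fit\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat(sprintf("Genes: %d   Regulations: %d   (alpha1 = %g, alpha2 = %g)\n\n",
              x$n_genes, x$n_edges, x$alpha1, x$alpha2))
  cat("Network statistics panel:\n")
  print(as.data.frame(x$stats), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.grn_fit <- function(object, ...) object$coefficients

#' @export
residuals.grn_fit <- function(object, ...) object$residuals

#' One-step-ahead predictions from a fitted network
#'
#' Predicts expression at each time point from the previous one using the
#' estimated lag-1 coefficients: column k of the result predicts column k + 1
#' of the series.
#'
#' @param object a [grn_fit()] object.
#' @param newdata an [expression_series()] over the same gene panel; defaults
#'   to the training series.
#' @param ... unused.
#' @return A p x (T-1) matrix of predicted values.
#' @export
predict.grn_fit <- function(object, newdata = object$series, ...) {
  stopifnot(inherits(newdata, "expression_series"))
  if (!identical(newdata$gene_ids, object$gene_ids)) {
    stop("`newdata` must cover the fitted gene panel in the same order",
         call. = FALSE)
  }
  X <- newdata$values[, -ncol(newdata$values), drop = FALSE]
  pred <- object$intercept + object$coefficients %*% X
  colnames(pred) <- colnames(newdata$values)[-1]
  pred
}

#' Simulate series from a fitted network
#'
#' Draws new expression time series from the fitted VAR(1) model, using the
#' estimated coefficients, intercepts and per-gene residual standard
#' deviations. Useful for parametric-bootstrap style checks of downstream
#' statistics.
#'
#' @param object a [grn_fit()] object.
#' @param nsim number of series to draw.
#' @param seed integer seed.
#' @param time_labels_h sampling times of the simulated series; defaults to
#'   the training design.
#' @param ... unused.
#' @return A list of `nsim` [expression_series()] objects.
#' @export
simulate.grn_fit <- function(object, nsim = 1, seed = 1L,
                             time_labels_h = object$series$time_labels_h, ...) {
  p <- length(object$gene_ids)
  T <- length(time_labels_h)
  local_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      X <- matrix(0, p, T)
      X[, 1] <- stats::rnorm(p)
      for (k in 2:T) {
        X[, k] <- object$intercept + object$coefficients %*% X[, k - 1] +
          stats::rnorm(p, sd = object$sigma)
      }
      expression_series(X, gene_ids = object$gene_ids,
                        time_labels_h = time_labels_h)
    })
  })
}

#' Plot the degree distribution of a fitted network
#'
#' Log-log plot of the total-degree histogram with the least-squares
#' power-law line of [fit_power_law()] overlaid (when enough distinct degrees
#' exist to fit one).
#'
#' @param x a `grn_fit` (or any [grn()]) object.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [fit_power_law()] result (or `NULL`).
#' @export
plot.grn <- function(x, ...) {
  hist <- degree_histogram(x)
  tab <- hist$total[hist$total$degree >= 1 & hist$total$count >= 1, ]
  if (nrow(tab) == 0) {
    stop("network has no positive-degree nodes to plot", call. = FALSE)
  }
  graphics::plot(log10(tab$degree), log10(tab$count),
                 xlab = "log10 degree", ylab = "log10 node count",
                 pch = 19, ...)
  fit <- NULL
  if (nrow(tab) >= 2) {
    fit <- fit_power_law(hist)
    graphics::abline(fit$intercept, fit$slope, lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("slope %.2f, R2 %.3f",
                                      fit$slope, fit$r_squared))
  }
  invisible(fit)
}
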