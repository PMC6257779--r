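#' Lagged transition pairs of a time series
#'
#' Pairs every time point with its successor: column k of `predictors` holds
#' the expression values at the k-th retained time point and column k of
#' `responses` the values at the (k+1)-th. Consecutive retained observations
#' are treated as unit-lag transitions whatever the hour spacing — the same
#' approximation the deletion experiment relies on.
#'
#' @param series an [expression_series()].
#' @return An object of class `transition_set` with elements `predictors`
#'   (p x (T-1)), `responses` (p x (T-1)), `n_transitions` and `gene_ids`.
#' @export
build_transitions <- function(series) {
  stopifnot(inherits(series, "expression_series"))
  T <- ncol(series$values)
  if (T < 2) stop("need at least 2 time points to form transitions", call. = FALSE)
  structure(list(predictors = series$values[, -T, drop = FALSE],
                 responses = series$values[, -1, drop = FALSE],
                 n_transitions = T - 1L,
                 gene_ids = series$gene_ids),
            class = "transition_set")
}

# Coefficient t-test p-values for the fixed design `X` (n x q), regressing
# every row of `Y` (p x n) on X at once via the normal equations.  Returns
# list(p = q x p p-value matrix, beta = q x p estimates), or NULL when the
# design is (numerically) rank deficient or df < 1.
.ols_fit <- function(X, Y) {
  n <- nrow(X)
  q <- ncol(X)
  df <- n - q
  if (df < 1) return(NULL)
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  if (is.null(XtX_inv)) return(NULL)
  B <- XtX_inv %*% crossprod(X, t(Y))          # q x p coefficients
  res <- t(Y) - X %*% B                        # n x p residuals
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(XtX_inv), sigma2))     # q x p standard errors
  tval <- B / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  # exact fits: se = 0 gives t = Inf (evidence) or 0/0 (none)
  bad <- !is.finite(tval)
  if (any(bad)) p[bad] <- ifelse(B[bad] == 0, 1, 0)
  list(p = unname(p), beta = unname(B))
}

# p-values for one coefficient across all targets
.ols_coef_pvals <- function(X, Y, index) {
  fit <- .ols_fit(X, Y)
  if (is.null(fit)) return(NULL)
  list(p = fit$p[index, ], beta = fit$beta[index, ])
}

#' First-order conditional-dependence scores (step 1)
#'
#' Scores every candidate edge j -> i by the *worst case* over single
#' conditioning genes: `s1[i, j]` is the maximum, over conditioning genes z
#' not in \{j\} (and z != i when self-regulation is excluded), of the
#' two-sided p-value for the coefficient of gene j's lagged values in the
#' least-squares regression of gene i's responses on an intercept, lagged j
#' and lagged z. A small score therefore marks a dependence that survives
#' adjustment for any single confounder. With only two genes no conditioning
#' gene exists and the simple-regression p-value is used.
#'
#' @param transitions a [build_transitions()] result with at least 4
#'   transitions (each regression fits 3 parameters).
#' @param exclude_self should self-edges be left unscored (default)?
#' @return An object of class `score_matrix`: list with `s1` (p x p matrix of
#'   p-values in \[0, 1\], `NA` for unscored pairs), `exclude_self`,
#'   `gene_ids`.
#' @export
score_step1 <- function(transitions, exclude_self = TRUE) {
  stopifnot(inherits(transitions, "transition_set"))
  P <- transitions$predictors
  R <- transitions$responses
  n <- transitions$n_transitions
  p <- nrow(P)
  if (n < 4) {
    stop("need at least 4 transitions to score edges (3 fitted parameters)",
         call. = FALSE)
  }
  s1 <- matrix(NA_real_, p, p, dimnames = list(transitions$gene_ids,
                                               transitions$gene_ids))
  pred_var <- apply(P, 1, stats::var)
  degenerate <- pred_var == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " predictor gene(s) with zero variance scored 1",
            call. = FALSE)
  }

  scored <- function(j) {        # target indices scored for predictor j
    if (exclude_self) setdiff(seq_len(p), j) else seq_len(p)
  }

  for (j in seq_len(p)) {
    idx <- scored(j)
    if (length(idx) == 0) next
    if (degenerate[j]) {
      s1[idx, j] <- 1
      next
    }
    conditioners <- setdiff(seq_len(p), j)
    conditioners <- conditioners[!degenerate[conditioners]]
    acc <- rep(-Inf, p)          # running max over conditioners, by target
    hit <- rep(FALSE, p)
    for (z in conditioners) {
      X <- cbind(1, P[j, ], P[z, ])
      fit <- .ols_coef_pvals(X, R, 2L)
      if (is.null(fit)) next     # lagged j and z collinear
      upd <- idx
      if (exclude_self) upd <- setdiff(upd, z)
      acc[upd] <- pmax(acc[upd], fit$p[upd])
      hit[upd] <- TRUE
    }
    if (!all(hit[idx])) {
      # no admissible conditioning gene (p = 2, or all degenerate/collinear):
      # fall back to the simple regression
      X <- cbind(1, P[j, ])
      fit <- .ols_coef_pvals(X, R, 2L)
      miss <- idx[!hit[idx]]
      acc[miss] <- if (is.null(fit)) 1 else fit$p[miss]
    }
    s1[idx, j] <- acc[idx]
  }
  structure(list(s1 = s1, exclude_self = exclude_self,
                 gene_ids = transitions$gene_ids),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  sc <- x$s1[!is.na(x$s1)]
  cat(sprintf("Edge score matrix: %d genes, %d scored pairs, min score %.3g\n",
              length(x$gene_ids), length(sc),
              if (length(sc)) min(sc) else NA_real_))
  invisible(x)
}

#' Threshold step-1 scores into a candidate network
#'
#' @param scores a [score_step1()] result.
#' @param alpha1 retain edge j -> i when `s1[i, j] <= alpha1`; in (0, 1].
#' @return A [grn()] whose edge scores are the step-1 p-values.
#' @export
threshold_step1 <- function(scores, alpha1) {
  stopifnot(inherits(scores, "score_matrix"))
  check_alpha(alpha1, "alpha1")
  keep <- which(!is.na(scores$s1) & scores$s1 <= alpha1, arr.ind = TRUE)
  grn(scores$gene_ids,
      data.frame(predictor = scores$gene_ids[keep[, 2]],
                 target = scores$gene_ids[keep[, 1]],
                 score = scores$s1[keep],
                 stringsAsFactors = FALSE))
}

#' Joint-regression pruning (step 2)
#'
#' For each target gene, all its candidate parents enter one multiple
#' least-squares regression (intercept plus every parent's lagged values);
#' an edge survives iff the two-sided p-value of its coefficient is at most
#' `alpha2`. If a target has more candidate parents than the regression can
#' support (`n_transitions - 2`), parents are ranked by their step-1 score and
#' truncated to fit, with a warning.
#'
#' @param transitions a [build_transitions()] result.
#' @param candidate a [grn()] of candidate edges (scores used for ranking).
#' @param alpha2 significance threshold in (0, 1].
#' @return A [grn()] over the full gene panel; edge scores are the step-2
#'   p-values.
#' @export
prune_step2 <- function(transitions, candidate, alpha2) {
  stopifnot(inherits(transitions, "transition_set"), inherits(candidate, "grn"))
  check_alpha(alpha2, "alpha2")
  P <- transitions$predictors
  R <- transitions$responses
  n <- transitions$n_transitions
  ids <- transitions$gene_ids
  if (!identical(sort(ids), sort(candidate$gene_ids))) {
    stop("candidate network and transitions cover different gene panels",
         call. = FALSE)
  }
  max_parents <- n - 2L
  out <- vector("list", length(ids))
  truncated <- 0L
  for (i in seq_along(ids)) {
    ed <- candidate$edges[candidate$edges$target == ids[i], , drop = FALSE]
    if (nrow(ed) == 0) next
    if (nrow(ed) > max_parents) {
      ed <- ed[order(ed$score), , drop = FALSE][seq_len(max_parents), , drop = FALSE]
      truncated <- truncated + 1L
    }
    parents <- match(ed$predictor, ids)
    X <- cbind(1, t(P[parents, , drop = FALSE]))
    y <- matrix(R[i, ], nrow = 1)
    fit <- .ols_fit(X, y)
    # collinear parent sets carry no separable evidence for any single edge
    pv <- if (is.null(fit)) rep(1, length(parents)) else fit$p[-1, 1]
    keep <- pv <= alpha2
    if (any(keep)) {
      out[[i]] <- data.frame(predictor = ed$predictor[keep],
                             target = ids[i],
                             score = pv[keep],
                             stringsAsFactors = FALSE)
    }
  }
  if (truncated > 0) {
    warning(truncated, " target(s) had more candidate parents than ",
            "transitions allow; kept the best-scored ", max_parents,
            call. = FALSE)
  }
  grn(candidate$gene_ids, do.call(rbind, out))
}
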