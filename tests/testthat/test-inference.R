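test_that("transitions pair consecutive time points", {
  s <- expression_series(matrix(c(1, 2, 3), 1), gene_ids = "g1",
                         time_labels_h = c(0, 1, 2))
  tr <- build_transitions(s)
  expect_identical(tr$n_transitions, 2L)
  expect_equal(unname(tr$predictors[1, ]), c(1, 2))
  expect_equal(unname(tr$responses[1, ]), c(2, 3))

  m <- generate_ground_truth(p = 4, seed = 1)
  s11 <- simulate_expression(m, seed = 1)                 # 11-point design
  expect_identical(build_transitions(s11)$n_transitions, 10L)

  s2 <- expression_series(matrix(c(1, 2, 5, 3), 2), time_labels_h = c(0, 1))
  tr2 <- build_transitions(s2)
  expect_identical(tr2$n_transitions, 1L)
  expect_equal(unname(tr2$predictors), matrix(c(1, 2), 2))
  expect_equal(unname(tr2$responses), matrix(c(5, 3), 2))
})

test_that("step-1 scores equal the exhaustive regression oracle", {
  # a 3-gene system with one strong edge, every conditioning choice checked
  series <- chain_series(coef = 0.9, noise_sd = 0.05, T = 30, p = 3, seed = 11)
  tr <- build_transitions(series)
  got <- score_step1(tr)
  expect_equal(got$s1, oracle_score_step1(tr), tolerance = 1e-10)
  # the true edge scores far below the null pairs
  expect_lt(got$s1["g2", "g1"], 0.01)

  # self-edges unscored by default, scored when allowed
  expect_true(all(is.na(diag(got$s1))))
  got_self <- score_step1(tr, exclude_self = FALSE)
  expect_equal(got_self$s1, oracle_score_step1(tr, exclude_self = FALSE),
               tolerance = 1e-10)
  expect_true(all(!is.na(diag(got_self$s1))))
})

test_that("step-1 and step-2 p-values match lm() on random instances", {
  for (s in 1:25) {
    set.seed(s)
    p <- sample(3:5, 1)
    T <- sample(8:15, 1)
    series <- expression_series(matrix(rnorm(p * T), p),
                                time_labels_h = seq_len(T) - 1)
    tr <- build_transitions(series)
    expect_equal(score_step1(tr)$s1, oracle_score_step1(tr),
                 tolerance = 1e-10, info = paste("seed", s))

    # step 2 with a single parent per target is the simple-regression test
    ids <- series$gene_ids
    cand <- grn(ids, data.frame(predictor = ids[c(2, 3)], target = ids[c(1, 2)],
                                score = 0.5))
    pruned <- prune_step2(tr, cand, alpha2 = 1)
    for (k in seq_len(nrow(pruned$edges))) {
      i <- match(pruned$edges$target[k], ids)
      j <- match(pruned$edges$predictor[k], ids)
      expect_equal(pruned$edges$score[k],
                   oracle_lm_pvalue(tr$responses[i, ],
                                    cbind(1, tr$predictors[j, ]), 2),
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate inputs score 1 rather than erroring", {
  s <- expression_series(matrix(0, 4, 8), time_labels_h = 0:7)
  tr <- build_transitions(s)
  expect_warning(sc <- score_step1(tr), "zero variance")
  expect_true(all(sc$s1[!is.na(sc$s1)] == 1))
})

test_that("scoring demands enough transitions", {
  s <- expression_series(matrix(rnorm(12), 3), time_labels_h = 0:3)
  expect_error(score_step1(build_transitions(s)), "at least 4 transitions")
})

test_that("pre-max p-values are uniform under the null", {
  # with 2 genes the conditioning set is empty: raw simple-regression p-values
  pvals <- unlist(lapply(1:1000, function(s) {
    set.seed(s)
    series <- expression_series(matrix(rnorm(2 * 12), 2),
                                time_labels_h = 0:11)
    s1 <- score_step1(build_transitions(series))$s1
    s1[!is.na(s1)]
  }))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("max-over-conditioners scoring is conservative under the null", {
  frac <- mean(unlist(lapply(1:500, function(s) {
    set.seed(s)
    series <- expression_series(matrix(rnorm(3 * 30), 3),
                                time_labels_h = 0:29)
    s1 <- score_step1(build_transitions(series))$s1
    s1[!is.na(s1)] < 0.05
  })))
  se <- sqrt(0.05 * 0.95 / (500 * 6))
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("thresholding filters by score with subset monotonicity", {
  ids <- c("a", "b", "c")
  s1 <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  s1["b", "a"] <- 0.001
  s1["a", "c"] <- 0.5
  sc <- structure(list(s1 = s1, exclude_self = TRUE, gene_ids = ids),
                  class = "score_matrix")
  net <- threshold_step1(sc, 0.05)
  expect_identical(net$edges$predictor, "a")
  expect_identical(net$edges$target, "b")
  expect_identical(nrow(threshold_step1(sc, 1)$edges), 2L)     # everything scored
  expect_identical(nrow(threshold_step1(sc, 1e-4)$edges), 0L)  # below the minimum
  expect_error(threshold_step1(sc, 0), "alpha1")
  expect_error(threshold_step1(sc, 1.5), "alpha1")

  # nesting across thresholds on real scores
  series <- chain_series(T = 20, p = 4, seed = 3)
  sc <- score_step1(build_transitions(series))
  for (pair in list(c(0.05, 0.2), c(0.2, 0.8), c(0.01, 1))) {
    lo <- edge_keys(threshold_step1(sc, pair[1]))
    hi <- edge_keys(threshold_step1(sc, pair[2]))
    expect_true(all(lo %in% hi))
  }
})

test_that("pruning keeps the panel, honors boundaries and truncates overfull parents", {
  series <- chain_series(T = 12, p = 4, seed = 5)
  tr <- build_transitions(series)
  ids <- series$gene_ids

  empty <- grn(ids)
  expect_identical(nrow(prune_step2(tr, empty, 0.05)$edges), 0L)
  expect_identical(prune_step2(tr, empty, 0.05)$gene_ids, ids)

  sc <- score_step1(tr)
  cand <- threshold_step1(sc, 0.9)
  kept <- prune_step2(tr, cand, 1)
  expect_setequal(edge_keys(kept), edge_keys(cand))   # alpha2 = 1: set unchanged

  # more parents than transitions support: ranked by step-1 score, truncated
  tiny <- expression_series(matrix(rnorm(6 * 6), 6), time_labels_h = 0:5)
  trt <- build_transitions(tiny)
  cand_all <- grn(tiny$gene_ids,
                  data.frame(predictor = tiny$gene_ids[2:6],
                             target = tiny$gene_ids[1],
                             score = c(0.01, 0.02, 0.03, 0.04, 0.05)))
  expect_warning(out <- prune_step2(trt, cand_all, 1), "truncated|kept the best")
  expect_lte(nrow(out$edges), trt$n_transitions - 2)
  expect_true(all(out$edges$predictor %in% tiny$gene_ids[2:4]))
  expect_error(prune_step2(tr, cand, 2), "alpha2")
})

test_that("grn_fit composes the three stages and recovers planted structure", {
  series <- chain_series(coef = 0.9, noise_sd = 0.05, T = 30, p = 3, seed = 2)
  fit <- grn_fit(series, alpha1 = 0.5, alpha2 = 0.05)
  tr <- build_transitions(series)
  manual <- prune_step2(tr, threshold_step1(score_step1(tr), 0.5), 0.05)
  expect_identical(fit$edges, manual$edges)
  expect_true("g1\rg2" %in% edge_keys(fit))

  # all-zero series: empty edge set (and no error)
  zero <- expression_series(matrix(0, 5, 11), time_labels_h = 0:10)
  expect_identical(nrow(suppressWarnings(grn_fit(zero))$edges), 0L)
})

test_that("fit methods are mutually consistent", {
  series <- chain_series(coef = 0.8, noise_sd = 0.1, T = 25, p = 4, seed = 9)
  fit <- grn_fit(series)
  # coefficients live exactly on the edge set
  nz <- which(coef(fit) != 0, arr.ind = TRUE)
  keys <- paste(fit$gene_ids[nz[, 2]], fit$gene_ids[nz[, 1]], sep = "\r")
  expect_setequal(keys, edge_keys(fit))
  # one-step-ahead predictions + residuals reproduce the responses
  pred <- predict(fit)
  expect_equal(pred + residuals(fit),
               series$values[, -1], tolerance = 1e-12, ignore_attr = TRUE)
  # simulate returns series of the requested shape, deterministically
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]$values), dim(series$values))
  expect_identical(simulate(fit, seed = 4)[[1]]$values, sims[[1]]$values)
  # summary carries the statistics panel
  sm <- summary(fit)
  expect_s3_class(sm, "summary.grn_fit")
  expect_equal(sm$stats$Rn, nrow(fit$edges))
})

test_that("inferred networks may contain directed cycles", {
  # two genes driving each other: feedback must be representable
  A <- matrix(c(0, 0.7, -0.7, 0), 2, 2)
  model <- ground_truth_model(c("a", "b"), A, noise_sd = 0.05)
  series <- simulate_expression(model, time_labels_h = 0:29, seed = 6)
  fit <- grn_fit(series)
  expect_setequal(edge_keys(fit), c("a\rb", "b\ra"))
})
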