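path_abc <- grn(c("a", "b", "c"),
                data.frame(predictor = c("a", "b"), target = c("b", "c")))

test_that("degree metrics follow the total-degree convention", {
  # study-scale identity: N = 800, Rn = 447 gives K = 2 * 447 / 800 = 1.1175
  net <- random_digraph_n_edges(800, 447, seed = 1)
  dm <- degree_metrics(net)
  expect_identical(dm$Rn, 447L)
  expect_equal(dm$K, 1.1175)

  empty <- grn(letters[1:5])
  dm0 <- degree_metrics(empty)
  expect_equal(dm0$K, 0)
  expect_identical(dm0$N0, 5L)
  expect_identical(dm0$Rn, 0L)

  tri <- grn(c("a", "b", "c"),
             data.frame(predictor = c("a", "b", "c"), target = c("b", "c", "a")))
  dmt <- degree_metrics(tri)
  expect_true(all(dmt$indegree == 1) && all(dmt$outdegree == 1))
  expect_equal(dmt$K, 2)
  # histogram counts cover the whole panel
  expect_identical(sum(dmt$histogram$total$count), 3L)
})

test_that("path metrics handle chains, complete graphs and dead networks", {
  pm <- path_metrics(path_abc)
  expect_equal(pm$Dia, 2)
  expect_equal(pm$l, (1 + 1 + 2) / 3)
  expect_equal(pm$E, (1 + 1 + 0.5) / 6)

  ids <- letters[1:4]
  pairs <- expand.grid(predictor = ids, target = ids, stringsAsFactors = FALSE)
  complete <- grn(ids, pairs[pairs$predictor != pairs$target, ])
  pmc <- path_metrics(complete)
  expect_equal(pmc$Dia, 1)
  expect_equal(pmc$l, 1)
  expect_equal(pmc$E, 1)

  dead <- path_metrics(grn(letters[1:3]))
  expect_equal(dead$Dia, 0)
  expect_equal(dead$l, 0)
  expect_equal(dead$E, 0)
  expect_false(dead$defined)
})

test_that("betweenness matches geodesic enumeration", {
  b <- betweenness_scores(path_abc)
  expect_equal(unname(b), c(0, 1, 0))

  # directed 4-cycle: each node lies inside the geodesics of (s, t) pairs at
  # distance 2 and 3; enumeration gives 3 per node
  cyc <- grn(letters[1:4], data.frame(predictor = c("a", "b", "c", "d"),
                                      target = c("b", "c", "d", "a")))
  expect_equal(unname(betweenness_scores(cyc)), rep(3, 4))
  expect_equal(betweenness_scores(cyc), oracle_betweenness(cyc))
})

test_that("clustering coefficient and centralization match their definitions", {
  tri <- grn(c("a", "b", "c"),
             data.frame(predictor = c("a", "b", "c"), target = c("b", "c", "a")))
  expect_equal(clustering_coefficient(tri), 1)

  star <- grn(c("hub", paste0("leaf", 1:4)),
              data.frame(predictor = "hub", target = paste0("leaf", 1:4)))
  expect_equal(clustering_coefficient(star), 0)
  expect_equal(centralization(star)$Ce, 1)

  # both-direction star is still maximally centralized on the projection
  star2 <- grn(c("hub", paste0("leaf", 1:4)),
               data.frame(predictor = c(rep("hub", 4), paste0("leaf", 1:4)),
                          target = c(paste0("leaf", 1:4), rep("hub", 4))))
  expect_equal(centralization(star2)$Ce, 1)

  ring <- grn(letters[1:5], data.frame(predictor = letters[1:5],
                                       target = letters[c(2:5, 1)]))
  expect_equal(centralization(ring)$Ce, 0)
  expect_false(centralization(grn(c("a", "b")))$defined)
})

test_that("vulnerability captures the worst single-node removal", {
  vu <- max_vulnerability(path_abc)
  expect_equal(vu$Vu, 1)           # removing b destroys every path
  expect_identical(vu$most_vulnerable, "b")

  ids <- letters[1:4]
  pairs <- expand.grid(predictor = ids, target = ids, stringsAsFactors = FALSE)
  complete <- grn(ids, pairs[pairs$predictor != pairs$target, ])
  expect_equal(max_vulnerability(complete)$Vu, 0)
})

test_that("all graph statistics equal brute-force oracles on random digraphs", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(3:8, 1)
    net <- random_digraph(n, q = runif(1, 0.1, 0.5), seed = s * 13)
    pm <- path_metrics(net)
    opm <- oracle_path_metrics(net)
    expect_equal(pm$Dia, opm$Dia, info = paste("seed", s))
    expect_equal(pm$l, opm$l, info = paste("seed", s))
    expect_equal(pm$E, opm$E, info = paste("seed", s))
    expect_equal(clustering_coefficient(net), oracle_clustering(net),
                 info = paste("seed", s))
    expect_equal(max_vulnerability(net)$Vu, oracle_vulnerability(net),
                 info = paste("seed", s))
    if (n <= 7) {
      expect_equal(betweenness_scores(net), oracle_betweenness(net),
                   info = paste("seed", s))
    }
  }
})

test_that("network_summary assembles the panel consistently", {
  row <- network_summary(path_abc, "path")
  expect_identical(row$label, "path")
  expect_equal(row$K, 2 * row$Rn / 3)
  expect_equal(row$Dia, 2)
  expect_equal(row$Vu, 1)

  e <- network_summary(grn(letters[1:6]), "empty")
  expect_equal(e$K, 0)
  expect_identical(e$N0, 6L)
  expect_equal(e$E, 0)
  expect_equal(e$Vu, 0)
  expect_equal(e$CC, 0)

  for (s in 1:5) {
    net <- random_digraph(6, 0.3, seed = s)
    r <- network_summary(net)
    expect_equal(r$K, 2 * r$Rn / 6)
  }
})

test_that("metrics are invariant under gene relabeling", {
  net <- random_digraph(7, 0.3, seed = 42)
  relabeled <- grn(paste0("X", seq_along(net$gene_ids)),
                   data.frame(
                     predictor = paste0("X", match(net$edges$predictor,
                                                   net$gene_ids)),
                     target = paste0("X", match(net$edges$target,
                                                net$gene_ids))))
  a <- as.data.frame(network_summary(net))[-1]
  b <- as.data.frame(network_summary(relabeled))[-1]
  expect_equal(a, b)
})

test_that("removing an edge never helps connectivity", {
  for (s in 1:10) {
    net <- random_digraph(7, 0.35, seed = 100 + s)
    if (nrow(net$edges) == 0) next
    drop <- sample(nrow(net$edges), 1)
    sub <- grn(net$gene_ids, net$edges[-drop, , drop = FALSE])
    expect_lte(path_metrics(sub)$E, path_metrics(net)$E)
    expect_lte(degree_metrics(sub)$Rn, degree_metrics(net)$Rn)
    expect_lte(degree_metrics(sub)$K, degree_metrics(net)$K)
    expect_gte(degree_metrics(sub)$N0, degree_metrics(net)$N0)
  }
})

test_that("power-law fits recover constructed exponents", {
  h <- data.frame(degree = 1:10, count = round(1000 * (1:10)^-2))
  fit <- fit_power_law(h)
  expect_lt(abs(fit$slope - (-2)), 0.05)
  expect_gte(fit$r_squared, 0.999)

  flat <- data.frame(degree = 1:10, count = rep(5L, 10))
  expect_lt(abs(fit_power_law(flat)$slope), 0.05)

  expect_error(fit_power_law(data.frame(degree = 3, count = 7)),
               "at least 2")

  # also accepts full histograms from a network
  net <- random_digraph(8, 0.5, seed = 3)
  expect_no_error(fit_power_law(degree_histogram(net)))
})
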