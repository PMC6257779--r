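# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately naive: loops, enumeration and lm(), no igraph
# and no shared code with R/.

# p-value of the coefficient of `xcol` in lm(y ~ X[, -1]) via summary.lm
oracle_lm_pvalue <- function(y, X, index) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  names(df) <- paste0("v", seq_along(df))
  df$y <- y
  fit <- lm(y ~ ., data = df)
  unname(summary(fit)$coefficients[index, 4])
}

# step-1 score matrix recomputed by exhaustive looping over conditioners
oracle_score_step1 <- function(transitions, exclude_self = TRUE) {
  P <- transitions$predictors
  R <- transitions$responses
  p <- nrow(P)
  s1 <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (exclude_self && i == j) next
      zs <- setdiff(seq_len(p), j)
      if (exclude_self) zs <- setdiff(zs, i)
      if (length(zs) == 0) {
        s1[i, j] <- oracle_lm_pvalue(R[i, ], cbind(1, P[j, ]), 2)
      } else {
        s1[i, j] <- max(vapply(zs, function(z) {
          oracle_lm_pvalue(R[i, ], cbind(1, P[j, ], P[z, ]), 2)
        }, numeric(1)))
      }
    }
  }
  dimnames(s1) <- list(transitions$gene_ids, transitions$gene_ids)
  s1
}

# adjacency matrix (directed, no self loops) of a grn
oracle_adjacency <- function(net) {
  p <- length(net$gene_ids)
  A <- matrix(FALSE, p, p, dimnames = list(net$gene_ids, net$gene_ids))
  if (nrow(net$edges)) {
    A[cbind(match(net$edges$predictor, net$gene_ids),
            match(net$edges$target, net$gene_ids))] <- TRUE
  }
  A
}

# all-pairs shortest directed path lengths, Floyd-Warshall
oracle_distances <- function(net) {
  A <- oracle_adjacency(net)
  p <- nrow(A)
  d <- matrix(Inf, p, p)
  d[A] <- 1
  diag(d) <- 0
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_path_metrics <- function(net) {
  d <- oracle_distances(net)
  p <- nrow(d)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) return(list(Dia = 0, l = 0, E = 0))
  list(Dia = max(fin), l = mean(fin), E = sum(1 / fin) / (p * (p - 1)))
}

# unnormalized directed betweenness by exhaustive simple-path enumeration
oracle_betweenness <- function(net) {
  A <- oracle_adjacency(net)
  p <- nrow(A)
  d <- oracle_distances(net)
  # enumerate all simple paths from s to t, keep geodesics
  geodesics <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        if (length(path) - 1 == d[s, t]) out[[length(out) + 1]] <<- path
        return()
      }
      if (length(path) - 1 >= d[s, t]) return()
      for (w in which(A[v, ])) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    out
  }
  B <- numeric(p)
  for (s in seq_len(p)) {
    for (t in seq_len(p)) {
      if (s == t || !is.finite(d[s, t])) next
      paths <- geodesics(s, t)
      g <- length(paths)
      for (v in seq_len(p)) {
        if (v == s || v == t) next
        g_v <- sum(vapply(paths, function(pp) v %in% pp, logical(1)))
        B[v] <- B[v] + g_v / g
      }
    }
  }
  names(B) <- net$gene_ids
  B
}

# transitivity on the undirected projection by triple enumeration
oracle_clustering <- function(net) {
  A <- oracle_adjacency(net)
  U <- A | t(A)
  diag(U) <- FALSE
  p <- nrow(U)
  deg <- rowSums(U)
  triples <- sum(choose(deg, 2))
  tri <- 0
  if (p >= 3) {
    for (u in seq_len(p - 2)) for (v in (u + 1):(p - 1)) for (w in (v + 1):p) {
      if (U[u, v] && U[v, w] && U[u, w]) tri <- tri + 1
    }
  }
  if (triples == 0) 0 else 3 * tri / triples
}

# maximum vulnerability by per-node removal and recomputation
oracle_vulnerability <- function(net) {
  E <- oracle_path_metrics(net)$E
  if (E == 0) return(0)
  p <- length(net$gene_ids)
  drops <- vapply(seq_len(p), function(i) {
    keep <- net$gene_ids[-i]
    ed <- net$edges[net$edges$predictor %in% keep &
                      net$edges$target %in% keep, , drop = FALSE]
    Ei <- if (length(keep) < 2) 0 else oracle_path_metrics(grn(keep, ed))$E
    (E - Ei) / E
  }, numeric(1))
  max(drops)
}

# random directed graph over n nodes with edge probability q
random_digraph <- function(n, q = 0.25, seed = 1) {
  set.seed(seed)
  ids <- letters[seq_len(n)]
  pairs <- expand.grid(predictor = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$predictor != pairs$target, ]
  keep <- runif(nrow(pairs)) < q
  grn(ids, pairs[keep, , drop = FALSE])
}

# random directed graph with an exact edge count (no self loops)
random_digraph_n_edges <- function(n, m, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%04d", seq_len(n))
  idx <- sample(n * (n - 1), m)
  pred <- (idx - 1) %/% (n - 1) + 1
  off <- (idx - 1) %% (n - 1) + 1
  targ <- ifelse(off >= pred, off + 1, off)
  grn(ids, data.frame(predictor = ids[pred], target = ids[targ]))
}

# small seeded series from a 1-edge chain model, used across tests
chain_series <- function(coef = 0.9, noise_sd = 0.05, T = 30, p = 3,
                         seed = 1) {
  A <- matrix(0, p, p)
  A[2, 1] <- coef
  model <- ground_truth_model(paste0("g", seq_len(p)), A, noise_sd = noise_sd)
  simulate_expression(model, time_labels_h = seq_len(T) - 1, seed = seed)
}
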