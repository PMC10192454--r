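# PCA, Ward clustering, v-test cluster description, correlations.

toy_table <- function() {
  set.seed(101)
  n <- 30
  base <- rnorm(n)
  m <- cbind(t1 = base + rnorm(n, sd = 0.3),
             t2 = 2 * base + rnorm(n, sd = 0.3),
             t3 = rnorm(n),
             t4 = rnorm(n))
  rownames(m) <- paste0("cross", seq_len(n))
  m
}

test_that("standardized PCA: variance shares, sign convention, distances", {
  # two perfectly correlated traits -> one component carries everything
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  pc <- pca_standardized(x)
  expect_equal(pc$explained_pct[1], 100, tolerance = 1e-8)
  expect_equal(sum(pc$explained_pct), 100, tolerance = 1e-8)

  m <- toy_table()
  pc2 <- pca_standardized(m)
  expect_true(all(diff(pc2$explained_pct) <= 1e-12))  # decreasing order
  # deterministic sign: dominant loading positive in every component
  for (k in seq_len(ncol(pc2$loadings))) {
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, k])), k], 0)
  }
  # orthogonal transform preserves pairwise distances of standardized data
  expect_equal(as.matrix(dist(pc2$scores)), as.matrix(dist(scale(m))),
               tolerance = 1e-8)
})

test_that("PCA input handling: imputation, dropped traits, small n", {
  m <- toy_table()[1:6, ]
  m[2, "t3"] <- NA
  expect_warning(pca_standardized(m), "imputed")
  m2 <- cbind(toy_table()[1:6, 1:2], flat = 5)
  expect_warning(pca_standardized(m2), "zero-variance")
  expect_error(pca_standardized(toy_table()[1:2, ]),
               class = "kola_validation_error")
})

test_that("two separated blobs cluster perfectly with auto-k", {
  set.seed(9)
  x <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60) + 10, ncol = 2))
  colnames(x) <- c("t1", "t2")
  rownames(x) <- paste0("c", seq_len(nrow(x)))
  cl <- hcpc_cluster(pca_standardized(x), k = "auto", k_range = 2:6)
  expect_equal(cl$k, 2L)
  a <- cl$assignments
  expect_length(unique(a[1:30]), 1L)
  expect_length(unique(a[31:60]), 1L)
  expect_false(a[1] == a[31])
})

test_that("k = n gives singleton clusters with zero inertia; k > n errors", {
  m <- toy_table()[1:8, ]
  cl <- hcpc_cluster(pca_standardized(m), k = 8)
  expect_equal(length(unique(cl$assignments)), 8L)
  expect_equal(cl$within_inertia, 0, tolerance = 1e-12)
  expect_error(hcpc_cluster(pca_standardized(m), k = 9),
               class = "kola_validation_error")
})

test_that("merging order is invariant to row permutation", {
  m <- toy_table()
  cl1 <- hcpc_cluster(pca_standardized(m), k = 3)
  perm <- sample(nrow(m))
  cl2 <- hcpc_cluster(pca_standardized(m[perm, ]), k = 3)
  expect_equal(sort(cl1$merge_heights), sort(cl2$merge_heights),
               tolerance = 1e-9)
  # same partition up to cluster relabelling
  a1 <- cl1$assignments[rownames(m)]
  a2 <- cl2$assignments[rownames(m)]
  expect_equal(length(unique(paste(a1, a2))), 3L)
})

test_that("auto-k on the GX1 fixture follows the inertia-loss rule", {
  g <- kola_fixture("gx1_self")
  pc <- pca_standardized(g)
  cl <- hcpc_cluster(pc, k = "auto")
  expect_true(cl$k %in% 3:6)
  # independent recomputation of the selection rule
  ncomp <- which(cumsum(pc$explained_pct) >= 80)[1]
  s <- pc$scores[, seq_len(ncomp), drop = FALSE]
  hc <- hclust(dist(s), method = "ward.D2")
  W <- vapply(2:6, function(k) {
    sum(vapply(split(seq_len(nrow(s)), cutree(hc, k)), function(idx) {
      sc <- s[idx, , drop = FALSE]
      sum(sweep(sc, 2, colMeans(sc))^2)
    }, 0))
  }, 0)
  rel <- (W[1:4] - W[2:5]) / W[1:4]   # loss moving to k = 3..6
  expect_equal(cl$k, (3:6)[which.max(rel)])
})

test_that("v-test: null cases, sign, brute-force oracle, conservation", {
  m <- toy_table()[1:12, ]
  assign <- rep(1:3, each = 4)
  names(assign) <- rownames(m)
  ds <- describe_clusters(assign, m)

  # sign of v equals sign of (category mean - overall mean)
  expect_true(all(sign(ds$v) == sign(ds$category_mean - ds$overall_mean)))

  # brute-force oracle on the same formula, written independently
  N <- nrow(m)
  for (r in sample(nrow(ds), 6)) {
    k <- ds$cluster[r]; tr <- ds$trait[r]
    x <- m[, tr]
    nc <- sum(assign == k)
    vb <- (mean(x[assign == k]) - mean(x)) /
      sqrt((sum((x - mean(x))^2) / N / nc) * (N - nc) / (N - 1))
    expect_equal(ds$v[r], vb, tolerance = 1e-10)
  }

  # conservation: sum of n_c * category means equals N * overall mean
  for (tr in colnames(m)) {
    sub <- ds[ds$trait == tr, ]
    expect_equal(sum(sub$n * sub$category_mean),
                 N * sub$overall_mean[1], tolerance = 1e-9)
  }

  # category mean equal to overall mean -> v = 0, p = 1
  m2 <- cbind(flatish = c(1, 2, 3, 1, 2, 3), other = c(1, 5, 2, 6, 3, 9))
  rownames(m2) <- paste0("c", 1:6)
  ds2 <- describe_clusters(setNames(rep(1:2, each = 3), rownames(m2)), m2)
  row <- ds2[ds2$cluster == 1 & ds2$trait == "flatish", ]
  expect_equal(row$v, 0)
  expect_equal(row$p_value, 1)
})

test_that("correlations: exact cases, hand-computed r, PSD, significance", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 5, 8, 9)
  m <- cbind(x = x, y = y, negx = -x)
  rownames(m) <- paste0("c", 1:5)
  cr <- correlation_matrix(m)
  expect_equal(cr$r["x", "x"], 1)
  expect_equal(cr$r["x", "negx"], -1)
  # hand computation of Pearson r on the 5-point set
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cr$r["x", "y"], r_hand, tolerance = 1e-12)
  expect_equal(cr$r, t(cr$r))
  expect_true(all(cr$r >= -1 & cr$r <= 1))

  big <- correlation_matrix(toy_table())
  ev <- eigen(big$r, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # p-value matches cor.test
  ct <- cor.test(toy_table()[, "t1"], toy_table()[, "t2"])
  expect_equal(big$p_values["t1", "t2"], ct$p.value, tolerance = 1e-9)

  # < 3 complete pairs -> missing cell
  m3 <- cbind(a = c(1, 2, NA, NA, NA), b = c(2, 1, 3, 4, 5))
  rownames(m3) <- paste0("c", 1:5)
  cr3 <- correlation_matrix(m3)
  expect_true(is.na(cr3$r["a", "b"]))
  expect_equal(cr3$n_pairs["a", "b"], 2L)
})
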