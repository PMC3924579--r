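test_that("PCA variance fractions match an independent eigendecomposition", {
  set.seed(41)
  # n large enough that the random-matrix eigenvalue spread ((1 +/- sqrt(p/n))^2)
  # stays inside the 50% envelope around 1/p
  x <- matrix(rnorm(1024 * 32, 0.5, 0.05), ncol = 32)
  emb <- fit_pca(x)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(emb$var_fractions, ev / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(emb$var_fractions) <= 1e-12))
  expect_lt(abs(sum(emb$var_fractions) - 1), 1e-9)
  # isotropic cloud: each fraction close to 1/32
  expect_true(all(abs(emb$var_fractions - 1 / 32) / (1 / 32) < 0.5))
  # reconstruction with all components returns the centered data
  rec <- emb$scores %*% t(emb$loadings)
  expect_equal(rec, sweep(x, 2, emb$center), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("degenerate geometries are handled deterministically", {
  line <- cbind(seq_len(10), 2 * seq_len(10), -seq_len(10))
  embl <- fit_pca(line)
  expect_equal(embl$var_fractions[1], 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive, so repeated fits agree
  expect_identical(fit_pca(line)$loadings, embl$loadings)
  expect_error(fit_pca(line[1, , drop = FALSE]), "at least 2 rows")
})

test_that("projection preserves (k = p) or contracts (k < p) distances", {
  set.seed(42)
  x <- matrix(runif(40 * 32), ncol = 32)
  emb <- fit_pca(x)
  d_full <- dist(sweep(x, 2, emb$center))
  d32 <- dist(project_scores(emb, 32))
  expect_equal(as.vector(d32), as.vector(d_full), tolerance = 1e-9)
  d6 <- dist(project_scores(emb, 6))
  expect_true(all(as.vector(d6) <= as.vector(d32) + 1e-9))
  expect_error(project_scores(emb, 33), "exceeds")
  # identical rows stay identical
  x2 <- rbind(x, x[1, ], x[1, ])
  s2 <- project_scores(fit_pca(x2), 6)
  expect_equal(s2[41, ], s2[42, ], tolerance = 1e-12)
})

test_that("group distance means match the exhaustive double loop", {
  set.seed(7)
  pts <- rbind(matrix(rnorm(8 * 6, 0, 0.02), ncol = 6),
               sweep(matrix(rnorm(8 * 6, 0, 0.02), ncol = 6), 2,
                     c(0.3, rep(0, 5)), "+"))
  labels <- rep(c("ref", "far"), each = 8)
  rep_df <- group_distances(pts, labels, "ref")
  # brute-force oracle
  cross <- c()
  for (i in 9:16) for (j in 1:8) cross <- c(cross, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  expect_lt(abs(rep_df$cross_mean - mean(cross)), 1e-12)
  win <- c()
  for (i in 9:15) for (j in (i + 1):16) win <- c(win, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  expect_lt(abs(rep_df$within_mean - mean(win)), 1e-12)
  expect_true(rep_df$sig_vs_ref && rep_df$sig_vs_own)
  expect_gt(rep_df$t_vs_ref, 2)
})

test_that("trivial geometries give zero distances and errors on singletons", {
  pts <- matrix(0.5, nrow = 8, ncol = 6)
  labels <- rep(c("a", "b"), each = 4)
  rep_df <- group_distances(pts, labels, "a")
  expect_equal(rep_df$within_mean, 0)
  expect_equal(rep_df$cross_mean, 0)
  expect_error(group_distances(pts[1:5, ], c("a", "a", "a", "a", "b"), "a"),
               "singleton")
})

test_that("the report is invariant to row permutation and pre-rotation", {
  sv <- gen_sync_vectors(list(a = rep(0.4, 32), b = rep(0.55, 32)),
                         noise_sd = 0.03, n_per_group = 8, seed = 9)
  st1 <- run_study(sv, reference_group = "a")
  perm <- sample(nrow(sv))
  st2 <- run_study(sv[perm, ], reference_group = "a")
  expect_equal(st1$distances$cross_mean, st2$distances$cross_mean, tolerance = 1e-9)
  expect_equal(st1$distances$within_mean, st2$distances$within_mean, tolerance = 1e-9)
  # orthogonal rotation applied before PCA leaves all distances unchanged
  x <- as.matrix(sv[, -1])
  q <- qr.Q(qr(matrix(rnorm(32 * 32), 32)))
  svr <- sv
  svr[, -1] <- x %*% q
  emb1 <- fit_pca(sv); emb2 <- fit_pca(svr)
  k <- ncol(emb1$scores)                 # full rank available from 16 sessions
  d1 <- dist(project_scores(emb1, k))
  d2 <- dist(project_scores(emb2, k))
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-9)
})
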