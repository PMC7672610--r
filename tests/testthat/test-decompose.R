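# a normalized object from a random count matrix
toy_normalized <- function(genes = 12, cells = 30, seed = 8) {
  x <- random_counts(genes, cells, seed = seed)
  normalize_genes(log_fractions(scaled_fractions(x)))
}

test_that("PCA satisfies its algebraic identities", {
  n <- toy_normalized()
  p <- pca_decompose(n)
  k <- length(p$eigenvalues)
  # orthonormal weights
  expect_equal(p$weights %*% t(p$weights), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # score-row variance equals the eigenvalue
  expect_equal(apply(p$scores, 1, var), p$eigenvalues, tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalues sum to the number of genes (z-scored input) and descend
  expect_equal(sum(p$eigenvalues), nrow(n$values), tolerance = 1e-6)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # deterministic sign convention
  for (i in seq_len(k)) {
    expect_gt(p$weights[i, which.max(abs(p$weights[i, ]))], 0)
  }
})

test_that("rank-one data yield a single non-null eigenvalue", {
  pattern <- sin(seq_len(20))
  v <- rbind(g1 = pattern, g2 = pattern)
  colnames(v) <- paste0("c", 1:20)
  lf <- as_lf(v - min(v))
  n <- normalize_genes(lf)
  p <- pca_decompose(n)
  expect_lt(p$eigenvalues[2], 1e-10)
})

test_that("PCA agrees with an independent eigendecomposition oracle", {
  n <- toy_normalized(6, 10, seed = 13)
  p <- pca_decompose(n)
  cov_o <- n$values %*% t(n$values) / (ncol(n$values) - 1)
  eig <- eigen(cov_o, symmetric = TRUE)
  expect_equal(p$eigenvalues, eig$values[seq_along(p$eigenvalues)],
               tolerance = 1e-8)
  scores_o <- t(eig$vectors) %*% n$values
  for (i in seq_len(nrow(p$scores))) {
    if (p$eigenvalues[i] < 1e-10) next
    # equal up to sign
    expect_equal(min(max(abs(p$scores[i, ] - scores_o[i, ])),
                     max(abs(p$scores[i, ] + scores_o[i, ]))),
                 0, tolerance = 1e-8)
  }
})

test_that("eigenvalue outliers follow the IQR fence", {
  expect_length(eigenvalue_outliers(rep(2, 8)), 0)
  lam <- c(10, rep(1, 7))
  # hand evaluation: Q1 = Q3 = 1, IQR = 0, fence = 1
  expect_identical(eigenvalue_outliers(lam), 1L)
  # output is a prefix of the descending order
  set.seed(2)
  lam2 <- sort(rexp(50), decreasing = TRUE)
  out <- eigenvalue_outliers(lam2)
  if (length(out)) expect_identical(out, seq_len(max(out)))
})

test_that("cluster score is the population sd of the five phase means", {
  phases <- rep(cc_phases(), each = 4)
  # identical means -> 0
  expect_equal(cluster_score(rep(1:4, times = 5), phases), 0)
  # means (1,1,1,1,6): population sd = 2
  score <- rep(c(1, 1, 1, 1, 6), each = 4)
  expect_equal(cluster_score(score, phases), 2)
  # translation invariance
  set.seed(4)
  s <- rnorm(20)
  expect_equal(cluster_score(s, phases), cluster_score(s + 7.3, phases))
  # a missing phase is fatal and named
  expect_error(cluster_score(s[1:16], phases[1:16]), "M.G1")
})

test_that("marker score sums squared weights over the cyclic set", {
  set.seed(6)
  w <- rnorm(50); w <- w / sqrt(sum(w^2))
  names(w) <- paste0("g", 1:50)
  expect_equal(marker_score(w, character(0)), 0)
  expect_equal(marker_score(w, names(w)), 1)
  half <- names(w)[1:25]
  expect_equal(marker_score(w, half), sum(w[1:25]^2))
  ms <- marker_scores(rbind(w), half)
  expect_equal(ms$baseline, 0.5)
})

test_that("score outliers use mean + 2 sample SD over the leading components", {
  expect_warning(out <- score_outliers(rep(1, 50)), "no cell-cycle signal")
  expect_length(out, 0)
  sig <- c(5, 5, rep(0.1, 98))
  # direct evaluation of the rule
  expect_identical(score_outliers(sig),
                   which(sig - mean(sig) > 2 * sd(sig)))
  expect_identical(score_outliers(sig), c(1L, 2L))
  # cap: values beyond the cap are ignored
  sig2 <- c(rep(0.1, 100), 50)
  expect_length(suppressWarnings(score_outliers(sig2, max_components = 100)), 0)
})

test_that("variance decomposition fractions are exact and sum to one", {
  n <- toy_normalized(10, 40, seed = 15)
  p <- pca_decompose(n)
  genes <- rownames(n$values)
  all_dec <- variance_decomposition(n, p$weights, genes)
  expect_equal(all_dec$cc, rep(1, nrow(all_dec)))
  expect_equal(all_dec$implied, rep(0, nrow(all_dec)))
  none_dec <- variance_decomposition(n, p$weights, character(0))
  expect_equal(none_dec$unexplained, rep(1, nrow(none_dec)))
  set.seed(30)
  some <- sample(genes, 4)
  dec <- variance_decomposition(n, p$weights, some)
  expect_equal(dec$cc + dec$implied + dec$unexplained,
               rep(1, nrow(dec)), tolerance = 1e-8)
  # additivity of the split score matrices
  in_set <- genes %in% some
  p_set <- p$weights[, in_set] %*% n$values[in_set, ]
  p_rest <- p$weights[, !in_set] %*% n$values[!in_set, ]
  expect_equal(p_set + p_rest, p$scores, tolerance = 1e-10)
})

test_that("random gene splits leave the complement share at 1 - m1/m", {
  pipe <- shared_pipeline()
  n <- pipe$normalized
  p <- pipe$pca
  genes <- rownames(n$values)
  m <- length(genes)
  m1 <- round(m * 182 / 1031)
  keep <- which(p$eigenvalues > 1e-8)
  set.seed(77)
  vals <- replicate(3, {
    rnd <- sample(genes, m1)
    dec <- variance_decomposition(n, p$weights, rnd, components = keep)
    dec$unexplained + dec$implied / 2
  })
  est <- mean(vals)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(est - (1 - m1 / m)), 3 * se + 1e-12)
  # exact complement identity: share(set) + share(complement) = 1
  rnd <- sample(genes, m1)
  d1 <- variance_decomposition(n, p$weights, rnd, components = keep)
  d2 <- variance_decomposition(n, p$weights, setdiff(genes, rnd),
                               components = keep)
  expect_equal((d1$unexplained + d1$implied / 2) +
                 (d2$unexplained + d2$implied / 2),
               rep(1, length(keep)), tolerance = 1e-8)
})
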