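test_that("axis-to-e3 rotations satisfy their contract", {
  # e3 maps by the identity
  s <- rotation_from_axis(c(0, 0, 1))
  expect_equal(s$r3, diag(3), tolerance = 1e-12)
  expect_equal(s$alpha, 0)
  expect_equal(s$beta, 0)
  # e2 maps via alpha = pi/2
  s2 <- rotation_from_axis(c(0, 1, 0))
  expect_equal(s2$alpha, pi / 2)
  expect_equal(as.numeric(s2$r3 %*% c(0, 1, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  # degenerate +-e1 resolves to alpha = 0
  s3 <- rotation_from_axis(c(1, 0, 0))
  expect_equal(s3$alpha, 0)
  expect_equal(as.numeric(s3$r3 %*% c(1, 0, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  expect_error(rotation_from_axis(c(1, 1, 0)), "unit")
  # 1,000 random axes: R omega = e3, orthogonal, det +1
  set.seed(17)
  for (i in 1:1000) {
    w <- rnorm(3); w <- w / sqrt(sum(w^2))
    r <- rotation_from_axis(w)$r3
    expect_lt(max(abs(as.numeric(r %*% w) - c(0, 0, 1))), 1e-8)
    expect_lt(max(abs(r %*% t(r) - diag(3))), 1e-10)
    expect_equal(det(r), 1, tolerance = 1e-10)
  }
})

test_that("the golden spiral grid is near-uniform on the sphere", {
  g1 <- golden_spiral_grid(1)
  expect_equal(sum(g1^2), 1, tolerance = 1e-12)
  g <- golden_spiral_grid(10000)
  expect_true(all(abs(rowSums(g^2) - 1) < 1e-12))
  # nearest-neighbor angular distances: max/min ratio below 2
  nn <- numeric(nrow(g))
  chunk <- 500
  for (start in seq(1, nrow(g), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(g))
    cosang <- g[idx, , drop = FALSE] %*% t(g)
    cosang[cbind(seq_along(idx), idx)] <- -1   # exclude self
    nn[idx] <- acos(pmin(1, apply(cosang, 1, max)))
  }
  expect_lt(max(nn) / min(nn), 2)
  # deterministic
  expect_identical(golden_spiral_grid(100), golden_spiral_grid(100))
})

test_that("axis score equals the cluster score of projected cells", {
  # coplanar points: the normal scores 0, an in-plane axis scores maximally
  gm <- cbind(runif(5, -2, 2), runif(5, -2, 2), 0)
  expect_equal(axis_score(c(0, 0, 1), gm), 0)
  set.seed(23)
  gm2 <- matrix(rnorm(15), 5, 3)
  phases <- factor(rep(cc_phases(), each = 6), levels = cc_phases())
  # build cells whose per-phase means are exactly gm2
  cells <- matrix(0, 3, 30)
  for (i in 1:5) {
    block <- 6 * (i - 1) + 1:6
    noise <- matrix(rnorm(18), 3, 6)
    noise <- noise - rowMeans(noise)
    cells[, block] <- gm2[i, ] + noise
  }
  w <- rnorm(3); w <- w / sqrt(sum(w^2))
  expect_equal(axis_score(w, gm2),
               cluster_score(as.numeric(w %*% cells), phases),
               tolerance = 1e-10)
})

test_that("viewing-axis search finds known optima and refines the coarse grid", {
  # five points in the xy-plane: the axis is +-e3 (within half a degree)
  set.seed(31)
  planar <- cbind(rnorm(5), rnorm(5), 0)
  ax <- find_viewing_axis(planar)
  expect_lt(acos(min(1, abs(ax$omega[3]))), 0.5 * pi / 180)
  expect_lte(ax$score, ax$coarse_score)
  # slanted configuration with a known normal
  nu <- c(0.3, -0.5, 0.81); nu <- nu / sqrt(sum(nu^2))
  r <- t(rotation_from_axis(nu)$r3)     # maps e3 to nu
  slanted <- planar %*% t(r)
  ax2 <- find_viewing_axis(slanted)
  expect_lt(acos(min(1, abs(sum(ax2$omega * nu)))), 0.5 * pi / 180)
  # degenerate input returns e3 with a warning
  expect_warning(deg <- find_viewing_axis(matrix(1, 5, 3)), "degenerate")
  expect_equal(deg$omega, c(0, 0, 1))
})

test_that("two-step search matches an exhaustive fine-grid oracle", {
  set.seed(37)
  for (rep in 1:3) {
    gm <- matrix(rnorm(15, sd = 2), 5, 3)
    ax <- find_viewing_axis(gm)
    big <- golden_spiral_grid(1e6)
    sc <- axis_score(big, gm)
    best <- big[which.min(sc), ]
    # agreement within a few oracle-grid spacings
    ang <- acos(min(1, abs(sum(ax$omega * best))))
    expect_lt(ang, sqrt(4 * pi / 1e6) * 4)
    # and the achieved score is no worse than the exhaustive one (up to
    # the oracle grid's own resolution)
    expect_lte(ax$score, min(sc) + 1e-6)
  }
})

test_that("sequential rotation concentrates the cycle into DC1-DC2", {
  pipe <- slanted_pipeline()
  phases <- pipe$phases$phase
  pca <- pipe$pca
  expect_true(all(c(1, 2) %in% pipe$cc_components))
  expect_gte(length(pipe$cc_components), 3)
  dc <- pipe$dc_space
  k <- nrow(dc$dc_scores)
  # orthogonality, determinant, norm preservation
  expect_equal(dc$rotation %*% t(dc$rotation), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(det(dc$rotation), 1, tolerance = 1e-8)
  expect_equal(sqrt(colSums(dc$dc_scores^2)), sqrt(colSums(pca$scores^2)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # untouched components keep their PC scores exactly
  touched <- sort(unique(unlist(lapply(dc$steps, `[[`, "dims"))))
  untouched <- setdiff(seq_len(k), touched)[1:5]
  expect_equal(dc$dc_scores[untouched, ], pca$scores[untouched, ],
               ignore_attr = TRUE)
  # reconstruction: N = U^T DC
  expect_lt(max(abs(t(dc$rotated_weights) %*% dc$dc_scores -
                      pipe$normalized$values)), 1e-8)
  # the rotated third component's cluster score never exceeds the source
  sig_pc <- cluster_scores(pca$scores, phases)
  sig_dc <- cluster_scores(dc$dc_scores, phases)
  for (s in dc$steps) {
    expect_lte(sig_dc[s$dims[3]], sig_pc[s$dims[3]] + 1e-10)
  }
  # cycle concentrated: DC3..DC10 below the outlier fence, DC1-DC2 above
  kk <- seq_len(min(100, length(sig_dc)))
  fence <- mean(sig_dc[kk]) + 2 * sd(sig_dc[kk])
  expect_true(all(sig_dc[3:10] < fence))
  expect_true(all(sig_dc[1:2] > fence))
})

test_that("a cell-cycle set of {1,2} leaves the space unrotated", {
  pipe <- shared_pipeline()
  suppressMessages(
    dc <- sequential_rotation(pipe$pca, c(1, 2), pipe$phases$phase))
  expect_equal(dc$rotation, diag(nrow(pipe$pca$scores)))
  expect_equal(dc$dc_scores, pipe$pca$scores, ignore_attr = TRUE)
  # components 1 and 2 are forced in with a warning when absent
  expect_warning(
    dc2 <- sequential_rotation(pipe$pca, c(2, 3), pipe$phases$phase,
                               n_coarse = 500),
    "forced")
  expect_true(all(c(1, 2) %in% dc2$cc_components))
})
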