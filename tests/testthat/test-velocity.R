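test_that("steady-state velocity vanishes at equilibrium and is signed", {
  x <- random_counts(20, 40, seed = 71, lambda = 8)
  # unspliced exactly gamma * spliced (same size factors): V = 0
  u <- cc_counts(x$counts * 2L)
  vel <- estimate_velocity(x, u)
  expect_lt(max(abs(vel$v)), 1e-8)
  # genes without unspliced signal: velocity rows forced to zero; a gene
  # with sparse unspliced counts never gets a positive velocity where u = 0
  u0 <- x$counts * 0L; u0[1, ] <- 1L
  vel0 <- suppressMessages(estimate_velocity(x, cc_counts(u0)))
  expect_true(all(vel0$v[-1, ] == 0))
  expect_true(all(rownames(x$counts)[-1] %in% vel0$zero_genes))
})

test_that("zero velocity with shared statistics reproduces the DC scores", {
  pipe <- shared_pipeline()
  v0 <- matrix(0, nrow(pipe$counts$counts), ncol(pipe$counts$counts))
  proj <- extrapolate_and_project(pipe$counts, v0, pipe$dc_space,
                                  scale_constant = "kappa",
                                  stats = "observed")
  expect_lt(max(abs(proj$displacement)), 1e-8)
})

test_that("extrapolation follows the printed transform chain", {
  pipe <- shared_pipeline()
  dc <- pipe$dc_space
  set.seed(72)
  v <- matrix(rnorm(length(pipe$counts$counts), sd = 0.5),
              nrow(pipe$counts$counts), ncol(pipe$counts$counts))
  proj <- suppressMessages(extrapolate_and_project(pipe$counts, v, dc))
  # independent evaluation of the chain for a single cell
  theta <- colSums(pipe$counts$counts)
  s_ex <- sweep(pipe$counts$counts, 2, theta, "/") + v / dc$kappa
  n_clip <- sum(s_ex < 0)
  s_ex[s_ex < 0] <- 0
  lf_ex <- log(1e4 * s_ex + 1)[dc$gene_ids, ]
  mu <- rowMeans(lf_ex)
  sds <- apply(lf_ex, 1, sd)
  n_ex <- (lf_ex - mu) / sds
  n_ex[sds == 0, ] <- 0
  oracle <- dc$rotated_weights %*% n_ex
  expect_equal(proj$dc_ex, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(proj$n_clipped, n_clip)
})

test_that("simulated unspliced lead drives motion along pseudotime", {
  sim <- shared_sim()
  pipe <- shared_pipeline()
  vel <- shared_velocity()
  rec <- evaluate_recovery(pipe$coords, sim$truth)
  cyl <- cylinder_displacements(pipe$dc_space, vel$proj)
  # per-cell angular displacements predominantly follow progression
  expect_gt(mean(sign(cyl$d_angle) == rec$direction), 0.9)
  expect_identical(sign(stats::median(cyl$d_angle)), rec$direction)
  # smoothed grid arrows: angular component single-signed where shown
  pos <- t(pipe$dc_space$dc_scores[1:2, ])
  disp <- t(vel$proj$displacement[1:2, ])
  f <- grid_smooth(pos, disp)
  shown <- f[f$shown, ]
  ang_comp <- (-sin(atan2(shown$y, shown$x))) * shown$dx +
    cos(atan2(shown$y, shown$x)) * shown$dy
  expect_gt(mean(sign(ang_comp) == rec$direction), 0.9)
})

test_that("grid smoothing equals direct kernel evaluation", {
  # single cell with displacement d: the coincident grid point gets d
  f1 <- grid_smooth(matrix(c(0, 0), 1, 2), matrix(c(0.7, -0.2), 1, 2),
                    grid_n = 3, rho = 0.5, min_arrow = 0)
  center <- which(f1$x == 0 & f1$y == 0)[1]
  expect_equal(c(f1$dx[center], f1$dy[center]), c(0.7, -0.2))
  # two opposite displacements equidistant from a grid point cancel
  pos <- rbind(c(-1, 0), c(1, 0))
  disp <- rbind(c(0, 1), c(0, -1))
  f2 <- grid_smooth(pos, disp, grid_n = 3, rho = 1, min_arrow = 0)
  mid <- which(f2$x == 0 & f2$y == 0)[1]
  expect_equal(c(f2$dx[mid], f2$dy[mid]), c(0, 0), tolerance = 1e-12)
  # random field vs direct double-loop evaluation
  set.seed(73)
  pos3 <- matrix(rnorm(20), 10, 2)
  disp3 <- matrix(rnorm(20, sd = 0.3), 10, 2)
  f3 <- grid_smooth(pos3, disp3, grid_n = 5, rho = 0.6)
  for (k in c(1, 13, 25)) {
    w <- exp(-colSums((t(pos3) - c(f3$x[k], f3$y[k]))^2) / (2 * 0.6^2))
    expect_equal(c(f3$dx[k], f3$dy[k]),
                 c(sum(w * disp3[, 1]), sum(w * disp3[, 2])),
                 tolerance = 1e-10)
  }
})

test_that("cylinder-side field is periodic in the cut position", {
  set.seed(74)
  n <- 200
  angles <- runif(n, 0, 2 * pi)
  attr(angles, "mean_radius") <- 3
  dc3 <- rnorm(n)
  d_angle <- rnorm(n, sd = 0.1)
  d_dc3 <- rnorm(n, sd = 0.1)
  # zero displacements give a zero field
  f0 <- cylinder_side_field(angles, dc3, 0 * d_angle, 0 * d_dc3)
  expect_equal(max(abs(c(f0$dx, f0$dy))), 0)
  # rotating the cut by an exact grid step shifts the field cyclically
  grid_n <- 50
  shift_steps <- 7
  delta <- 2 * pi * shift_steps / (grid_n - 1)
  f_a <- cylinder_side_field(angles, dc3, d_angle, d_dc3, cut_angle = 0,
                             grid_n = grid_n)
  f_b <- cylinder_side_field(angles, dc3, d_angle, d_dc3, cut_angle = delta,
                             grid_n = grid_n)
  # compare at matching absolute angles
  get_col <- function(f, col_idx) f[round(f$x / (2 * pi / (grid_n - 1))) == col_idx, ]
  a <- get_col(f_a, shift_steps)
  b <- get_col(f_b, 0)
  expect_equal(a$dx, b$dx, tolerance = 1e-8)
  expect_equal(a$dy, b$dy, tolerance = 1e-8)
})

test_that("downward axial drift yields a consistently downward field", {
  set.seed(75)
  n <- 300
  angles <- runif(n, 0, 2 * pi)
  attr(angles, "mean_radius") <- 3
  dc3 <- rnorm(n)
  f <- cylinder_side_field(angles, dc3, rnorm(n, sd = 0.02),
                           rep(-0.5, n), min_arrow = 0)
  expect_true(all(f$dy < 0))
})
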