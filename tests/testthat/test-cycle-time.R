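test_that("polar coordinates handle axes and the origin", {
  pc <- polar_coordinates(c(1, 0, 0), c(0, 1, 0))
  expect_equal(pc$angle, c(0, pi / 2, 0))
  expect_equal(pc$radius, c(1, 1, 0))
  expect_identical(pc$at_origin, c(FALSE, FALSE, TRUE))
})

test_that("division search matches exhaustive shift evaluation on a sawtooth", {
  set.seed(51)
  n_bins <- 12
  n <- n_bins * 30
  angles <- sort(runif(n, 0, 2 * pi))
  # rising ramp of total UMIs that resets at the seam between bins 8 and 9
  bin_of <- pmin(ceiling(seq_len(n) / 30), n_bins)
  ramp_pos <- ((bin_of - 9) %% n_bins) + 1      # 1 at bin 9 .. 12 at bin 8
  theta <- 100 * ramp_pos + rnorm(n, sd = 1)
  course <- find_division(angles, theta)
  expect_identical(course$division_bin, 9L)
  # exhaustive oracle over all cyclic shifts
  u <- course$bin_means
  h <- seq(min(u), max(u), length.out = n_bins)
  res_o <- sapply(seq_len(n_bins) - 1L, function(l) {
    sum((u[((seq_len(n_bins) - 1L + l) %% n_bins) + 1L] - h)^2)
  })
  expect_equal(course$residuals, res_o, ignore_attr = TRUE)
  expect_identical(course$best_shift, which.min(res_o) - 1L)
  # a course already equal to the ramp has residual 0 at shift 0
  theta2 <- 10 * bin_of + 0.0 # exactly linear in bin index
  course2 <- find_division(angles, theta2)
  expect_identical(course2$best_shift, 0L)
  expect_equal(course2$residuals[1], 0, tolerance = 1e-9)
  # constant totals tie; shift 0 with a warning
  expect_warning(course3 <- find_division(angles, rep(5, n)), "tie")
  expect_identical(course3$best_shift, 0L)
})

test_that("division alignment is idempotent and handles the 2*pi seam", {
  set.seed(52)
  n <- 120
  angles <- sort(runif(n, 0, 2 * pi))
  bin_of <- pmin(ceiling(seq_len(n) / 30), 4)
  theta <- 100 * (((bin_of - 2) %% 4) + 1)     # division at bin 2
  course <- find_division(angles, theta)
  al <- align_division(angles, course)
  # the midpoint between the straddling cells sits at angle 0
  course_al <- find_division(al$angles, theta)
  al2 <- align_division(al$angles, course_al)
  expect_lt(min(al2$offset, 2 * pi - al2$offset), 1e-8)
  expect_equal(al2$angles, al$angles, tolerance = 1e-8)
  # wrap-around: division between the last and first cell in angle order
  a <- c(6.27, 0.01, seq(0.2, 6.0, length.out = 118))
  a_sorted <- sort(a)
  theta_w <- 2^(a_sorted / (2 * pi)) * 1000     # rising with angle, reset at 0
  course_w <- find_division(a_sorted, theta_w)
  al_w <- align_division(a_sorted, course_w)
  expect_identical(course_w$division_bin, 1L)
  # midpoint of 6.27 and 0.01 is ~6.2816, not ~pi
  expect_equal(al_w$division_angle, cyclodyn:::cyclic_midpoint(6.27, 0.01),
               tolerance = 1e-8)
})

test_that("phase boundaries fall at cumulative duration fractions", {
  angles <- sort(runif(100, 0, 2 * pi))
  eq <- phase_boundaries(angles, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(eq$after_cell, c(25L, 50L, 75L, 100L))
  half <- phase_boundaries(angles, c(G1 = 6, S = 3, G2 = 2, M = 1))
  expect_equal(half$after_cell[1], 50L)   # G1 takes half the cycle
  expect_identical(half$transition[1], "G1-S")
  # boundary fractions track cumulative normalized durations within 1/n
  pl <- default_phase_lengths()
  b <- phase_boundaries(angles, pl)
  expect_equal(b$after_cell / 100, cumsum(pl) / sum(pl),
               tolerance = 1 / 100, ignore_attr = TRUE)
  expect_error(phase_boundaries(angles, c(G1 = 0, S = 0)), "positive")
})

test_that("gene time courses bin by rank and conserve totals", {
  pipe <- shared_pipeline()
  coords <- pipe$coords
  n <- nrow(coords$cells)
  # constant gene -> flat course
  flat <- gene_time_course(rep(2.5, n), coords, n_bins = 10)
  expect_equal(flat$mean_value, rep(2.5, 10))
  # conservation: per-bin means times counts sum to the total
  set.seed(53)
  v <- rnorm(n)
  tc <- gene_time_course(v, coords, n_bins = 7)
  expect_equal(sum(tc$mean_value * tc$n_cells), sum(v))
  # a simulated gene peaking at true phase p peaks within one bin of p
  sim <- shared_sim()
  idx <- match(coords$cells$cell_id, sim$truth$cell_id)
  rec <- evaluate_recovery(coords, sim$truth)
  g <- sim$genes$gene[which(sim$genes$type == "cyclic")[25]]
  p_true <- sim$genes$peak_phase[sim$genes$gene == g]
  lf <- log_fractions(scaled_fractions(pipe$counts))
  n_bins <- 20
  tc2 <- gene_time_course(lf$values[g, ], coords, n_bins = n_bins)
  peak_frac <- (which.max(tc2$mean_value) - 0.5) / n_bins
  if (rec$direction < 0) peak_frac <- 1 - peak_frac
  d <- abs(peak_frac - p_true)
  expect_lt(min(d, 1 - d), 2.5 / n_bins)
})

test_that("onset ordering finds upward half-maximum crossings", {
  # two-bin step course: onset in bin 2
  two <- matrix(c(0, 1), 1, 2, dimnames = list("g", NULL))
  expect_identical(onset_times(two)$onset_bin, 2L)
  # sine-like course: onset matches a dense scan oracle
  nb <- 40
  tt <- (seq_len(nb) - 0.5) / nb
  course <- rbind(gA = sin(2 * pi * (tt - 0.1)),
                  gB = sin(2 * pi * (tt - 0.45)))
  ot <- onset_times(course)
  for (g in rownames(course)) {
    x <- course[g, ]
    sc <- (x - min(x)) / diff(range(x))
    prev <- sc[c(nb, seq_len(nb - 1))]
    oracle <- which(sc >= 0.5 & prev < 0.5)[1]
    expect_identical(ot$onset_bin[ot$gene == g], as.integer(oracle))
  }
  # constant courses are excluded with a warning
  expect_warning(ot2 <- onset_times(rbind(course, flatg = rep(1, nb))),
                 "constant")
  expect_false("flatg" %in% ot2$gene)
  # planted evenly spaced peaks yield approximately evenly spaced onsets
  pipe <- shared_pipeline()
  sim <- shared_sim()
  lf <- log_fractions(scaled_fractions(pipe$counts))
  mk <- unlist(sim$markers)
  courses <- t(sapply(mk, function(g) {
    gene_time_course(lf$values[g, ], pipe$coords, n_bins = 20)$mean_value
  }))
  oo <- onset_times(courses)
  slope_fit <- lm(onset_bin ~ rank, data = tibble::tibble(
    rank = seq_len(nrow(oo)), onset_bin = sort(oo$onset_bin)))
  expect_gt(summary(slope_fit)$r.squared, 0.9)
})

test_that("pseudotime is stable under an in-plane rotation before alignment", {
  pipe <- shared_pipeline()
  dc <- pipe$dc_space
  theta <- total_umis(pipe$counts)[dc$cell_ids]
  coords <- pipe$coords
  rot <- dc
  delta <- 0.9
  r2 <- matrix(c(cos(delta), -sin(delta), sin(delta), cos(delta)), 2, 2)
  rot$dc_scores[1:2, ] <- r2 %*% dc$dc_scores[1:2, ]
  coords_rot <- suppressWarnings(
    cycle_coordinates(rot, pipe$phases$phase, theta))
  d <- abs(coords_rot$cells$angle - coords$cells$angle)
  d <- pmin(d, 2 * pi - d)
  # aligned angles agree up to the binning granularity of the division search
  expect_lt(stats::median(d), 2 * pi / length(coords$umi_course$bin_means))
})
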