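#' Default five-arc partition of the cycle
#'
#' Fractions of the cycle occupied by each of the five marker time points,
#' starting at division (t = 0). Derived from the bundled phase-length
#' table: the five marker programs straddle the classic phase transitions,
#' so the arcs interpolate the G1/S/G2/M durations.
#'
#' @return Named numeric vector summing to 1, in order M.G1, G1.S, S, G2,
#'   G2.M starting at division.
#' @export
default_phase_arcs <- function() {
  c(M.G1 = 0.15, G1.S = 0.25, S = 0.25, G2 = 0.20, G2.M = 0.15)
}

#' Simulation configuration
#'
#' Parameters of the synthetic cycling-cell population. The defaults encode
#' the regime the method is designed for: a moderately sized unsynchronized
#' population (1,000 cells) at the rule-of-thumb sequencing depth of about
#' 4,500 mean UMIs per cell, with uniformly distributed phase angles,
#' phase-peaked cyclic gene programs, total transcript content doubling
#' over the cycle and halving at division, a slow non-cyclic drift program,
#' and unspliced counts leading the spliced phase.
#'
#' @param n_cells number of cells (default 1000).
#' @param n_genes total genes (default 2000).
#' @param n_cyclic_genes cyclic genes among them (default 300).
#' @param markers_per_phase cyclic genes planted per phase arc, used as
#'   ground-truth marker lists (default 30).
#' @param mean_depth target mean total UMI per cell (default 4500).
#' @param amplitude cyclic log-fold range of the phase bump (default 3).
#' @param concentration peak sharpness of the circular bump (default 0:
#'   pure raised cosine, a planar circular trajectory in log-rate space;
#'   larger values sharpen peaks and add higher circular harmonics).
#' @param drift_genes genes on the slow non-cyclic drift axis (default 150,
#'   disjoint from the cyclic set).
#' @param drift_strength log-scale strength of the drift program (default
#'   0.5: a slow secondary axis, weaker than the cycle, so the cell cycle
#'   dominates the leading principal components as in the populations the
#'   method targets).
#' @param division_fraction transcript content ratio retained at division
#'   (default 0.5: content doubles over the cycle and halves at t = 0).
#' @param unspliced_lead phase lead of unspliced counts, radians
#'   (default 0.5).
#' @param unspliced_depth unspliced depth as a fraction of spliced depth
#'   (default 0.15).
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson
#'   counts (default 20).
#' @param phase_arcs five-arc partition of the cycle (see
#'   [default_phase_arcs()]).
#' @param seed integer seed; the simulation is deterministic given the
#'   seed.
#' @return A list of class `cc_sim_config`.
#' @export
sim_config <- function(n_cells = 1000, n_genes = 2000, n_cyclic_genes = 300,
                       markers_per_phase = 30, mean_depth = 4500,
                       amplitude = 3, concentration = 0,
                       drift_genes = 150, drift_strength = 0.5,
                       division_fraction = 0.5, unspliced_lead = 0.5,
                       unspliced_depth = 0.15, dispersion = 20,
                       phase_arcs = default_phase_arcs(), seed = 1L) {
  stopifnot(n_cyclic_genes + drift_genes <= n_genes,
            5 * markers_per_phase <= n_cyclic_genes,
            division_fraction > 0, division_fraction <= 1,
            abs(sum(phase_arcs) - 1) < 1e-8)
  structure(as.list(environment()), class = "cc_sim_config")
}

# log-rate bump of a cyclic gene peaking at phase p, evaluated at phase t
# (both in cycle fractions); amplitude is the peak-to-trough log range.
# concentration = 0 is the pure raised cosine: all cyclic genes then span
# the {cos, sin} plane in log-rate space, the planar circular trajectory
# the method assumes. concentration > 0 sharpens the peak, adding higher
# circular harmonics (a non-planar deformation).
cyclic_bump <- function(t, p, amplitude, concentration = 0) {
  ct <- cos(2 * pi * (t - p))
  if (concentration == 0) {
    amplitude * (ct - 1) / 2
  } else {
    amplitude * (exp(concentration * (ct - 1)) - 1) /
      (1 - exp(-2 * concentration))
  }
}

# draw counts: negative binomial with mean mu and size `dispersion`;
# Poisson in the dispersion -> Inf limit
draw_counts <- function(mu, dispersion) {
  if (is.infinite(dispersion)) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = dispersion)
  }
}

#' Simulate a cycling single-cell population with ground truth
#'
#' Generates matched spliced and unspliced UMI count matrices plus the
#' ground truth needed to validate every pipeline stage. Cells get uniform
#' phase angles; cyclic genes follow a circular bump peaking at a planted
#' phase; total content scales as `division_fraction^(1 - t)` relative to
#' the pre-division maximum, so it doubles across the cycle (for the
#' default 0.5) and resets at division; drift genes follow a slow per-cell
#' latent value independent of phase; counts are negative binomial around
#' the expected profile; unspliced counts are generated from the same
#' bumps evaluated ahead of the cell's phase at reduced depth.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `cc_simulation`: `spliced` and `unspliced`
#'   ([cc_counts]), `truth` (tibble: `cell_id`, `true_phase`, `phase_label`,
#'   `drift_value`, `depth_factor`), `genes` (tibble: `gene`, `type`,
#'   `peak_phase`, `marker_phase`), `markers` (list of five ground-truth
#'   marker gene vectors), `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "cc_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cells; m <- cfg$n_genes
  t <- stats::runif(n)
  arcs <- cfg$phase_arcs
  arc_ends <- cumsum(arcs)
  arc_starts <- c(0, utils::head(arc_ends, -1))
  label <- names(arcs)[findInterval(t, arc_ends, left.open = TRUE) + 1]

  gene_ids <- sprintf("gene%04d", seq_len(m))
  n_cyc <- cfg$n_cyclic_genes
  n_mark <- 5 * cfg$markers_per_phase
  type <- rep("flat", m)
  type[seq_len(n_cyc)] <- "cyclic"
  type[n_cyc + seq_len(cfg$drift_genes)] <- "drift"

  # marker genes: peaks spread evenly inside each arc; remaining cyclic
  # genes peak uniformly over the cycle
  peak <- rep(NA_real_, m)
  marker_phase <- rep(NA_character_, m)
  idx <- 1
  for (ph in names(arcs)) {
    k <- cfg$markers_per_phase
    peaks <- arc_starts[[match(ph, names(arcs))]] +
      arcs[[ph]] * (seq_len(k) - 0.5) / k
    peak[idx:(idx + k - 1)] <- peaks
    marker_phase[idx:(idx + k - 1)] <- ph
    idx <- idx + k
  }
  if (n_cyc > n_mark) {
    peak[(n_mark + 1):n_cyc] <- (seq_len(n_cyc - n_mark) - 0.5) / (n_cyc - n_mark)
  }

  base <- stats::rlnorm(m, meanlog = 0, sdlog = 1)
  log_rate <- matrix(log(base), m, n)
  cyc <- which(type == "cyclic")
  log_rate[cyc, ] <- log_rate[cyc, ] +
    t(vapply(cyc, function(g) cyclic_bump(t, peak[g], cfg$amplitude,
                                          cfg$concentration),
             numeric(n)))
  drift_idx <- which(type == "drift")
  z <- stats::rnorm(n)
  loading <- stats::runif(cfg$drift_genes, 0.5, 1) *
    sample(c(-1, 1), cfg$drift_genes, replace = TRUE)
  log_rate[drift_idx, ] <- log_rate[drift_idx, ] +
    cfg$drift_strength * outer(loading, z)

  rate <- exp(log_rate)
  p <- sweep(rate, 2, colSums(rate), "/")
  # content grows from division_fraction^1 at t=0 to 1 at t=1; normalized
  # so the population mean depth equals mean_depth
  growth <- cfg$division_fraction^(1 - t)
  depth <- cfg$mean_depth * growth / mean(growth)
  if (any(depth < 1)) stop2("infeasible depth: expected totals below 1")
  mu <- sweep(p, 2, depth, "*")
  spliced <- matrix(draw_counts(mu, cfg$dispersion), m, n)

  lead <- cfg$unspliced_lead / (2 * pi)
  log_rate_u <- matrix(log(base), m, n)
  log_rate_u[cyc, ] <- log_rate_u[cyc, ] +
    t(vapply(cyc, function(g) cyclic_bump(t + lead, peak[g], cfg$amplitude,
                                          cfg$concentration),
             numeric(n)))
  log_rate_u[drift_idx, ] <- log_rate_u[drift_idx, ] +
    cfg$drift_strength * outer(loading, z)
  rate_u <- exp(log_rate_u)
  pu <- sweep(rate_u, 2, colSums(rate_u), "/")
  mu_u <- sweep(pu, 2, depth * cfg$unspliced_depth, "*")
  unspliced <- matrix(draw_counts(mu_u, cfg$dispersion), m, n)

  cell_ids <- sprintf("cell%04d", seq_len(n))
  dimnames(spliced) <- list(gene_ids, cell_ids)
  dimnames(unspliced) <- list(gene_ids, cell_ids)

  markers <- split(gene_ids[seq_len(n_mark)],
                   factor(marker_phase[seq_len(n_mark)], levels = cc_phases()))
  truth <- tibble::tibble(cell_id = cell_ids, true_phase = t,
                          phase_label = factor(label, levels = cc_phases()),
                          drift_value = z, depth_factor = growth / mean(growth))
  genes <- tibble::tibble(gene = gene_ids, type = type, peak_phase = peak,
                          marker_phase = marker_phase)
  structure(list(spliced = cc_counts(spliced),
                 unspliced = cc_counts(unspliced),
                 truth = truth, genes = genes, markers = markers,
                 config = cfg),
            class = "cc_simulation")
}

#' @export
print.cc_simulation <- function(x, ...) {
  cat(sprintf("<cc_simulation> %d genes x %d cells (%d cyclic, %d drift); mean depth %.0f\n",
              nrow(x$spliced$counts), ncol(x$spliced$counts),
              sum(x$genes$type == "cyclic"), sum(x$genes$type == "drift"),
              mean(colSums(x$spliced$counts))))
  invisible(x)
}

#' Binomial downsampling of a count matrix
#'
#' Thins every UMI independently with keep-probability `fraction`, emulating
#' shallower sequencing.
#'
#' @param x a [cc_counts] object.
#' @param fraction keep-probability in (0, 1].
#' @param seed integer seed.
#' @return A [cc_counts] object of thinned counts.
#' @export
downsample_counts <- function(x, fraction, seed = 1L) {
  stopifnot(inherits(x, "cc_counts"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(x)
  set.seed(seed)
  m <- x$counts
  thinned <- matrix(stats::rbinom(length(m), size = as.vector(m),
                                  prob = fraction),
                    nrow(m), ncol(m), dimnames = dimnames(m))
  cc_counts(thinned, x$batch)
}

#' Circular rank correlation of two angular variables
#'
#' Fisher-Lee circular correlation of the circular ranks of `a` and `b`.
#' Invariant to rotations of either variable; the sign carries the relative
#' orientation.
#'
#' @param a,b numeric vectors (angles or any monotone representation; only
#'   ranks are used).
#' @return Correlation in `[-1, 1]`.
#' @export
circular_rank_correlation <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 3)
  ra <- 2 * pi * rank(a, ties.method = "average") / n
  rb <- 2 * pi * rank(b, ties.method = "average") / n
  da <- sin(outer(ra, ra, "-"))
  db <- sin(outer(rb, rb, "-"))
  num <- sum(da * db)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) return(0)
  num / den
}

#' Evaluate pseudotime recovery against simulation truth
#'
#' @param coords a `cc_cycle_coordinates` object (cells are a subset of the
#'   simulated cells).
#' @param truth the `truth` tibble of a `cc_simulation`.
#' @return List with `circular_correlation` (absolute Fisher-Lee circular
#'   rank correlation), `direction` (+1 if inferred angle advances with
#'   true phase), `division_angle_error` (radians), `confusion` (inferred
#'   phase x true arc table).
#' @export
evaluate_recovery <- function(coords, truth) {
  stopifnot(inherits(coords, "cc_cycle_coordinates"))
  idx <- match(coords$cells$cell_id, truth$cell_id)
  if (anyNA(idx)) stop2("cells missing from truth table")
  t_true <- truth$true_phase[idx]
  ang <- coords$cells$angle
  r <- circular_rank_correlation(ang, t_true)
  dir <- if (r >= 0) 1 else -1
  # offset of the inferred division (angle 0) from the true division (t=0)
  d <- dir * ang - 2 * pi * t_true
  offset <- atan2(mean(sin(d)), mean(cos(d)))
  conf <- table(inferred = coords$cells$phase,
                true = truth$phase_label[idx])
  list(circular_correlation = abs(r), direction = dir,
       division_angle_error = abs(offset), confusion = conf)
}
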