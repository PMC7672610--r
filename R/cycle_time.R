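#' Orient the cell-cycle plane
#'
#' The rotation leaves the direction of travel around the DC1-DC2 annulus
#' arbitrary. The convention here: pseudotime (increasing polar angle) is
#' the direction along which the phase sequence G1.S, S, G2, G2.M, M.G1
#' advances, decided by a majority vote over adjacent cell pairs in angular
#' order; if the vote says the labels run backwards, the DC2 sign is
#' flipped. This fixes the orientation reproducibly without visual
#' inspection.
#'
#' @param dc1,dc2 per-cell coordinates in the cell-cycle plane.
#' @param phases per-cell phase labels.
#' @return List with `dc1`, `dc2` (possibly sign-flipped), `flipped`
#'   (logical).
#' @keywords internal
orient_cycle <- function(dc1, dc2, phases) {
  ang <- wrap_angle(atan2(dc2, dc1))
  ord <- order(ang)
  idx <- as.integer(factor(as.character(phases), levels = cc_phases()))[ord]
  nxt <- c(idx[-1], idx[1])
  d <- (nxt - idx) %% 5
  forward <- sum(d == 1)       # label advances with increasing angle
  backward <- sum(d == 4)      # label recedes
  flipped <- backward > forward
  if (flipped) dc2 <- -dc2
  list(dc1 = dc1, dc2 = dc2, flipped = flipped)
}

#' Polar coordinates in the cell-cycle plane
#'
#' @param dc1,dc2 per-cell coordinates (oriented; see [orient_cycle()]).
#' @return A tibble with `angle` (in `[0, 2*pi)`), `radius`, and
#'   `at_origin` (cells exactly at the origin get angle 0 and are flagged).
#' @export
polar_coordinates <- function(dc1, dc2) {
  radius <- sqrt(dc1^2 + dc2^2)
  at_origin <- radius == 0
  angle <- wrap_angle(atan2(dc2, dc1))
  angle[at_origin] <- 0
  tibble::tibble(angle = angle, radius = radius, at_origin = at_origin)
}

#' Locate cell division from the total-UMI ramp
#'
#' Cells ordered by angle are grouped into consecutive bins of `bin_size`
#' cells (the remainder merges into the last bin) and the mean total UMI
#' count per bin gives a time course U. Because transcript content roughly
#' doubles over the cycle and halves at division, the course is a rising
#' ramp with a sharp reset. A linear ramp h from min(U) to max(U) is fit
#' against every cyclic shift of the course; the shift with the smallest
#' squared residual places the reset — cell division — at the start of its
#' winning bin.
#'
#' @param angles per-cell angles in `[0, 2*pi)`.
#' @param total_umi per-cell total UMI counts (same order as `angles`).
#' @param bin_size cells per bin (default 30).
#' @return Object of class `cc_umi_course`: list with `bin_means`,
#'   `bin_cells` (list of cell indices per bin, angular order),
#'   `best_shift` (0-based), `division_bin`, `residuals` (per shift), and
#'   `division_angle_hint` (start angle of the division bin).
#' @export
find_division <- function(angles, total_umi, bin_size = 30) {
  n <- length(angles)
  stopifnot(length(total_umi) == n, n >= 2 * bin_size)
  ord <- order(angles)
  n_bins <- as.integer(n %/% bin_size)
  bin_of <- pmin(ceiling(seq_len(n) / bin_size), n_bins)  # remainder -> last
  bin_cells <- split(ord, bin_of)
  u <- vapply(bin_cells, function(i) mean(total_umi[i]), numeric(1))
  h <- seq(min(u), max(u), length.out = n_bins)
  residuals <- vapply(seq_len(n_bins) - 1L, function(l) {
    sum((u[((seq_len(n_bins) - 1L + l) %% n_bins) + 1L] - h)^2)
  }, numeric(1))
  if (diff(range(u)) == 0) {
    warn2("constant UMI course; all shifts tie, shift 0 returned")
    best <- 0L
  } else {
    best <- which.min(residuals) - 1L
  }
  # under the winning shift, position 1 of the ramp (the minimum) is bin
  # 1 + best: division happens at the start of that bin
  division_bin <- as.integer((best %% n_bins) + 1L)
  first_cell <- bin_cells[[division_bin]][1]
  structure(list(bin_means = u, bin_cells = bin_cells,
                 bin_size = bin_size, best_shift = best,
                 division_bin = division_bin,
                 residuals = residuals,
                 division_angle_hint = angles[first_cell]),
            class = "cc_umi_course")
}

#' Align the division point to the positive DC1 axis
#'
#' Rotates the cell-cycle plane in-plane so that the cyclic midpoint
#' between the last pre-division cell and the first post-division cell sits
#' at angle 0. Idempotent: aligning an already-aligned plane is the
#' identity.
#'
#' @param angles per-cell angles in `[0, 2*pi)`.
#' @param umi_course a `cc_umi_course` from [find_division()].
#' @return List with `angles` (aligned), `offset` (the rotation applied,
#'   subtract from old angles), `division_angle` (the original-frame angle
#'   now at 0).
#' @export
align_division <- function(angles, umi_course) {
  bins <- umi_course$bin_cells
  n_bins <- length(bins)
  db <- umi_course$division_bin
  prev <- if (db == 1) n_bins else db - 1L
  first_post <- angles[bins[[db]][1]]
  cells_prev <- bins[[prev]]
  last_pre <- angles[cells_prev[length(cells_prev)]]
  division_angle <- cyclic_midpoint(last_pre, first_post)
  list(angles = wrap_angle(angles - division_angle),
       offset = division_angle,
       division_angle = division_angle)
}

#' Phase boundaries from literature phase durations
#'
#' With cells assumed uniform along the cycle, a phase occupying a fraction
#' f of total cycle time occupies the same fraction of cells in pseudotime
#' order. The transition out of each phase falls after
#' `x = n * cumulative_fraction` cells (counting from the first cell after
#' division); the boundary angle is the cyclic mean angle of cells x and
#' x + 1.
#'
#' @param angles_aligned per-cell division-aligned angles.
#' @param phase_lengths named numeric vector of positive phase durations in
#'   cycle order starting at division (e.g. `c(G1 = 11, S = 8, G2 = 4,
#'   M = 1)`).
#' @return A tibble with `transition` (e.g. `"G1-S"`), `after_cell`
#'   (boundary rank x), `angle`.
#' @export
phase_boundaries <- function(angles_aligned, phase_lengths) {
  if (any(phase_lengths <= 0) || sum(phase_lengths) <= 0) {
    stop2("phase durations must be positive")
  }
  n <- length(angles_aligned)
  ord <- order(angles_aligned)
  frac <- cumsum(phase_lengths) / sum(phase_lengths)
  x <- round(n * frac)
  nm <- names(phase_lengths)
  to <- c(nm[-1], nm[1])
  ang <- vapply(x, function(xi) {
    a <- angles_aligned[ord[((xi - 1) %% n) + 1]]
    b <- angles_aligned[ord[(xi %% n) + 1]]
    cyclic_midpoint(a, b)
  }, numeric(1))
  tibble::tibble(transition = paste0(nm, "-", to),
                 after_cell = as.integer(x), angle = ang)
}

#' Cycle coordinates: pseudotime from the DC plane
#'
#' Full conversion of DC1-DC2 coordinates into a synchronized pseudotime:
#' orients the plane along the phase sequence, finds the division point
#' from the total-UMI ramp, aligns it to angle 0, and ranks cells by
#' aligned angle.
#'
#' @param dc_space a `cc_dc_space` object.
#' @param phases per-cell phase labels (the retained cells, in
#'   `dc_space$cell_ids` order).
#' @param total_umi per-cell total UMI counts (same order).
#' @param bin_size cells per UMI bin (default 30).
#' @param phase_lengths optional named duration vector for
#'   [phase_boundaries()]; default the bundled HeLa-like table.
#' @return Object of class `cc_cycle_coordinates`: list with `cells` (a
#'   tibble: `cell_id`, `dc1`, `dc2`, `dc3`, `angle`, `radius`,
#'   `pseudotime_rank`, `phase`), `division_angle` (in the oriented,
#'   pre-alignment frame), `flipped`, `boundaries`, `umi_course`.
#' @export
cycle_coordinates <- function(dc_space, phases, total_umi, bin_size = 30,
                              phase_lengths = default_phase_lengths()) {
  stopifnot(inherits(dc_space, "cc_dc_space"))
  dc <- dc_space$dc_scores
  n <- ncol(dc)
  stopifnot(length(phases) == n, length(total_umi) == n)
  ori <- orient_cycle(dc[1, ], dc[2, ], phases)
  pol <- polar_coordinates(ori$dc1, ori$dc2)
  if (any(pol$at_origin)) {
    warn2(sum(pol$at_origin), " cell(s) exactly at the origin")
  }
  course <- find_division(pol$angle, total_umi, bin_size = bin_size)
  al <- align_division(pol$angle, course)
  rank <- integer(n)
  rank[order(al$angles)] <- seq_len(n)
  boundaries <- phase_boundaries(al$angles, phase_lengths)
  cells <- tibble::tibble(
    cell_id = dc_space$cell_ids,
    dc1 = pol$radius * cos(al$angles),
    dc2 = pol$radius * sin(al$angles),
    dc3 = if (nrow(dc) >= 3) dc[3, ] else NA_real_,
    angle = al$angles,
    radius = pol$radius,
    pseudotime_rank = rank,
    phase = factor(as.character(phases), levels = cc_phases())
  )
  structure(list(cells = cells, division_angle = al$division_angle,
                 flipped = ori$flipped, boundaries = boundaries,
                 umi_course = course),
            class = "cc_cycle_coordinates")
}

#' @export
print.cc_cycle_coordinates <- function(x, ...) {
  cat(sprintf("<cc_cycle_coordinates> %d cells; division at angle %.3f (pre-alignment frame)%s\n",
              nrow(x$cells), x$division_angle,
              if (x$flipped) "; DC2 sign flipped for orientation" else ""))
  invisible(x)
}

#' Binned gene time course over pseudotime
#'
#' Cells are uniformly re-spaced by pseudotime rank (so progression is
#' proportional to cycle time under the uniform-density assumption) and a
#' per-bin mean expression course is computed over `n_bins` equal-count
#' bins in pseudotime order.
#'
#' @param values per-cell numeric vector (e.g. one gene's expression), in
#'   the same cell order as `coords`.
#' @param coords a `cc_cycle_coordinates` object.
#' @param n_bins number of pseudotime bins (default 20).
#' @return A tibble with `bin`, `n_cells`, `mean_value`.
#' @export
gene_time_course <- function(values, coords, n_bins = 20) {
  stopifnot(inherits(coords, "cc_cycle_coordinates"), n_bins >= 2)
  n <- nrow(coords$cells)
  stopifnot(length(values) == n)
  ord <- order(coords$cells$pseudotime_rank)
  bins <- equal_count_bins(n, n_bins)
  v <- values[ord]
  tibble::tibble(
    bin = seq_len(n_bins),
    n_cells = as.integer(table(bins)),
    mean_value = as.numeric(tapply(v, bins, mean))
  )
}

#' Onset times from normalized time courses
#'
#' Each gene's binned course is rescaled to \[0, 1\] and the onset is the
#' first pseudotime bin (scanning cyclically from division) where the
#' rescaled course crosses 0.5 from below. Genes with constant courses are
#' excluded with a warning. The result is sorted by onset.
#'
#' @param courses genes x bins matrix of binned mean courses (rows named by
#'   gene), bins in pseudotime order starting at division.
#' @return A tibble with `gene`, `onset_bin`, sorted by onset (ties keep
#'   input order); attribute `scaled` holds the rescaled course matrix.
#' @export
onset_times <- function(courses) {
  stopifnot(is.matrix(courses), ncol(courses) >= 2)
  rng <- apply(courses, 1, function(x) diff(range(x)))
  if (any(rng == 0)) {
    warn2(sum(rng == 0), " constant course(s) excluded from onset ordering")
  }
  keep <- which(rng > 0)
  scaled <- courses[keep, , drop = FALSE]
  scaled <- (scaled - apply(scaled, 1, min)) / rng[keep]
  nb <- ncol(scaled)
  onset <- apply(scaled, 1, function(x) {
    prev <- x[c(nb, seq_len(nb - 1))]
    hits <- which(x >= 0.5 & prev < 0.5)
    if (length(hits) == 0) which.max(x >= 0.5) else hits[1]
  })
  out <- tibble::tibble(gene = rownames(scaled), onset_bin = as.integer(onset))
  out <- out[order(out$onset_bin), ]
  attr(out, "scaled") <- scaled[out$gene, , drop = FALSE]
  out
}

#' Bundled phase-length table
#'
#' Literature-rough cell-cycle phase durations (hours) for a HeLa-like
#' cell line, in cycle order starting at division. Configuration data;
#' replace with the table for your cell line.
#'
#' @return Named numeric vector `c(G1, S, G2, M)`.
#' @export
default_phase_lengths <- function() {
  tab <- utils::read.table(system.file("extdata", "phase_lengths_hela.tsv",
                                       package = "cyclodyn", mustWork = TRUE),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$hours, tab$phase)
}
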