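#' Steady-state RNA velocity estimate
#'
#' Constant-derivative ("model I") velocity on size-normalized profiles:
#' spliced and unspliced counts are depth-normalized per cell (to the
#' spliced median total, the same convention as the fraction transform),
#' a per-gene degradation ratio \eqn{\gamma_g} is fit by least squares
#' through the origin on the cells in the extreme quantiles of the gene's
#' spliced expression, and the velocity is \eqn{v = u - \gamma_g s}.
#' A precomputed velocity matrix may be supplied downstream instead of this
#' estimate.
#'
#' @param spliced,unspliced matched [cc_counts] objects (same gene and cell
#'   universe).
#' @param gamma_quantile fraction of cells at each extreme used for the
#'   \eqn{\gamma} fit (default 0.05).
#' @return List with `v` (genes x cells velocity matrix on the
#'   size-normalized scale), `gamma` (per gene), `zero_genes` (genes with no
#'   unspliced signal; their velocity row is 0).
#' @export
estimate_velocity <- function(spliced, unspliced, gamma_quantile = 0.05) {
  stopifnot(inherits(spliced, "cc_counts"), inherits(unspliced, "cc_counts"))
  if (!identical(rownames(spliced$counts), rownames(unspliced$counts)) ||
      !identical(colnames(spliced$counts), colnames(unspliced$counts))) {
    stop2("spliced and unspliced matrices must share genes and cells")
  }
  s_tot <- colSums(spliced$counts)
  u_tot <- colSums(unspliced$counts)
  if (any(s_tot == 0) || any(u_tot == 0)) {
    stop2("cell with zero spliced or unspliced total")
  }
  kappa <- stats::median(s_tot)
  s <- sweep(spliced$counts, 2, s_tot, "/") * kappa
  u <- sweep(unspliced$counts, 2, u_tot, "/") * kappa
  n <- ncol(s)
  n_ext <- max(1L, floor(gamma_quantile * n))
  gamma <- numeric(nrow(s))
  zero_genes <- character(0)
  for (i in seq_len(nrow(s))) {
    si <- s[i, ]; ui <- u[i, ]
    if (all(ui == 0)) {
      gamma[i] <- NA_real_
      zero_genes <- c(zero_genes, rownames(s)[i])
      next
    }
    ord <- order(si)
    ext <- c(utils::head(ord, n_ext), utils::tail(ord, n_ext))
    denom <- sum(si[ext]^2)
    gamma[i] <- if (denom == 0) 0 else sum(si[ext] * ui[ext]) / denom
  }
  v <- u - gamma * s
  v[is.na(gamma), ] <- 0
  if (length(zero_genes)) {
    message(length(zero_genes), " gene(s) with no unspliced signal; velocity row set to 0")
  }
  names(gamma) <- rownames(s)
  list(v = v, gamma = gamma, zero_genes = zero_genes)
}

#' Extrapolate cell states and project into DC space
#'
#' Implements the extrapolation chain: \eqn{s^{ex} = S\,T + V} at t = 1 on
#' the per-cell fraction scale (negative entries clipped to 0),
#' \eqn{LF^{ex} = \log_e(c \cdot s^{ex} + 1)} with the fixed constant
#' \eqn{c = 10^4} (or \eqn{\kappa} via `scale_constant = "kappa"` for
#' consistency experiments), per-gene z-scoring restricted to the analyzed
#' genes, and \eqn{DC^{ex} = R\,W^T\,N^{ex}}. The per-cell displacement is
#' `dc_ex - dc`.
#'
#' By default the z-scoring uses the extrapolated matrix's own gene
#' statistics, as specified; `stats = "observed"` reuses the observed-data
#' means/sds recorded at normalization (with `scale_constant = "kappa"`
#' this makes V = 0 reproduce the observed DC scores exactly).
#'
#' @param spliced a [cc_counts] object (the raw data the velocity was
#'   estimated on, restricted to the analyzed cells).
#' @param v genes x cells velocity matrix on the size-normalized scale.
#' @param dc_space a `cc_dc_space` object.
#' @param t extrapolation time (default 1).
#' @param scale_constant `1e4` (default) or `"kappa"`.
#' @param stats `"extrapolated"` (default) or `"observed"`.
#' @return List with `dc_ex` (components x cells), `displacement`
#'   (components x cells, `dc_ex - dc`), `n_clipped` (negative extrapolated
#'   entries clipped to 0).
#' @export
extrapolate_and_project <- function(spliced, v, dc_space, t = 1,
                                    scale_constant = 1e4,
                                    stats = c("extrapolated", "observed")) {
  stopifnot(inherits(spliced, "cc_counts"), inherits(dc_space, "cc_dc_space"))
  stats <- match.arg(stats)
  genes <- dc_space$gene_ids
  stopifnot(identical(colnames(spliced$counts), dc_space$cell_ids))
  theta <- colSums(spliced$counts)
  if (any(theta == 0)) stop2("cell with zero total UMI count")
  kappa <- dc_space$kappa
  # velocity operates on the kappa-scaled profiles; bring both terms to the
  # plain fraction scale of S.T before applying the transform constant
  s_frac <- sweep(spliced$counts, 2, theta, "/")
  s_ex <- s_frac + (v / kappa) * t
  n_clipped <- sum(s_ex < 0)
  s_ex[s_ex < 0] <- 0
  const <- if (identical(scale_constant, "kappa")) kappa else scale_constant
  lf_ex <- log(const * s_ex + 1)
  lf_ex <- lf_ex[genes, , drop = FALSE]
  if (stats == "extrapolated") {
    z <- zscore_rows(lf_ex)
    n_ex <- z$values
    if (length(z$degenerate)) {
      # constant rows carry no direction; contribute 0 after centering
      n_ex[z$degenerate, ] <- 0
      message(length(z$degenerate), " constant extrapolated gene row(s) set to 0")
    }
  } else {
    n_ex <- (lf_ex - dc_space$gene_means[genes]) / dc_space$gene_sds[genes]
  }
  dc_ex <- dc_space$rotated_weights %*% n_ex
  displacement <- dc_ex - dc_space$dc_scores
  list(dc_ex = dc_ex, displacement = displacement, n_clipped = n_clipped)
}

#' Gaussian-kernel smoothing of a displacement field on a grid
#'
#' Overlays a regular `grid_n` x `grid_n` lattice on the positions and
#' assigns each grid point the kernel-weighted sum of per-cell
#' displacements, \eqn{\Delta x_{grid}(k) = \sum_j K(x_{grid}(k), x_j)
#' \Delta x_j} with the (unnormalized) Gaussian kernel
#' \eqn{K(a, b) = \exp(-\|a-b\|^2 / 2\varrho^2)}. Arrows shorter than
#' `min_arrow` are flagged hidden for display.
#'
#' @param positions n x 2 matrix of cell positions.
#' @param displacements n x 2 matrix of per-cell displacements.
#' @param grid_n grid resolution per side (default 50).
#' @param rho kernel width (default 0.6).
#' @param min_arrow display threshold on arrow length (default 0.1).
#' @return A tibble (class `cc_field`) with `x`, `y`, `dx`, `dy`, `length`,
#'   `shown`.
#' @export
grid_smooth <- function(positions, displacements, grid_n = 50, rho = 0.6,
                        min_arrow = 0.1) {
  positions <- as.matrix(positions); displacements <- as.matrix(displacements)
  stopifnot(ncol(positions) == 2, all(is.finite(positions)),
            nrow(positions) == nrow(displacements))
  gx <- seq(min(positions[, 1]), max(positions[, 1]), length.out = grid_n)
  gy <- seq(min(positions[, 2]), max(positions[, 2]), length.out = grid_n)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  d2 <- outer(rowSums(grid^2), rowSums(positions^2), "+") -
    2 * grid %*% t(positions)
  w <- exp(-pmax(d2, 0) / (2 * rho^2))
  arrows <- w %*% displacements
  len <- sqrt(rowSums(arrows^2))
  out <- tibble::tibble(x = grid[, 1], y = grid[, 2],
                        dx = arrows[, 1], dy = arrows[, 2],
                        length = len, shown = len >= min_arrow)
  class(out) <- c("cc_field", class(out))
  attr(out, "rho") <- rho
  attr(out, "min_arrow") <- min_arrow
  out
}

#' Smoothed field on the opened cylinder side
#'
#' For motion parallel to the cylinder axis, the angle coordinate is scaled
#' by the mean annulus radius (making the Gaussian kernel approximately
#' symmetric in both directions), the field is smoothed as in
#' [grid_smooth()] with `rho = 2`, and arrows are rescaled back to the
#' angle-DC3 plane. The cylinder is cut at `cut_angle`; periodic wrap is
#' handled by replicating all cells one full period to each side before
#' smoothing, which makes the field independent of the cut position.
#'
#' @param angles per-cell angles in `[0, 2*pi)`.
#' @param dc3 per-cell DC3 coordinate.
#' @param d_angle per-cell angular displacement (radians).
#' @param d_dc3 per-cell DC3 displacement.
#' @param cut_angle angle at which the cylinder is cut open (default 0, the
#'   division / M-G1 transition in aligned coordinates).
#' @param grid_n grid resolution per side (default 50).
#' @param rho kernel width in scaled units (default 2).
#' @param min_arrow display threshold (default 0.4).
#' @return A `cc_field` tibble with `x` (angle from the cut, in radians),
#'   `y` (DC3), `dx` (angular), `dy`, `length`, `shown`.
#' @export
cylinder_side_field <- function(angles, dc3, d_angle, d_dc3, cut_angle = 0,
                                grid_n = 50, rho = 2, min_arrow = 0.4) {
  stopifnot(all(angles >= 0 & angles < 2 * pi))
  mean_r <- attr(angles, "mean_radius")
  if (is.null(mean_r)) stop2("angles must carry a 'mean_radius' attribute; see cycle field helpers")
  phi <- wrap_angle(angles - cut_angle)
  period <- 2 * pi * mean_r
  x <- phi * mean_r
  # replicate one period to each side so the kernel sees the wrap
  x_rep <- c(x - period, x, x + period)
  y_rep <- rep(dc3, 3)
  dx_rep <- rep(d_angle * mean_r, 3)
  dy_rep <- rep(d_dc3, 3)
  gx <- seq(0, period, length.out = grid_n)
  gy <- seq(min(dc3), max(dc3), length.out = grid_n)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  pos <- cbind(x_rep, y_rep)
  d2 <- outer(rowSums(grid^2), rowSums(pos^2), "+") - 2 * grid %*% t(pos)
  w <- exp(-pmax(d2, 0) / (2 * rho^2))
  arrows <- w %*% cbind(dx_rep, dy_rep)
  len <- sqrt(rowSums(arrows^2))
  out <- tibble::tibble(x = grid[, 1] / mean_r, y = grid[, 2],
                        dx = arrows[, 1] / mean_r, dy = arrows[, 2],
                        length = len, shown = len >= min_arrow)
  class(out) <- c("cc_field", class(out))
  attr(out, "rho") <- rho
  attr(out, "min_arrow") <- min_arrow
  attr(out, "mean_radius") <- mean_r
  out
}

#' Angular and axial displacement of extrapolated states
#'
#' Converts DC-space displacements to the cylinder coordinates used by the
#' side-view field: angular displacement in the DC1-DC2 plane (short-arc
#' difference of polar angles) and the DC3 displacement. The returned
#' angles carry a `mean_radius` attribute consumed by
#' [cylinder_side_field()].
#'
#' @param dc_space a `cc_dc_space` object.
#' @param projection result of [extrapolate_and_project()].
#' @return List with `angles` (observed, with `mean_radius` attribute),
#'   `d_angle`, `dc3`, `d_dc3`.
#' @export
cylinder_displacements <- function(dc_space, projection) {
  dc <- dc_space$dc_scores
  dce <- projection$dc_ex
  a0 <- atan2(dc[2, ], dc[1, ])
  a1 <- atan2(dce[2, ], dce[1, ])
  d_angle <- ((a1 - a0 + pi) %% (2 * pi)) - pi
  angles <- wrap_angle(a0)
  attr(angles, "mean_radius") <- mean(sqrt(dc[1, ]^2 + dc[2, ]^2))
  list(angles = angles, d_angle = d_angle,
       dc3 = dc[3, ], d_dc3 = dce[3, ] - dc[3, ])
}
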