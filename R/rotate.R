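#' Rotation taking a viewing axis to the third coordinate
#'
#' Given a unit 3-vector \eqn{\omega} (the axis of the cell-cycle cylinder),
#' constructs the rotation \eqn{R = R_y(\beta) R_x(\alpha)} with
#' \eqn{R \omega = (0, 0, 1)^T}. The angles are computed robustly as
#' \eqn{\alpha = \mathrm{atan2}(\omega_2, \omega_3)},
#' \eqn{\beta = -\arcsin(\omega_1)}; the degenerate axis
#' \eqn{\omega = \pm e_1} resolves to \eqn{\alpha = 0}.
#'
#' @param omega unit 3-vector (tolerance 1e-8 on the norm).
#' @return Object of class `cc_rotation_step`: list with `omega`, `alpha`,
#'   `beta`, and the 3x3 rotation matrix `r3` (orthogonal, det +1).
#' @export
rotation_from_axis <- function(omega) {
  stopifnot(length(omega) == 3)
  if (abs(sqrt(sum(omega^2)) - 1) > 1e-8) stop2("omega must be a unit vector")
  alpha <- atan2(omega[2], omega[3])          # 0 when omega = +-e1
  beta <- -asin(max(-1, min(1, omega[1])))
  rx <- matrix(c(1, 0, 0,
                 0, cos(alpha), -sin(alpha),
                 0, sin(alpha), cos(alpha)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(beta), 0, sin(beta),
                 0, 1, 0,
                 -sin(beta), 0, cos(beta)), 3, 3, byrow = TRUE)
  r3 <- ry %*% rx
  structure(list(omega = omega, alpha = alpha, beta = beta, r3 = r3),
            class = "cc_rotation_step")
}

#' Spherical Fibonacci (golden spiral) grid
#'
#' Deterministic set of `n` approximately equidistant points on the unit
#' sphere: the z coordinates are uniformly spaced and the azimuth advances
#' by the golden angle.
#'
#' @param n number of points (default 10000).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_grid <- function(n = 10000) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- if (n == 1) 0 else 1 - (2 * (i - 1) + 1) / n   # midpoints of n z-slabs
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Cluster-score of an axis over the five phase cluster means
#'
#' The cluster score of a candidate viewing axis is the standard deviation
#' (1/5 denominator) of the scalar projections of the five phase cluster
#' means onto the axis. By linearity of means this equals the cluster score
#' of all cells projected onto the axis. Minimizing it over axes places the
#' five cluster means into a common plane orthogonal to the winner.
#'
#' @param candidate unit 3-vector (or n x 3 matrix of candidates).
#' @param cluster_means 5 x 3 matrix, the phase cluster means
#'   \eqn{\gamma_\eta} in the current 3-subspace.
#' @return Scalar score (or vector, one per candidate row).
#' @export
axis_score <- function(candidate, cluster_means) {
  stopifnot(ncol(cluster_means) == 3, nrow(cluster_means) == 5)
  if (is.null(dim(candidate))) candidate <- matrix(candidate, nrow = 1)
  proj <- cluster_means %*% t(candidate)      # 5 x n_candidates
  m <- colMeans(proj)
  out <- sqrt(colMeans((proj - rep(m, each = 5))^2))
  if (length(out) == 1) out[[1]] else out
}

# Fibonacci-style grid of n points in the spherical cap of angular radius
# `radius` around the +z pole, then rotated so the pole maps to `center`.
cap_grid <- function(n, radius, center) {
  i <- seq_len(n)
  zmin <- cos(radius)
  z <- if (n == 1) 1 else 1 - (2 * (i - 1) + 1) / n * (1 - zmin)
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  # rotate +e3 onto center: inverse of the axis-to-e3 rotation
  rot <- t(rotation_from_axis(center / sqrt(sum(center^2)))$r3)
  pts %*% t(rot)
}

# canonical sign for a viewing axis: third coordinate non-negative,
# ties toward positive first coordinate
canonical_axis <- function(omega) {
  if (omega[3] < 0 || (omega[3] == 0 && omega[1] < 0)) -omega else omega
}

#' Find the optimal viewing axis
#'
#' Two-step minimization of [axis_score()]: a coarse search over an
#' `n_coarse`-point spherical Fibonacci grid, then a refined search over an
#' equally sized Fibonacci-style cap grid of angular radius twice the coarse
#' grid spacing around the coarse winner (about a thousandfold finer
#' solid-angle resolution). Deterministic. The axis sign is canonicalized
#' to a non-negative third coordinate (both signs define the same plane).
#'
#' @param cluster_means 5 x 3 matrix of phase cluster means.
#' @param n_coarse grid size for both stages (default 10000).
#' @return List with `omega` (unit 3-vector), `score`, `coarse_score`.
#' @export
find_viewing_axis <- function(cluster_means, n_coarse = 10000) {
  stopifnot(nrow(cluster_means) == 5, ncol(cluster_means) == 3)
  if (all(apply(cluster_means, 2, function(col) pop_sd(col) == 0))) {
    warn2("degenerate cluster means (all identical); returning e3")
    return(list(omega = c(0, 0, 1), score = 0, coarse_score = 0))
  }
  grid <- golden_spiral_grid(n_coarse)
  sc <- axis_score(grid, cluster_means)
  best <- which.min(sc)
  coarse_axis <- grid[best, ]
  coarse_score <- sc[best]
  spacing <- sqrt(4 * pi / n_coarse)          # coarse cell angular scale
  ref <- cap_grid(n_coarse, 2 * spacing, coarse_axis)
  sc2 <- axis_score(ref, cluster_means)
  best2 <- which.min(sc2)
  if (sc2[best2] <= coarse_score) {
    omega <- ref[best2, ]; score <- sc2[best2]
  } else {
    omega <- coarse_axis; score <- coarse_score
  }
  list(omega = canonical_axis(omega / sqrt(sum(omega^2))), score = score,
       coarse_score = coarse_score)
}

# Embed a 3x3 rotation into a K x K identity at dimensions dims (ordered
# triple), preserving all other coordinates.
embed_rotation <- function(r3, dims, k) {
  r <- diag(k)
  r[dims, dims] <- r3
  r
}

#' Sequence of three-dimensional rotations to dynamical components
#'
#' Rotates PC space so that cell-cycle variation concentrates in the first
#' two components. For each cell-cycle-significant component k beyond the
#' first two (ascending order), the current components (1, 2, k) span a
#' 3-subspace; the five phase cluster means are computed there, the optimal
#' viewing axis (minimal cluster score) is found, and the axis-to-e3
#' rotation is embedded into the full K x K space and applied. The composed
#' rotation R is orthogonal with determinant +1; components never touched by
#' any step keep their PC scores exactly. Rotated weights are
#' \eqn{U = R W^T} and DC scores \eqn{DC = R P}.
#'
#' @param pca a `cc_pca` object.
#' @param cc_components integer vector of cell-cycle-significant components
#'   (from [score_outliers()]). Components 1 and 2 are forced in with a
#'   warning if absent.
#' @param phases per-cell phase labels (all five represented).
#' @param n_coarse grid size for the axis search (default 10000).
#' @return Object of class `cc_dc_space`: list with `rotation` (K x K),
#'   `rotated_weights` (U), `dc_scores` (DC), `steps` (per-step records:
#'   dims, omega, alpha, beta, score), `cc_components`, and fields carried
#'   over from `pca`.
#' @export
sequential_rotation <- function(pca, cc_components, phases,
                                n_coarse = 10000) {
  stopifnot(inherits(pca, "cc_pca"))
  k <- nrow(pca$scores)
  cc_components <- sort(unique(as.integer(cc_components)))
  if (any(cc_components > k | cc_components < 1)) {
    stop2("cc component index out of range")
  }
  if (!all(c(1L, 2L) %in% cc_components)) {
    warn2("components 1 and 2 forced into the cell-cycle set")
    cc_components <- sort(union(cc_components, c(1L, 2L)))
  }
  rot <- diag(k)
  scores <- pca$scores
  steps <- list()
  todo <- setdiff(cc_components, c(1L, 2L))
  if (length(todo) == 0) {
    message("cell-cycle set is {1, 2}; rotation is the identity")
  }
  for (comp in todo) {
    dims <- c(1L, 2L, comp)
    mu <- phase_cluster_means(scores[dims, , drop = FALSE], phases)  # 5 x 3
    ax <- find_viewing_axis(mu, n_coarse = n_coarse)
    step <- rotation_from_axis(ax$omega)
    r_full <- embed_rotation(step$r3, dims, k)
    rot <- r_full %*% rot
    scores <- r_full %*% scores
    steps[[length(steps) + 1]] <- list(dims = dims, omega = ax$omega,
                                       alpha = step$alpha, beta = step$beta,
                                       score = ax$score)
  }
  u <- rot %*% pca$weights
  dimnames(scores) <- list(paste0("DC", seq_len(k)), pca$cell_ids)
  dimnames(u) <- list(paste0("DC", seq_len(k)), pca$gene_ids)
  structure(list(rotation = rot, rotated_weights = u, dc_scores = scores,
                 steps = steps, cc_components = cc_components,
                 eigenvalues = pca$eigenvalues,
                 gene_ids = pca$gene_ids, cell_ids = pca$cell_ids,
                 gene_means = pca$gene_means, gene_sds = pca$gene_sds,
                 kappa = pca$kappa),
            class = "cc_dc_space")
}

#' @export
print.cc_dc_space <- function(x, ...) {
  cat(sprintf("<cc_dc_space> %d components, %d rotation step(s), cc components {%s}\n",
              nrow(x$dc_scores), length(x$steps),
              paste(x$cc_components, collapse = ", ")))
  invisible(x)
}
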