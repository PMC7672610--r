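#' Per-gene mean and dispersion statistics
#'
#' Computes, per gene, the log mean expression
#' \eqn{\zeta_i = \log_e(\frac{1}{n}\sum_j \exp(LF_{ij}))} and the dispersion
#' \eqn{d_i = \log_e\big(\frac{\mathrm{Var}_j(\exp(LF_{ij}) - 1)}{\frac{1}{n}\sum_j \exp(LF_{ij}) - 1}\big)}
#' on the log-fraction matrix. Genes whose dispersion argument is not
#' positive (e.g. constant genes) get `d = -Inf` and are excluded from the
#' dispersion buckets.
#'
#' @param lf a `cc_transformed` object at stage `"log"`.
#' @return A tibble with columns `gene`, `zeta`, `d`.
#' @export
gene_stats <- function(lf) {
  stopifnot(inherits(lf, "cc_transformed"), lf$stage == "log")
  e <- exp(lf$values)           # back-transformed: SF + 1
  n <- ncol(e)
  mean_e <- rowMeans(e)
  zeta <- log(mean_e)
  x <- e - 1                    # SF
  # population (1/n) variance of exp(LF) - 1, as printed
  var_x <- rowMeans((x - rowMeans(x))^2)
  denom <- mean_e - 1
  arg <- var_x / denom
  d <- ifelse(is.finite(arg) & arg > 0 & denom > 0, log(arg), -Inf)
  tibble::tibble(gene = rownames(lf$values), zeta = unname(zeta),
                 d = unname(d))
}

#' Bucket-normalized dispersion
#'
#' Splits the observed range of \eqn{\zeta} into `n_bins` equal-width
#' buckets (half-open on the right; the max-\eqn{\zeta} gene goes into the
#' last bucket) and z-scores each gene's dispersion against its bucket
#' members. Buckets with a single member or zero spread get `d_norm = 0`, a
#' conservative choice that keeps such genes below the variability cutoff.
#'
#' @param stats tibble from [gene_stats()].
#' @param n_bins number of equal-width buckets over the \eqn{\zeta} range
#'   (default 20).
#' @return `stats` with added columns `bucket` and `d_norm` (`NA` for genes
#'   with infinite dispersion, which never enter a bucket).
#' @export
normalize_dispersion <- function(stats, n_bins = 20) {
  ok <- is.finite(stats$d)
  if (!any(ok)) stop2("no gene with finite dispersion")
  zmin <- min(stats$zeta[ok]); zmax <- max(stats$zeta[ok])
  step <- (zmax - zmin) / n_bins
  bucket <- rep(NA_integer_, nrow(stats))
  if (step == 0) {
    bucket[ok] <- 1L
  } else {
    b <- floor((stats$zeta[ok] - zmin) / step) + 1L
    b[b > n_bins] <- n_bins            # max-zeta gene closes the last bucket
    bucket[ok] <- as.integer(b)
  }
  d_norm <- rep(NA_real_, nrow(stats))
  for (bi in unique(bucket[ok])) {
    idx <- which(!is.na(bucket) & bucket == bi)
    dd <- stats$d[idx]
    if (length(idx) < 2) { d_norm[idx] <- 0; next }
    # population (1/n) sd within the bucket, as printed
    s <- pop_sd(dd)
    d_norm[idx] <- if (s == 0) 0 else (dd - mean(dd)) / s
  }
  stats$bucket <- bucket
  stats$d_norm <- d_norm
  stats
}

#' Select highly variable genes
#'
#' A gene is variable iff `zeta_min < zeta < zeta_max` and
#' `dnorm_min < d_norm < dnorm_max` (all strict).
#'
#' @param stats tibble from [normalize_dispersion()].
#' @param zeta_min,zeta_max bounds on the log mean expression (defaults 0.2
#'   and 4).
#' @param dnorm_min,dnorm_max bounds on the bucket-normalized dispersion
#'   (defaults 0.5 and 10).
#' @return Character vector of variable gene ids.
#' @export
select_variable <- function(stats, zeta_min = 0.2, zeta_max = 4,
                            dnorm_min = 0.5, dnorm_max = 10) {
  keep <- !is.na(stats$d_norm) &
    stats$zeta > zeta_min & stats$zeta < zeta_max &
    stats$d_norm > dnorm_min & stats$d_norm < dnorm_max
  out <- stats$gene[keep]
  if (length(out) == 0) stop2("no variable genes")
  out
}

#' Combine variable-gene sets across batches
#'
#' With L experiments analyzed individually, a gene enters the combined set
#' iff it is a variable gene in at least Q of them, where Q is the integer
#' part of \eqn{L - (L-1)/3}. For L = 2 this gives Q = 1 (the union of the
#' two sets); for L = 4, Q = 3.
#'
#' @param vg_per_batch list of character vectors, one per batch.
#' @return Object of class `cc_gene_sets`: list with `vg_all` (combined gene
#'   ids), `Q` (the integer threshold), `Q_raw` (the formula value before
#'   taking the integer part), `L`, and `vg_per_batch`.
#' @export
combine_batches <- function(vg_per_batch) {
  if (!is.list(vg_per_batch)) vg_per_batch <- list(vg_per_batch)
  L <- length(vg_per_batch)
  stopifnot(L >= 1)
  q_raw <- L - (L - 1) / 3
  q <- floor(q_raw)
  counts <- table(unlist(lapply(vg_per_batch, unique)))
  vg_all <- sort(names(counts)[counts >= q])
  structure(list(vg_all = vg_all, Q = q, Q_raw = q_raw, L = L,
                 vg_per_batch = vg_per_batch),
            class = "cc_gene_sets")
}

#' @export
print.cc_gene_sets <- function(x, ...) {
  cat(sprintf("<cc_gene_sets> %d combined variable genes from %d batch(es), Q = %.3g",
              length(x$vg_all), x$L, x$Q))
  if (!is.null(x$vg_cc)) cat(sprintf("; %d cyclic markers", length(x$vg_cc)))
  cat("\n")
  invisible(x)
}

#' Cell-cycle marker subset of the variable genes
#'
#' Intersects the combined variable-gene set with a reference list of known
#' cyclic genes.
#'
#' @param gene_sets a `cc_gene_sets` object from [combine_batches()].
#' @param cyclic_reference character vector of known cyclic gene ids.
#' @return `gene_sets` with an added `vg_cc` element.
#' @export
cc_marker_subset <- function(gene_sets, cyclic_reference) {
  stopifnot(inherits(gene_sets, "cc_gene_sets"),
            length(cyclic_reference) > 0)
  vg_cc <- intersect(gene_sets$vg_all, cyclic_reference)
  if (length(vg_cc) == 0) {
    warn2("cyclic reference disjoint from variable genes; marker scores degenerate to 0")
  }
  gene_sets$vg_cc <- vg_cc
  gene_sets
}

#' Variable genes per batch, combined
#'
#' Convenience wrapper: computes gene statistics and variable genes per
#' experiment on the log-fraction matrix of each batch, then combines the
#' per-batch sets.
#'
#' @param x a [cc_counts] object (filtered).
#' @inheritParams normalize_dispersion
#' @inheritParams select_variable
#' @return A `cc_gene_sets` object (see [combine_batches()]).
#' @export
variable_genes <- function(x, n_bins = 20, zeta_min = 0.2, zeta_max = 4,
                           dnorm_min = 0.5, dnorm_max = 10) {
  stopifnot(inherits(x, "cc_counts"))
  batches <- if (is.null(x$batch)) rep("all", ncol(x$counts)) else x$batch
  vg <- lapply(unique(batches), function(b) {
    lf <- log_fractions(scaled_fractions(subset_cells(x, batches == b)))
    st <- normalize_dispersion(gene_stats(lf), n_bins = n_bins)
    select_variable(st, zeta_min, zeta_max, dnorm_min, dnorm_max)
  })
  combine_batches(vg)
}
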