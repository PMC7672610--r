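#' Cell cycle phases
#'
#' The five cell-cycle time points used throughout, in their fixed cyclic
#' order.
#'
#' @return Character vector of the five phase labels.
#' @export
cc_phases <- function() c("G1.S", "S", "G2", "G2.M", "M.G1")

#' Read marker gene buckets
#'
#' Marker buckets are configuration data: five gene lists, one per cell-cycle
#' time point. Accepted layouts: a directory holding one plain-text file per
#' phase (named `<phase>.txt`, one gene symbol per line) or a single
#' two-column TSV (gene, phase).
#'
#' @param path directory or TSV file.
#' @return Named list of five character vectors in [cc_phases()] order.
#' @export
read_markers <- function(path) {
  phases <- cc_phases()
  if (dir.exists(path)) {
    out <- lapply(phases, function(ph) {
      f <- file.path(path, paste0(ph, ".txt"))
      if (!file.exists(f)) stop2("missing marker file for phase ", ph)
      unique(readLines(f))
    })
    names(out) <- phases
    out
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("gene", "phase") %in% names(tab))) {
      stop2("marker TSV needs columns 'gene' and 'phase'")
    }
    bad <- setdiff(unique(tab$phase), phases)
    if (length(bad)) stop2("unknown phase label: ", bad[1])
    out <- split(tab$gene, factor(tab$phase, levels = phases))
    lapply(out, unique)
  }
}

#' Bundled default marker buckets
#'
#' A compact list of canonical human cell-cycle marker genes for the five
#' time points, shipped as replaceable configuration data.
#'
#' @return Named list of five character vectors.
#' @export
default_markers <- function() {
  read_markers(system.file("extdata", "markers_human.tsv",
                           package = "cyclodyn", mustWork = TRUE))
}

restrict_buckets <- function(buckets, genes) {
  out <- lapply(buckets, intersect, genes)
  empty <- names(out)[lengths(out) == 0]
  if (length(empty)) {
    stop2("no marker genes present in data for bucket ", empty[1])
  }
  out
}

#' Average marker expression per bucket
#'
#' For each phase bucket, the per-cell mean of the log-fraction expression of
#' the bucket's genes — the average expression pattern each marker gene is
#' later correlated against.
#'
#' @param lf a `cc_transformed` object at stage `"log"`.
#' @param buckets named list of five marker gene vectors ([cc_phases()] order).
#' @return 5 x cells numeric matrix, rows named by phase.
#' @export
bucket_mean_profiles <- function(lf, buckets) {
  stopifnot(inherits(lf, "cc_transformed"), lf$stage == "log")
  buckets <- restrict_buckets(buckets, rownames(lf$values))
  xi <- t(vapply(buckets, function(g) {
    colMeans(lf$values[g, , drop = FALSE])
  }, numeric(ncol(lf$values))))
  rownames(xi) <- names(buckets)
  xi
}

#' Refine marker buckets by correlation
#'
#' Drops marker genes whose expression correlates poorly (Pearson by
#' default) with their bucket's average expression pattern; such genes
#' behave differently from the rest of the bucket and carry no phase signal.
#'
#' @param lf a `cc_transformed` object at stage `"log"`.
#' @param buckets named list of five marker gene vectors.
#' @param xi optional precomputed bucket profile matrix from
#'   [bucket_mean_profiles()].
#' @param min_corr genes with correlation below this are removed (default
#'   0.2).
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return Named list: `buckets` (refined lists), `correlations` (named list
#'   of per-gene correlations per phase).
#' @export
refine_buckets <- function(lf, buckets, xi = NULL, min_corr = 0.2,
                           method = c("pearson", "spearman")) {
  stopifnot(inherits(lf, "cc_transformed"), lf$stage == "log")
  method <- match.arg(method)
  if (ncol(lf$values) < 2) stop2("need >= 2 cells for correlation")
  buckets <- restrict_buckets(buckets, rownames(lf$values))
  if (is.null(xi)) xi <- bucket_mean_profiles(lf, buckets)
  refined <- list(); cors <- list()
  for (ph in names(buckets)) {
    g <- buckets[[ph]]
    cg <- apply(lf$values[g, , drop = FALSE], 1, stats::cor, y = xi[ph, ],
                method = method)
    keep <- g[!is.na(cg) & cg >= min_corr]
    if (length(keep) == 0) stop2("refined bucket empty for phase ", ph)
    refined[[ph]] <- keep
    cors[[ph]] <- cg
  }
  list(buckets = refined, correlations = cors)
}

#' Doubly z-scored phase score matrix
#'
#' Raw phase scores are the per-cell mean log-fraction expression over each
#' refined bucket. The 5 x cells matrix is then z-scored along rows (over
#' cells, sample sd) and afterwards along columns (over the five phases),
#' yielding scores comparable both across cells and across phases.
#'
#' @param lf a `cc_transformed` object at stage `"log"`.
#' @param refined named list of five refined marker gene vectors.
#' @return 5 x cells matrix of doubly z-scored phase scores.
#' @export
phase_scores <- function(lf, refined) {
  stopifnot(inherits(lf, "cc_transformed"), lf$stage == "log")
  if (ncol(lf$values) < 2) stop2("need >= 2 cells for phase scores")
  refined <- restrict_buckets(refined, rownames(lf$values))
  a <- t(vapply(refined, function(g) {
    colMeans(lf$values[g, , drop = FALSE])
  }, numeric(ncol(lf$values))))
  z <- zscore_rows(a)
  if (length(z$degenerate)) {
    stop2("degenerate phase score row (constant over cells) for phase ",
          names(refined)[z$degenerate[1]])
  }
  a <- z$values
  col_sd <- apply(a, 2, sample_sd)
  if (any(col_sd == 0)) stop2("degenerate phase score column (all phases equal)")
  a <- scale(a)           # column z-score over the 5 phases, sample sd
  a <- matrix(a, nrow = 5, dimnames = list(names(refined), colnames(lf$values)))
  a
}

#' Assign phases and flag doublets / low-confidence cells
#'
#' Each cell gets the phase with the highest score. Cells whose two top
#' phases are non-neighboring on the cycle (1 < |eta - eta2| < 4, so the
#' 1-5 wrap-adjacency is exempt) with a substantial runner-up score
#' (q2 > `doublet_q2`) are flagged as suspected doublets; cells whose top
#' score is below `min_q` are flagged low-confidence. Argmax ties break
#' toward the lower phase index.
#'
#' @param a 5 x cells phase score matrix from [phase_scores()].
#' @param doublet_q2 runner-up score threshold for the doublet rule
#'   (default 0.3).
#' @param min_q minimum top score for a confident assignment (default 0.75).
#' @return A tibble with one row per cell: `cell_id`, `phase` (factor in
#'   cyclic order), `phase_idx`, `q`, `phase2`, `q2`, `doublet`,
#'   `low_confidence`, `keep`.
#' @export
assign_and_filter <- function(a, doublet_q2 = 0.3, min_q = 0.75) {
  stopifnot(is.matrix(a), nrow(a) == 5)
  eta <- apply(a, 2, which.max)           # ties -> lowest index
  q <- a[cbind(eta, seq_len(ncol(a)))]
  a2 <- a
  a2[cbind(eta, seq_len(ncol(a)))] <- -Inf
  eta2 <- apply(a2, 2, which.max)
  q2 <- a2[cbind(eta2, seq_len(ncol(a)))]
  d <- abs(eta - eta2)
  doublet <- d > 1 & d < 4 & q2 > doublet_q2
  low_conf <- q < min_q
  tibble::tibble(
    cell_id = colnames(a),
    phase = factor(cc_phases()[eta], levels = cc_phases()),
    phase_idx = as.integer(eta),
    q = q,
    phase2 = factor(cc_phases()[eta2], levels = cc_phases()),
    q2 = q2,
    doublet = doublet,
    low_confidence = low_conf,
    keep = !doublet & !low_conf
  )
}

#' Marker-based phase assignment
#'
#' End-to-end phase assignment for one or more batches: bucket profiles,
#' correlation refinement, doubly z-scored phase scores, and doublet /
#' low-confidence filtering. When the counts carry batch labels, the whole
#' procedure runs on each experiment individually (so batch effects cannot
#' dominate the z-scores) and the per-cell results are concatenated in the
#' original cell order.
#'
#' @param x a [cc_counts] object (filtered).
#' @param markers named list of five marker gene vectors; defaults to the
#'   bundled list.
#' @inheritParams refine_buckets
#' @inheritParams assign_and_filter
#' @return Object of class `cc_phase_assignment`: list with `cells` (the
#'   [assign_and_filter()] tibble), `scores` (5 x cells matrix), `buckets`
#'   (refined per batch), and `params`.
#' @export
assign_phases <- function(x, markers = default_markers(), min_corr = 0.2,
                          doublet_q2 = 0.3, min_q = 0.75,
                          method = "pearson") {
  stopifnot(inherits(x, "cc_counts"))
  batches <- if (is.null(x$batch)) rep("all", ncol(x$counts)) else x$batch
  cells_order <- colnames(x$counts)
  per_batch <- lapply(unique(batches), function(b) {
    xb <- subset_cells(x, batches == b)
    lf <- log_fractions(scaled_fractions(xb))
    ref <- refine_buckets(lf, markers, min_corr = min_corr, method = method)
    a <- phase_scores(lf, ref$buckets)
    list(cells = assign_and_filter(a, doublet_q2, min_q), scores = a,
         buckets = ref$buckets)
  })
  names(per_batch) <- unique(batches)
  cells <- dplyr::bind_rows(lapply(per_batch, `[[`, "cells"))
  cells <- cells[match(cells_order, cells$cell_id), ]
  scores <- do.call(cbind, lapply(per_batch, `[[`, "scores"))
  scores <- scores[, cells_order, drop = FALSE]
  structure(list(cells = cells, scores = scores,
                 buckets = lapply(per_batch, `[[`, "buckets"),
                 params = list(min_corr = min_corr, doublet_q2 = doublet_q2,
                               min_q = min_q, method = method)),
            class = "cc_phase_assignment")
}

#' @export
print.cc_phase_assignment <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf("<cc_phase_assignment> %d cells: %d kept, %d doublets, %d low-confidence\n",
              n, sum(x$cells$keep), sum(x$cells$doublet),
              sum(x$cells$low_confidence)))
  print(table(phase = x$cells$phase[x$cells$keep]))
  invisible(x)
}
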