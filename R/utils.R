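# Internal numerical helpers shared across modules.

# Sample standard deviation (n-1 denominator); the convention used everywhere
# a standard deviation appears, except the five-phase cluster score which the
# method defines with a population (1/5) denominator.
sample_sd <- function(x) stats::sd(x)

# Population standard deviation (1/n denominator).
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Row-wise z-scoring of a matrix (per-row mean 0, sample sd 1).
# Returns list(values, means, sds); rows with sd <= tol are reported in
# `degenerate` and left untouched (callers decide the policy).
zscore_rows <- function(x, tol = 0) {
  means <- rowMeans(x)
  n <- ncol(x)
  sds <- sqrt(rowSums((x - means)^2) / (n - 1))
  degenerate <- which(sds <= tol)
  ok <- setdiff(seq_len(nrow(x)), degenerate)
  out <- x
  if (length(ok)) {
    out[ok, ] <- (x[ok, , drop = FALSE] - means[ok]) / sds[ok]
  }
  list(values = out, means = means, sds = sds, degenerate = degenerate)
}

# Wrap angles into [0, 2*pi).
wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a
}

# Circular mean of two angles along the short arc, wrapped to [0, 2*pi).
cyclic_midpoint <- function(a, b) {
  d <- wrap_angle(b - a)
  if (d > pi) d <- d - 2 * pi
  wrap_angle(a + d / 2)
}

# Equal-count bin assignment for n items into n_bins bins (sizes differ by
# at most one; earlier bins get the extra items).
equal_count_bins <- function(n, n_bins) {
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(n_bins), times = sizes)
}

# abort with a short classed condition so tests can match on message text
stop2 <- function(...) stop(paste0(...), call. = FALSE)

warn2 <- function(...) warning(paste0(...), call. = FALSE)
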