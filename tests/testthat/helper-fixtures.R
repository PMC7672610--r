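# Shared fixtures, built once per test run and cached. All simulation-based
# tests draw from these so the suite stays fast and deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default study conditions: 1,000 cells at ~4,500 mean UMIs
shared_sim <- function() {
  fixture("sim", function() simulate_population(sim_config(seed = 101)))
}

shared_pipeline <- function() {
  fixture("pipe", function() {
    sim <- shared_sim()
    suppressWarnings(suppressMessages(run_cycle_pipeline(
      sim$spliced, markers = sim$markers,
      cyclic_reference = sim$genes$gene[sim$genes$type == "cyclic"],
      verbose = FALSE)))
  })
}

# slanted-cylinder regime: drift variance comparable to the in-plane cycle
# variance, so the cycle spreads over three PCs and the rotation is real
slanted_sim <- function() {
  fixture("slanted_sim",
          function() simulate_population(sim_config(drift_strength = 0.9,
                                                    seed = 1)))
}

slanted_pipeline <- function() {
  fixture("slanted_pipe", function() {
    sim <- slanted_sim()
    suppressWarnings(suppressMessages(run_cycle_pipeline(
      sim$spliced, markers = sim$markers,
      cyclic_reference = sim$genes$gene[sim$genes$type == "cyclic"],
      verbose = FALSE)))
  })
}

# velocity objects on the shared pipeline
shared_velocity <- function() {
  fixture("velocity", function() {
    sim <- shared_sim()
    pipe <- shared_pipeline()
    us <- subset_cells(sim$unspliced, colnames(pipe$counts$counts))
    us <- cc_counts(us$counts[rownames(pipe$counts$counts), , drop = FALSE])
    vel <- estimate_velocity(pipe$counts, us)
    proj <- suppressMessages(
      extrapolate_and_project(pipe$counts, vel$v, pipe$dc_space))
    list(unspliced = us, vel = vel, proj = proj)
  })
}

# tiny deterministic count matrix for parser/transform tests
toy_counts <- function() {
  m <- matrix(c(1L, 0L,
                0L, 2L,
                5L, 5L), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  cc_counts(m)
}

# a larger random count matrix with no structure
random_counts <- function(genes = 40, cells = 25, seed = 5, lambda = 4) {
  set.seed(seed)
  m <- matrix(rpois(genes * cells, lambda), genes, cells,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("c%02d", seq_len(cells))))
  cc_counts(m)
}

# build a stage="log" object directly from a value matrix (for unit tests
# that need full control of LF entries)
as_lf <- function(values, kappa = 100) {
  out <- scaled_fractions(random_counts(2, 2, seed = 1))
  out$values <- values
  out$stage <- "log"
  out$kappa <- kappa
  out
}

# independent z-score helper used as an oracle (not the package path)
oracle_zscore_rows <- function(m) {
  t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
}
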