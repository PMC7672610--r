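# cyclodyn

Unsynchronized cell populations carry every stage of the cell cycle at
once, and in single-cell RNA-seq the cycle is usually the strongest —
and most confounding — signal in the data. `cyclodyn` isolates it by a
purely **linear** procedure: after marker-based phase assignment,
variable-gene selection, and PCA, the package composes a sequence of
three-dimensional rotations of PC space so that the cycle collapses into
a two-dimensional plane of *dynamical components* (DC1–DC2). Because
the transform is a rotation, the geometry of the trajectory is
preserved, the transform is trivially invertible, and the cycle can be
*removed* from the data by subtracting two matrix terms.

## The method in brief

Given a genes×cells UMI matrix S with per-cell totals θ<sub>j</sub>:

1. **Transforms** — scaled fractions SF = κ·S·T with T = diag(1/θ<sub>j</sub>)
   and κ the median total; LF = log(SF + 1); N = per-gene z-scored LF
   restricted to the variable genes.
2. **Phase assignment** — five marker-gene buckets (G1.S, S, G2, G2.M,
   M.G1); bucket scores are doubly z-scored; suspected doublets
   (two distant phase peaks with runner-up score > 0.3) and
   low-confidence cells (top score < 0.75) are removed.
3. **Variable genes** — per-gene log mean ζ and dispersion d, z-scored
   within 20 equal-width ζ buckets; a gene is variable iff
   0.2 < ζ < 4 and 0.5 < d̃ < 10; multi-batch sets combine at threshold
   Q = ⌊L − (L−1)/3⌋.
4. **PCA and scores** — eigendecomposition of Cov(Nᵀ) = (1/(n−1))·N·Nᵀ;
   per component a *cluster score* σ (spread of the five phase-cluster
   means) and a *marker score* (summed squared loadings of known cyclic
   genes). Components with σ > mean + 2·SD over the first 100 are
   cell-cycle significant.
5. **Rotation** — for each significant component k beyond {1,2}, the
   five cluster means in the (1, 2, k) subspace are projected onto
   10,000 candidate viewing axes on a spherical Fibonacci grid (plus a
   ~1000× finer local refinement); the axis minimizing the cluster
   score is rotated onto the third coordinate. The composed R is
   orthogonal: DC = R·P, U = R·Wᵀ, and N = Uᵀ·DC exactly.
6. **Pseudotime** — polar angle in DC1–DC2, oriented along the phase
   sequence; cell division located from the cyclic-shift least-squares
   fit of the 30-cell-binned total-UMI ramp and aligned to angle 0;
   phase boundaries placed by literature phase durations.
7. **Extras** — cell-cycle removal (Ñ = N − Uᵀ₁DC₁ − Uᵀ₂DC₂) with
   verification reports; RNA-velocity extrapolation projected into DC
   space with Gaussian-kernel field smoothing (annulus and opened
   cylinder side); a Spearman-based critical-transition index along the
   cycle; and a negative-binomial simulator of cycling populations with
   full ground truth.

## Worked example

Everything below is computed, not loaded — the simulator generates a
1,000-cell population at ~4,500 mean UMIs with known phases:

```r
library(cyclodyn)

sim  <- simulate_population(sim_config(seed = 101))
pipe <- run_cycle_pipeline(sim$spliced, markers = sim$markers,
                           cyclic_reference = sim$genes$gene[sim$genes$type == "cyclic"])
pipe
#> <cc_pipeline> 2000 genes x 999 cells; 310 variable genes; cc components {1, 2}
#>   division at angle 2.863; DC1/DC2 cluster scores 5.85 / 5.74

evaluate_recovery(pipe$coords, sim$truth)$circular_correlation
#> [1] 0.988
min(pipe$coords$umi_course$bin_means) / max(pipe$coords$umi_course$bin_means)
#> [1] 0.528
```

The circular rank correlation of 0.99 says the inferred pseudotime
angle tracks the true phase almost perfectly; the 0.53 ratio is the
reset of the binned total-UMI course at the inferred division point —
transcript content halves when cells divide. `tidy(pipe)` returns the
per-cell table (DC coordinates, angle, pseudotime rank, phase, scores);
`autoplot(pipe$coords)` draws the annulus with phase-boundary spokes.

Removing the cycle and checking nothing else moved:

```r
cleaned <- remove_components(pipe$normalized, pipe$dc_space, c(1, 2))
ver <- verify_removal(cleaned, pipe$dc_space, pipe$phases$phase, pipe$gene_sets$vg_cc)
round(abs(diag(ver$weight_correlation[, -(1:2)]))[1:4], 3)
#> [1] 1 1 1 1     # cleaned PC k == original DC k+2 (up to sign)
```

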