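---
title: "Low-rank genotype imputation: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank genotype imputation: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankimpute)
```

## Why low rank?

A sample-by-SNP genotype matrix is highly redundant: linkage
disequilibrium makes nearby SNPs co-vary, and individuals share long
haplotype stretches inherited from a modest number of ancestral templates.
Numerically this shows up as a singular-value spectrum with a few dominant
values followed by a flat noise floor, so a matrix with missing calls — or
with whole columns untyped in one cohort — can be completed by asking for
the *simplest* matrix consistent with the observed entries. `rankimpute`
operationalizes "simplest" in two ways: smallest nuclear norm (a convex
surrogate for rank) and an explicit factorization through small
cluster spaces.

Both solvers work directly on the numeric coding: 0/1/2 minor-allele
counts for diploid genotypes, 0/1 for phased haplotypes, with an integer
sentinel (default −1) for missing entries. Raw solver output is real
valued and is converted back to codes by clamping to the valid range and
rounding.

## Nuclear-norm completion

With $\Omega$ the observed index set and $P_\Omega$ the projection that
zeroes everything else, the solver addresses

$$\min_X \; \mu\,\lVert X \rVert_* \; + \; \tfrac12 \lVert P_\Omega(X - M)
\rVert_F^2 ,$$

by fixed-point (proximal-gradient) iterations
$X \leftarrow \mathrm{svt}\!\left(X - \tau P_\Omega(X - M),\ \tau\mu\right)$,
where $\mathrm{svt}(\cdot, t)$ soft-thresholds singular values by $t$ —
the exact proximal operator of the nuclear norm. A continuation schedule
starts from $\mu_0 = \lVert P_\Omega(M)\rVert_2$ (where the first iterate
is an easy problem) and shrinks $\mu \leftarrow \max(\eta\mu,
\mu_{\text{final}})$ between stages, each stage iterating until the
relative objective change falls below `rel_tol`.

Tunable parameters (all in `fpca_config()`):

* `mu_final_ratio` (default `1e-4`): target regularization as a fraction
  of $\mu_0$. Smaller values push the solution toward exact interpolation
  of the observed entries; the default leaves a relative shrinkage bias of
  order $10^{-4}$, negligible after rounding to integer codes.
* `eta` (default 0.25): continuation decay; ~7 stages from $\mu_0$ to the
  default target.
* `tau` (default 1): gradient step. The masked-residual gradient is
  1-Lipschitz, so $\tau = 1$ is always stable; no line search is needed.
* `rel_tol` (default `1e-5`), `max_inner` (200), `max_outer` (50):
  stopping rules. On small matrices (tens of rows) the objective plateaus
  slowly near the solution; tests that demand recovery to $10^{-3}$
  relative error on such matrices tighten `rel_tol` to `1e-8`–`1e-10`.
* `svd_rank_cap` (default 100): singular triplets retained per
  thresholding step, a cost/accuracy guard for wide windows.
* `center` (default `"auto"`): see below.

### Column centering

Allele frequencies differ strongly across SNPs, so the raw 0/1/2 matrix
contains a dominant "column-mean" component of rank one *per scale*, and
the nuclear norm — which pays for every singular value — spends most of
its budget reproducing per-SNP means rather than sample structure. With
`center = TRUE` the solver subtracts each column's observed mean, completes
the residual matrix, and adds the means back. The zero matrix then encodes
"every sample at its SNP's mean", and the rank budget buys deviations from
that baseline. In our experiments this is immaterial under light uniform
masking but decisive under systematic missingness, where the uncentered
solver fails to improve on majority-code imputation while the centered one
clearly does. `"auto"` centers genotype panels but not bare numeric
matrices: a generic low-rank matrix has no allele-frequency offset, and
estimating spurious means from few observations degrades exact recovery,
visibly so on small matrices.

### Sliding windows

LD is local: a window of a few hundred SNPs is closer to low-rank than a
whole chromosome. `lrmc_s_complete()` splits columns into overlapping
windows (`window_spec()`, default width 500, overlap 100), completes each
window independently, and stitches overlaps either by averaging
(`average_overlap`, default) or by keeping the earlier window's estimate
(`left_priority`). With a single full-width window the result is exactly
`fpca_complete()`. The defaults are a speed/accuracy compromise — windows
also cap the SVD cost per iteration — and are deliberately configurable
because no single width suits all LD scales.

## Co-clustering factorization

The second model assigns the $n$ samples to $k_1$ row clusters and the
$m$ SNPs to $k_2$ column clusters through the factorization

$$\min \; f = \lVert A - Y_1 X Y_2^\top \rVert_F^2
\quad \text{s.t.} \quad A_{ij} = M_{ij} \;\; (i,j) \in \Omega,$$

with $Y_1$ ($n \times k_1$), $Y_2$ ($m \times k_2$) and the central-point
matrix $X$ ($k_1 \times k_2$). The completed matrix is the terminal $A$:
observed cells pinned to the data, missing cells carrying the model value
$(Y_1 X Y_2^\top)_{ij}$.

Every block has an exact minimizer with the other three fixed:

* $A$: observed cells := data, missing cells := model (zeroes their
  residual);
* $X$: minimum-norm least squares, $X = Y_1^+ A (Y_2^\top)^+$;
* $Y_1$: with regressor $B = X Y_2^\top$, $Y_1 = A B^+$;
* $Y_2$: symmetrically, $Y_2^\top = (Y_1 X)^+ A$.

Pseudo-inverses (via `MASS::ginv`) give the minimum-norm solution when a
block is rank-deficient, so every update is a true block minimizer and the
objective is non-increasing by construction — the code traps any increase
beyond `1e-10` relative slack as an internal error. We treat $Y_1, Y_2$ as
unconstrained real matrices: exact single-block minimization is only
closed-form without integrality constraints, and the "assignment"
interpretation survives as soft membership weights.

Four schedules (`mccf_config()` defaults: $k_1 = 100$, $k_2 = 20$):

* **BCU-1**: paired blocks $(A,X) \to (Y_1,X) \to (Y_2,X)$, each pair
  alternated until its objective stalls (`inner_tol = 1e-6`, cap 50);
* **BCU-2**: $A \to X \to Y_1 \to X \to Y_2$ — $X$ twice per sweep;
* **BCU-3**: BCU-2 plus a third $X$ update closing the sweep;
* **MBI-BL**: per sweep, tentatively evaluates the four moves
  $(Y_1,X)$, $(Y_2,X)$, $(A,X)$ and the lone $X$ update from the current
  state and commits only the best. Ties go to the first candidate in that
  fixed order. The fourth candidate is the single-block $X$ move: the
  central-point matrix is the only block paired with every other block, so
  it is the natural lone move alongside the three pairings.

Sweeps stop when the relative per-sweep objective change drops below
`rel_tol` (default `1e-5`) or at `max_sweeps` (500).

### Initialization

`init = "svd_warm"` (default) builds $A$ by filling missing cells with
their column's observed mean (overall mean for fully hidden columns),
takes $Y_1, Y_2$ as leading singular vectors of that filled matrix
(zero-padded past its rank), and $X$ from its closed-form update.
`init = "random_normal"` draws factor entries $N(0, 1/k)$ under the
configured seed. We made the deterministic warm start the default after
observing that random starts, while fine under uniform masking, stall in
visibly poorer stationary points when whole study columns are missing —
the regime where initialization information is scarcest. The same
observation motivated the `1e-5` sweep tolerance: under systematic
missingness the objective's slow tail still carries real improvement in
the hidden cells, and a `1e-4` stop abandons it.

### Choosing $k_1$ and $k_2$

Error is flat in $k_1$ over a wide range (the row factor is only ever used
through its column space, and extra dimensions go unused), which the test
suite verifies as a property; $k_2$ matters more, with larger values
generally better until overfitting. `k2_grid_search()` selects $k_2$ from a
candidate list (default $\{2, 3, 5, 10, 20\}$) by scoring each fit on a
held-out validation mask, breaking ties toward the smaller value.

## Evaluation

The allelic imputation error rate is the fraction of masked *alleles*
imputed incorrectly: a diploid entry carries two alleles, so truth $g$
versus imputed $\hat g$ contributes $|g - \hat g|$ errors out of 2, and a
haplotype entry 0 or 1 out of 1. An alternative whole-genotype mismatch
mode (`error_mode = "genotype"`) is provided because published error rates
do not always state which convention they use; the two agree on haplotype
data. Rounding clamps to the valid range and rounds half away from zero —
the tie rule is fixed so tests can be bit-exact; ties are measure-zero for
the solvers' real-valued output, so the choice does not affect accuracy.
The per-entry distance between raw and rounded output is exposed as a
crude uncertainty proxy; no probabilistic calibration is attempted.

The floor any model must beat is `impute_baseline_majority()`: fill every
hidden cell with its column's most frequent observed code. On haplotype
data its expected error is the mean per-column minor frequency, a useful
analytic anchor for the test suite.

## The synthetic-data generator

`simulate_mosaic_haplotypes()` realizes the mechanism that makes genotype
matrices low-rank. Each haplotype copies one of `n_founders` founder
haplotypes, switching to a random founder between adjacent SNPs with
probability `switch_rate` and flipping each allele with probability
`flip_rate`; pairs of haplotypes are summed into diploid genotypes.
Founder allele frequencies are drawn uniformly from `maf_range`. With zero
switch and flip rates the matrix rank is exactly at most `n_founders`;
positive rates blur this into the "approximately low rank plus noise"
regime real panels occupy.

The study conditions used throughout the tests and the acceptance script
are 4 founders, 400 haplotypes paired into 200 genotype samples, 1000
SNPs, and switch and flip rates of 1% — a panel whose mosaic segments are
tens of SNPs long, so that it is locally much lower rank than globally,
which is the feature that makes the windowed solver and the systematic
missingness scenario interesting. `maf_range` defaults to (0.05, 0.5):
a flat folded-frequency spread over common variants. Two masking regimes
mirror practice: `mask_uniform()` hides a fixed fraction of observed
entries at random (failed calls), and `mask_systematic()` keeps a
reference block of samples fully typed while hiding the *same* randomly
chosen 85.3% of SNP columns in every study sample — the chip-mismatch
signature, at the missingness level of a realistic cross-chip
meta-analysis.

What the generator does *not* emulate: population structure and admixture,
recombination-map heterogeneity, realistic (skewed) allele-frequency
spectra dominated by rare variants, genotyping error correlated with
allele frequency, and Hardy–Weinberg sampling of haplotype pairs (pairs
are consecutive, not random-mated). Passing tests therefore demonstrate
that the solvers exploit mosaic/LD low-rank structure correctly, not that
the specific error percentages transfer to any particular real cohort —
on real data, error rates depend heavily on the MAF spectrum, since rare
variants are easy for both the baseline and the solvers.

## Numerical choices and degenerate inputs

* Thresholding uses a full SVD truncated to `svd_rank_cap` triplets after
  shrinkage; shrunken-to-zero values never consume cap slots.
* `pinv(0) = 0` by convention, so zero blocks yield zero updates rather
  than errors; the objective still cannot increase.
* All-missing matrices are rejected at mask construction; all-missing
  *columns* are permitted (they arise under systematic masking) and fall
  back to overall-mean initialization.
* Solvers are deterministic given their configuration; the only randomness
  is factor initialization under `random_normal`, governed by `seed`, and
  every generator is a pure function of its seed with the caller's RNG
  state restored.
* Problem sizes in the test suite were chosen to exercise each property at
  the smallest scale at which it is meaningful: oracle comparisons at
  matrices up to 20×30, recovery-phase checks at 200×300 with rank 2, and
  end-to-end imputation at the 200×1000 study conditions.

## Known limitations

Completion quality under systematic missingness depends on the reference
block actually spanning the study samples' haplotype space; nothing in the
model detects reference/study mismatch. The factorization objective is
non-convex, so different initializations can reach different stationary
points (the warm start makes this reproducible but not optimal). Neither
solver phases genotypes, outputs dosage probabilities, or computes
info-scores; and SNP identity across panels is by ID string only — strand
flips and position liftover are upstream concerns.
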