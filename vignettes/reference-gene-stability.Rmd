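---
title: "Selecting stable qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(refstab)
library(dplyr)
```

## The problem

qPCR expression measurements must be normalised before they can be compared
across samples: RNA isolation yield, RNA integrity and cDNA synthesis
efficiency all vary from sample to sample and multiply every measured
quantity by a sample-specific factor. The standard remedy is to divide each
target's relative quantity by a normalisation factor built from *reference
genes* — genes whose expression is stable across the experimental
conditions. Reference genes cannot be assumed (classics such as *18S*,
*ACTB* and *GAPDH* fail under many conditions); they must be determined
empirically for the tissue and the experimental contrasts at hand.

refstab implements the four standard stability algorithms, an integrated
consensus, and a validation step, on tidy tables of quantification cycles
(Cq). The motivating design is a rodent tendon-injury experiment: a
2 (limb: injured / contralateral uninjured) × 2 (treatment: rapamycin /
vehicle) × 2 (timepoint: 7 d / 21 d) factorial with modest group sizes and
an 11-gene candidate panel, the sort of transcriptionally plastic setting
in which bad reference genes do real damage.

## Data model

The package's central structure is an ordinary tibble with one row per
sample: a `sample` column, annotation columns (`limb`, `treatment`,
`timepoint`, optionally `animal`), and one numeric column per candidate
gene. `read_cq()` builds it from long (one row per well) or wide delimited
text; technical replicates are collapsed to their mean, with per-well SDs
retained and triplicates whose SD exceeds 0.5 cycles flagged but never
dropped (the package refuses to mutate data silently; well rejection is the
analyst's decision). Samples missing any gene are dropped with a warning:
all four algorithms assume a complete rectangular matrix, and sample-level
exclusion mirrors the quality control such studies apply anyway.

Two of the methods (geNorm, NormFinder) operate on linear relative
quantities, `RQ = E^(calibrator − Cq)`:

* `E` is the amplification efficiency, a single configurable constant
  (default 2, i.e. perfect doubling) applied to all genes. Per-gene
  efficiencies are deliberately not supported: every downstream statistic
  here is ratio-based and a common `E` only rescales the log-quantity axis.
* The calibrator is the per-gene minimum Cq, so RQ ∈ (0, 1] with max 1 —
  the geNorm convention. Any per-gene anchor cancels in every pairwise
  ratio, which the test suite asserts directly.

The other two (BestKeeper, deltaCt) use raw Cq, as is conventional.

## The four algorithms

**BestKeeper** (`bestkeeper()`) forms a per-sample consensus index — the
geometric mean Cq over the panel, the original BestKeeper definition; an
arithmetic-mean variant is available behind the `index` argument since the
difference is negligible at typical Cq — and ranks genes by the Pearson
correlation `r` of their Cq profile with it. Per-gene SD and CV are
reported, and the classical `SD > 1` exclusion flag is carried as an
annotation without ever filtering the ranking. The gene under analysis is
included in its own index. BestKeeper rewards *correlation with total cDNA
content*: a gene that faithfully tracks sample loading scores highly even
if noisy in ratio terms.

**geNorm** (`genorm()`) defines the stability `M` of a gene as the mean SD
of its pairwise log2 RQ ratios with all other candidates, iteratively
discards the highest-M gene, and stops at the final "best pair", which it
cannot rank internally and which is reported tied (both rank 1.5,
preserving the rank sum for the consensus step). Ties in M break
lexicographically and are logged, making elimination fully deterministic.
The `V(n, n+1)` pairwise-variation series compares normalisation factors
built from the top n vs n + 1 ranked genes; values ≤ 0.2 conventionally
mean the extra gene is unnecessary. The `M < 0.5` and `V ≤ 0.2` thresholds
are annotations on reports and plots, never hard filters — in
transcriptionally plastic tissue `M < 1.0` is routinely accepted.

**deltaCt** (`deltact()`) is the raw-Cq twin of the first geNorm round:
the SD over samples of every pairwise Cq difference, averaged over
partners (mean rather than sum, so scores are comparable across panel
sizes; the ranking is unaffected). At `E = 2` the deltaCt score and the
first-round geNorm M are *identical*, an exact algebraic identity the
acceptance suite verifies to 1e-10 on a thousand random matrices.

**NormFinder** (`normfinder()`) is model-based. With `y = log2(RQ)`, each
sample's mean over genes is subtracted (removing the shared loading
component), residuals `r` are formed, and per-(gene, group) variances are
bias-corrected for the centering (each residual contains −1/k of every
gene's error):

σ̂²  = max{ (k/(k−2)) · (s² − T̂/k²), 0 },  T̂ = (k/(k−1)) · Σᵢ s²ᵢ

with k the panel size. Ungrouped mode treats all samples as one group and
reports ρ = sqrt(σ̂²). Grouped mode estimates per-group intergroup
differences `d` (weighted to zero across groups), a per-gene between-group
variance γ̂² = max{Σ d²/(G−1) − mean(σ̂²/n), 0}, and shrinks each `d` by
γ̂²/(γ̂² + σ̂²/n) — an empirical-Bayes guard against overinterpreting group
means at small n. The per-group stability is

ρ = |d̃| + sqrt( (σ̂²/n)·γ̂²/(γ̂² + σ̂²/n) + σ̂²/n )

averaged over groups. The design here was genuinely open: a formulation
that drops the trailing within-group term collapses to ρ = 0 for any gene
whose γ̂² truncates to zero, so a *noisy* gene with group differences
swamped by its own sampling error would rank best — an inversion of the
method's intent. Retaining the within-group sampling term keeps ρ
monotone in a gene's noise (a property the test suite checks over a noise
grid) while still penalising systematic group bias. Variance truncations
are flagged on the result. The best pair averages two genes' shrunk
differences (so opposite-signed biases cancel) with variance
(σ̂²ₐ + σ̂²ᵦ)/(4n) and a pair-level shrinkage recomputed from the averaged
differences; all pairs are scored exhaustively and the minimum returned.
Log base 2 is used throughout for consistency with geNorm — the base
rescales ρ by a constant and changes no ranking.

## Consensus and validation

`aggregate_ranks()` combines the four *ranks* (not scores — the scores live
on incommensurable scales: a correlation, two log-ratio SDs in different
units, a model SD) by geometric mean, ties broken by arithmetic-mean rank
then name. `normalization_factor()` builds the per-sample geometric mean RQ
of the chosen references (three by default; a single reference is refused
outright per MIQE, two triggers a warning). `validate_target()` divides a
target's RQ by the NF and compares within-group coefficients of variation
before and after, on the linear scale — "coefficient of variation" is a
linear-scale quantity; log2 values are emitted separately for plotting.
Good references reduce within-group CoV and expose genuine group-linked
expression patterns in the group means.

## What the simulator emulates — and what it does not

`simulate_cq()` draws Cq values from an additive model on the cycle scale:
baseline + per-sample loading offset (shared across genes, SD
`loading_sd`) + condition-linked shifts + per-sample gene noise + per-well
replicate noise. Gaussian noise in cycles is log-normal noise in quantity,
which is how qPCR error behaves. `loading_coupling < 1` creates genes that
only partially track sample loading — exactly the genes on which
BestKeeper (which rewards loading correlation) and geNorm (which cancels
it) disagree.

`default_study_config()` fixes the study conditions: 35 samples in the
2×2×2 design (19 uninjured / 16 injured, 18 rapamycin / 17 vehicle,
n = 4–5 per cell), triplicate wells with 0.1-cycle replicate noise,
0.8-cycle loading SD (a realistic spread for variable-yield tissue RNA
preps), 0.15-cycle biological noise for stable genes, and a panel of 11
candidates with baselines graded from Cq 8 (an abundant rRNA-like *18S*)
to 26. Two genes are unstable by construction — *SDHA* carries a 1.0-cycle
injury effect and *GAPDH* an opposite-signed rapamycin-by-injury
interaction (±0.7 cycles) — and *18S* (0.35) and *UBC* (0.25) carry
elevated noise, mirroring the qualitative behaviour reported for these
genes in injured tendon. These values were chosen once, as plausible
magnitudes for the tissue, and are the conditions under which the
acceptance properties are evaluated.

The simulator does *not* model amplification curves, inhibition,
pipetting outliers, melt-curve failures, or count-like dispersion at very
high Cq. Passing recovery tests therefore demonstrate that the algorithms
detect the statistical structure they claim to detect (shared loading,
group-linked shifts, gene-level noise), not that any particular real
dataset is free of artefacts the model omits.

## Numerical choices and degenerate inputs

* All SDs are unbiased (n − 1); correlations are plain Pearson.
* Ties (geNorm M, deltaCt scores, NormFinder ρ, aggregate ranks) break
  lexicographically by gene name, so every ranking is deterministic.
* A zero-variance gene: BestKeeper reports undefined r and ranks it last;
  NormFinder truncates its variance to zero (ρ = 0 ungrouped) with a flag —
  expected only for synthetic fixtures.
* Subsets with fewer than 2 samples are excluded from analysis (warned at
  fewer than 3); NormFinder refuses groups of size 1; panels below 3 genes
  are refused everywhere (the centering correction needs k − 2 > 0).
* Simulation seeds are mandatory; nothing seeds from the clock.

## Problem sizes

The test-suite and acceptance computations use the study-scale design
(11 genes × 35 samples) for recovery runs of 200 seeds, 1,000 random
matrices (≤10 genes × ≤40 samples) for the deltaCt/geNorm identity, 500
small-design runs for null calibration, and 5-gene × 8-sample fixtures for
brute-force oracle comparisons — sizes at which every brute-force oracle is
exact and fast.

## Limitations

* Efficiency is a global constant; per-gene efficiencies from standard
  curves are out of scope (rank-based results are insensitive to a common
  rescaling, but absolute M and ρ values shift with E).
* The NormFinder grouped model supports one grouping (possibly crossed)
  per fit and reports no confidence intervals on ρ.
* BestKeeper's pairwise regression p-values are not reproduced; r, SD and
  CV cover the published use of the method.
* Instrument-native exports (RDML etc.) are not parsed; inputs are plain
  delimited text.

## A complete run

```{r, eval = FALSE}
sim <- simulate_study(seed = 1)
res <- run_refstab(sim$data, out_dir = "refstab_report")
res$rankings$all_data$aggregate
```

writes every per-subset method table, the V series, grouped NormFinder
diagnostics, the aggregate rankings, validation reports for the two
worst-ranked genes, and a JSON manifest (input checksum, configuration,
collected warnings) sufficient to reproduce the run.
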