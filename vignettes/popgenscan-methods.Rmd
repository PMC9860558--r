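---
title: "Models and methods in popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

`popgenscan` analyses resequencing panels of selfing crops: windowed
diversity and differentiation scans, LD decay, joint
F~ST~/π-ratio sweep calling, multi-environment BLUPs, an EMMAX-style
mixed-model association scan, and favorable-allele tests. This vignette
documents the statistical models, the tunable parameters and their defaults,
the synthetic-data generator that the test suite validates against, and the
numerical and design choices a maintainer should know about.

## The genotype container and site filters

Genotypes live in a `geno_matrix`: an accessions × sites matrix of diploid
ALT-allele dosages (0/1/2, `NA` missing), a site tibble (`chrom`, `pos`
1-based as in VCF, `ref`, `alt`, `id`), and optionally a same-shaped depth
matrix. All downstream statistics consume dosages only; phase is never
assumed.

`filter_sites()` applies the canonical resequencing filters. A minimum-depth
rule is ambiguous between "mask individual calls" and "drop whole sites";
the default masks per-genotype calls with `DP < 8` (the conservative,
GATK-style reading) and a `depth_mode = "site_mean"` alternative drops sites
by mean depth. MAF (default ≥ 0.05) is computed on non-missing calls after
depth masking; the missing-rate cap (default 0.2) follows. Filtering is
idempotent, and the attached report records counts per criterion.

## Windowed diversity statistics

Windows are nonoverlapping 10 kb tiles per chromosome (terminal window
truncated); internally coordinates are 0-based half-open, converted to
1-based inclusive at every file boundary.

**π.** Per site, with `m` non-missing haplotypes (2 × calls) and ALT
frequency `p̂`, the unbiased heterozygosity `2p̂(1−p̂)·m/(m−1)` equals the
mean pairwise difference among the `m` haplotypes (the test suite checks
this against exhaustive enumeration). Window π sums site values and divides
by window length in bp, so unobserved positions count as invariant. Sites
with fewer than two calls are skipped.

**Tajima's D.** Computed on the complete-case samples of a window (no
missing call at any window SNP), giving a fixed haplotype count as in the
standard VCF-based implementations. `D = (π̂ − θ_W)/√(e₁S + e₂S(S−1))`
with `θ_W = S/a₁` and the 1989 constants; here `π̂` is the sum of mean
pairwise differences, not per-bp. `S = 0` returns `NA`. Under the
generator's neutral-SFS mode (below) the mean of D over unlinked windows is
centred at zero; because sites within a window are unlinked rather than
genealogically correlated, the classical variance normalization is
conservative there, which is acceptable for a null check.

**F~ST~.** Per-site Weir–Cockerham (1984) components `a` (among
populations), `b` (among individuals) and `c` (within individuals) are
computed from sample sizes, allele frequencies and observed heterozygosity
of each group, then combined as a **ratio of sums** `Σa/Σ(a+b+c)` across
the sites of a window or the genome. The ratio of sums is the weighted
estimator most tools report and is the package default; a mean of per-site
ratios is available because "average" F~ST~ is sometimes computed that way,
but it is biased upward by low-information sites and is never used by the
pipeline itself. Negative window estimates are retained (clamping happens
only in plots) so genome-wide sums stay unbiased. Sites where a group has
fewer than two calls, or with a zero denominator, are excluded.

## LD decay

LD is squared Pearson correlation of dosage vectors over shared non-missing
samples — genotype r², appropriate for unphased inbred panels and the
default of the standard decay tools. All intra-chromosomal pairs within
500 kb are evaluated through masked cross-product accumulators (above
4000 sites per chromosome, sites are thinned with the curve's seed; above
the pair budget, pairs are subsampled — both deterministic). Binned means
(1 kb default) are smoothed with a rolling median over 5 bins before any
feature extraction: single noisy bins otherwise corrupt the maximum. The
half-decay distance is the smallest distance at which the smoothed curve
reaches half its observed maximum, linearly interpolated between straddling
bins; a curve that never drops returns `NA` with a warning. "Maximum" means
the observed smoothed maximum, not a fitted intercept — with 1 kb bins the
short-distance bins estimate the intercept well.

## Sweep calling

For a focal group scanned against a background group,
`window_contrast()` emits per-window F~ST~ and
`log2(π_background/π_focal)`, oriented so that diversity loss in the focal
group scores positive. Windows with zero background π are uninformative and
excluded; zero focal π with positive background π gets a finite cap
(default 10) so region peak statistics stay finite.

`call_sweep_regions()` flags windows exceeding **both** `F_ST > 0.45` and
`log2 ratio > 2.5` (the printed criteria of crop sweep scans; both
inequalities strict), or, in `mode = "quantile"`, the empirical top 5% of
both statistics — provided because "a 5% cutoff" can also be read as an
outlier definition. Flagged windows within `merge_gap` windows (default 1)
merge into regions; genes overlap regions by ≥ 1 bp. High/low-trait
accession groups use strict thresholds (defaults > 6 and < 1 mg/g on
BLUPs) and reuse the same scan machinery.

## BLUP phenotypes

Multi-environment trait values are combined by
`value ~ environment + (1 | accession)` fitted by REML in lme4 (the
standard tool for exactly this model). The reported value is the population
mean (intercept plus average environment effect) plus the accession BLUP.
For a balanced design with `r` environments the BLUP shrinks the
env-adjusted accession deviation by `σ_a²/(σ_a² + σ_e²/r)` — the test
suite verifies this closed form. A single-environment table falls back to
the raw values with a warning.

## Mixed-model association

**Kinship** is the standardized (VanRaden) GRM `K = ZZᵀ/m` with
`z = (x − 2p)/√(2p(1−p))` and per-site mean imputation of missing dosages.
It is PSD by construction, its diagonal averages ≈ 1, and its off-diagonals
for unrelated samples concentrate at `−1/(n−1)` (a consequence of
estimating `p` from the sample itself). The same eigendecomposition drives
the PCA helper. An IBS kinship is a reasonable alternative but offers no
PSD guarantee and no PCA reuse, so the GRM is the default and only built-in.

**Null model.** `y = Xβ + u + ε`, `u ~ (0, σ_g²K)`, `ε ~ (0, σ_e²I)`.
With `K = UΛUᵀ` computed once, the restricted likelihood is profiled over
`δ = σ_e²/σ_g²` on a 100-point grid of `log₁₀δ ∈ [−5, 5]` with
golden-section refinement (tolerance 10⁻⁶). Hitting a grid boundary raises
a warning — with `K = I` (or a pure-noise trait) only `σ_g²(1+δ)` is
identifiable and the fit degenerates gracefully to ordinary least squares.
No principal components are included as covariates by default: the kinship
term absorbs the structure, which is the convention of the EMMAX family;
covariates can be supplied.

**Scan.** The null covariance `σ_g²K + σ_e²I` is held fixed (the EMMAX
approximation); each SNP is tested by generalized least squares through the
cached rotation, with a Wald t on `n − rank(X)` df and a per-marker
residual scale. The per-marker scale makes the `K = I` case agree with
per-SNP `lm()` to 10⁻⁸, and the test suite checks Spearman ρ > 0.99 against
an exact per-SNP REML oracle implemented independently by direct matrix
inversion. Collinear SNPs get `p = 1` with a flag.

Significant loci use strict `−log₁₀p > 6`; significant SNPs within 89 kb
chain into one locus represented by its peak SNP, and candidate genes are
collected in the ±89 kb window around the peak — one radius for both so
locus counting and gene extraction stay consistent.

A calibration note: with very small marker panels (under ~10³ markers for
n = 400) every tested marker is a substantial part of `K` itself and the
scan visibly overcorrects (λ ≈ 0.75 at 800 markers in our simulations) —
textbook proximal contamination. At realistic panel sizes (≥ ~4000
markers) λ sits in [0.9, 1.1] under polygenic nulls. The package does not
implement leave-one-chromosome-out kinship; for real multi-chromosome data
that is the standard remedy if contamination is a concern.

## Allele effects

At a locus, homozygous REF and ALT carriers form the allele groups;
heterozygotes are excluded by default because the intended panels are
selfing and multi-generation inbred (an `own_group` policy exists).
Welch's unequal-variance t-test is the default — the robust choice when
group sizes are as lopsided as favorable-allele splits usually are — with
pooled-variance Student behind a flag. The superior allele is the
higher-mean group's allele (direction configurable), flagged significant at
p < 0.05; exact mean ties return `NA`.

## The synthetic-data generator

The generator exists so every stage can be tested against known truth; its
defaults are the study conditions of a sesame-scale panel.

**Structure.** Site ancestral frequencies are uniform on [0.05, 0.95] — a
deliberately non-neutral, filter-safe law that keeps simulated sites away
from the MAF boundary so filters do not silently change the truth.
Subpopulation frequencies follow Balding–Nichols
`Beta(p(1−F)/F, (1−p)(1−F)/F)`, chosen over coalescent simulation because
the truth (per-site expectations, F itself) is closed-form: the
Weir–Cockerham estimate between two populations at divergence `F` recovers
`F`, which is what the acceptance benchmarks exercise at the published
values 0.068/0.156/0.159 with group sizes 257/92, 61/257 and 61/92.
Genotypes are binomial (Hardy–Weinberg within population) — adequate for
dosage-based statistics even though real selfers are more homozygous.
Defaults of 2% missing calls and Poisson(25) depths mirror a ~25× panel
and exercise the filters. Diversity calibration inverts
`E[2p(1−p)] = 0.365` for the uniform law to choose the SNP density that
yields a target per-bp π (1.62/1.07/1.09 × 10⁻³ in the benchmarks, 5 Mb
chromosome, ≥ 500 windows).

**Sweeps** are planted by frequency distortion, not trajectory simulation:
within the interval the focal population's frequency moves a fraction
`intensity` of the way to a boundary, and focal genotypes are redrawn. The
direction policy matters more than intuition suggests. Always moving to the
*nearer* boundary (the minimal distortion) reduces focal diversity but
caps the achievable Weir–Cockerham F~ST~ near 0.40 even at complete
fixation, because the focal group fixes the allele the background already
favours — under that policy no sweep would ever satisfy the joint
0.45/2.5 criteria. The default is therefore a hitchhiking-style policy:
the allele fixes with probability equal to its current frequency, which is
the marginal frequency effect of one haplotype sweeping, and yields jointly
elevated F~ST~ and π-ratio. Even so, the two criteria are only jointly
cleared reliably for near-complete sweeps (intensity ≳ 0.97 against an
F = 0.05 background in our measurements); partial sweeps at intensity 0.9
sit near F~ST~ ≈ 0.43 and log₂ ratio ≈ 2.4 and are mostly missed — a
genuine property of the thresholds, which the test suite records rather
than hides. The false-flag rate on neutral windows is far below 0.1%.

**LD** comes from a founder-copying model: haplotypes copy from a pool of
founders, switching founders between adjacent sites with probability
`1−(1−r)^d`. Mean r² then decays with distance at a scale set by `r` and
the pool size; the truth curve for tests is measured on a 10×-sample
simulation of the same process. **Neutral SFS** genotypes draw each site's
derived-allele count with probability ∝ 1/i, under which π-based and
S-based θ estimators are equal in expectation — the Tajima's D null.
**Traits** are `y_ij = μ + env_j + g_i + ε_ij` with `g` the dosage-weighted
sum of causal effects and `ε` scaled so a chosen single-environment
heritability holds; defaults (μ = 3 mg/g, effects ~1 mg/g, six
environments) put phenotypes on the 0.06–10.65 mg/g scale of seed lignan
content. `h² = 0` would make the noise infinite, so effects are ignored in
the noise calibration with a warning.

Everything is deterministic given the config seed; sweeps and fixture
writing derive fixed substreams from it.

**What the generator does not emulate.** Balding–Nichols sites are
unlinked, so the structure generator produces no background LD (LD tests
use the copying model instead) and no genealogical correlation within
windows; sweeps distort frequencies without creating the haplotype
signature real sweeps leave; InDels, multi-allelic sites and genotyping
error beyond random missingness are absent. Passing tests therefore
validate the estimators and the pipeline plumbing, not robustness to every
artifact of real data.

## Problem sizes and numerics

The test suite runs at desk scale by design: 20,000-SNP genomes for
F~ST~ recovery, 5 Mb / ≥ 500 windows for π recovery, 100 seeded replicates
for the sweep operating characteristics, 20 and 50 replicates for GWAS
calibration and power at n = 400, and 1000 windows for the Tajima null.
Numerical conventions: δ-grid bounds [10⁻⁵, 10⁵] with boundary warnings;
PSD tolerance −10⁻⁶ relative on K's spectrum; the log₂ π-ratio cap at 10;
strict inequalities wherever a printed threshold is strict; ratio-of-sums
accumulators skip undefined sites rather than zero-filling them. The
pipeline writes a manifest (parameter set, input and output MD5 hashes,
seed, package version) and reruns byte-identically.

## Known limitations

Single-trait, single-locus association only; no permutation thresholds; no
haplotype statistics (iHS/XP-EHH); multi-allelic sites are excluded rather
than decomposed; BCF/tabix and phased data are out of scope. The BLUP
model assumes one value per accession × environment; replicated plots
within an environment should be pre-averaged.
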