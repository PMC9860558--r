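# popgenscan

Population-genomic scans, mixed-model GWAS and selective-sweep detection for
crop resequencing panels, with a seeded synthetic-data generator so the whole
pipeline is testable against known truth.

`popgenscan` targets the standard analysis arc of a diversity panel of a
selfing crop such as sesame: hundreds of resequenced accessions, a few
million SNPs, subpopulations shaped by geography, and a quantitative seed
trait (e.g. sesamin content, mg/g) measured in several environments. It
implements, as tidyverse-style R functions over a compact genotype container:

- **Site filtering** of VCF genotypes (per-genotype depth masking, minor
  allele frequency, missing rate — defaults `DP >= 8`, `MAF >= 0.05`,
  missing `<= 0.2`).
- **SNP annotation**: intergenic / upstream / downstream / intronic /
  splicing / exonic classes with exonic-first precedence, codon-level coding
  effects (synonymous, nonsynonymous, stop gain/loss) on either strand, and
  Ts/Tv and ns/s summary ratios.
- **Windowed diversity and differentiation** in 10 kb nonoverlapping
  windows: nucleotide diversity π (per-site unbiased heterozygosity
  `2p̂(1−p̂)·m/(m−1)` summed over SNPs and divided by window length),
  Watterson's θ, Tajima's D (complete-case haplotypes, the 1989
  normalization), and Weir–Cockerham (1984) F<sub>ST</sub> from the
  per-site variance components `a`, `b`, `c` combined as
  `Σa / Σ(a+b+c)` (ratio of sums; a mean-of-ratios mode is available).
- **LD decay**: genotype r² for all intra-chromosomal pairs within 500 kb,
  binned by distance, median-smoothed, with the half-decay distance (the
  smallest distance where the smoothed curve falls to half its maximum,
  linearly interpolated).
- **Selective-sweep calling** on joint criteria
  `F_ST > 0.45` **and** `log2(π_background / π_focal) > 2.5` per window
  (an empirical top-5% quantile mode is also provided), merging of flagged
  windows into regions, gene overlap, and cross-population intersection of
  selected gene sets.
- **Multi-environment BLUP** phenotypes via
  `value ~ environment + (1 | accession)` (lme4 REML).
- **EMMAX-style mixed-model GWAS**: standardized (VanRaden) kinship `K`,
  spectral REML of the null `y = Xβ + u + ε`, `u ~ (0, σ_g²K)` over
  `δ = σ_e²/σ_g²`, then per-SNP generalized least squares with the null
  covariance held fixed; Wald t tests, genomic-inflation λ, significant
  loci at `−log10 p > 6` collapsed within ±89 kb, candidate genes in the
  ±89 kb LD window.
- **Favorable-allele analysis**: phenotype means by homozygous allele class
  (heterozygotes excluded by default — the panel is selfing), Welch's
  t-test, superior-allele call.
- **Synthetic data with truth tables**: Balding–Nichols population
  structure (`p_pop ~ Beta(p(1−F)/F, (1−p)(1−F)/F)`), planted sweeps by
  hitchhiking-style frequency distortion, founder-copying haplotypes with
  distance-decaying LD, neutral-SFS genotypes for frequency-spectrum nulls,
  and multi-environment traits with planted causal SNPs — all deterministic
  given a seed, all writable to VCF/GFF3/FASTA/CSV fixtures.

## Worked example

Simulate a sesame-like panel (61 SC / 257 MC / 92 NC accessions, one 1 Mb
chromosome, a complete sweep planted in MC at 400–450 kb, a causal trait
SNP), then run the scan stages:

```r
library(popgenscan)

cfg <- sim_config(
  pop_sizes = c(SC = 61, MC = 257, NC = 92), F = c(0.02, 0.10, 0.10),
  chrom_lengths = c(chr1 = 1e6), snp_density = 3e-3,
  sweep_specs = list(list(pop = "MC", chrom = "chr1",
                          start = 400001, end = 450000, intensity = 1)),
  seed = 2026)
sim <- simulate_structured_genotypes(cfg)
gm  <- filter_sites(sim$gm)                       # 3000 -> 2794 sites (206 fail MAF)

ws  <- window_stats(gm, sim$groups, chrom_lengths = cfg$chrom_lengths)
ct  <- window_contrast(ws, focal = "MC", background = "SC")
call_sweep_regions(ct, focal = "MC", background = "SC")
#>   chrom  start    end n_windows peak_fst peak_log2_ratio focal background
#> 1 chr1  400000 450000         5    0.824              10 MC    SC
```

The five windows of the planted sweep — and only those — are flagged: MC
diversity collapses to 0 there (`log2` ratio capped at 10) while
F<sub>ST</sub> against SC jumps from a ~0.05–0.09 background to 0.68–0.82.

```r
tr   <- simulate_trait(gm, causal_ids = gm$sites$id[1500], effects = 1.2,
                       h2 = 0.4, n_envs = 6, seed = 7)
blup <- blup_phenotype(tr$phenotypes, "sesamin")
K    <- kinship_matrix(gm)
null <- fit_null_mlm(blup$blup[match(gm$samples, blup$accession)], K)
scan <- emmax_scan(gm, null)
significant_loci(scan)
#>   id          beta    se    minus_log10_p n_snps_in_locus
#> 1 chr1-539529 0.949 0.0265          127.                1
```

The single significant locus is exactly the planted causal SNP
(`chr1-539529`), with the effect estimate (0.95 mg/g per ALT allele) close
to the planted 1.2 scaled by shrinkage and imputation. Allele mining at the
locus then recovers the favorable allele:

```r
allele_effect(gm, "chr1-539529",
              tibble::tibble(accession = blup$accession, value = blup$blup))
#> <allele_effect> chr1-539529: p = 2.85e-06, superior allele = C (significant)
```

Carriers of the common "C" allele (n = 315) average 5.19 mg/g against
3.18 mg/g for the 5 minor-allele homozygotes.

`run_pipeline(pipeline_config(...))` chains every stage (filter → annotate →
window stats → LD → sweeps → BLUP → trait-extreme divergence → GWAS →
allele effects) from files on disk, writes each table as TSV and emits a
manifest of input/output hashes; reruns with the same seed are
byte-identical.

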