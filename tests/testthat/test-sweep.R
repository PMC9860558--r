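make_stats <- function(pi_f, pi_b, fst) {
  n <- length(pi_f)
  tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1) * 10000,
                 end = seq_len(n) * 10000, n_snps = 20,
                 pi_focal = pi_f, pi_bg = pi_b, fst_focal_bg = fst)
}

test_that("window_contrast orients the pi ratio and caps zero focal diversity", {
  st <- make_stats(pi_f = c(0.1e-3, 0.8e-3, 0), pi_b = c(0.8e-3, 0.8e-3, 0.8e-3),
                   fst = c(0.5, 0.1, 0.6))
  ct <- window_contrast(st, "focal", "bg")
  expect_equal(ct$log2_pi_ratio, c(3, 0, 10))
  expect_equal(ct$capped, c(FALSE, FALSE, TRUE))
  # zero-background windows are excluded entirely
  st0 <- make_stats(0.1e-3, 0, 0.5)
  expect_equal(nrow(window_contrast(st0, "focal", "bg")), 0)
  expect_error(window_contrast(st, "focal", "nope"), "lacks columns")
})

test_that("both criteria are required and merging respects the gap", {
  ct <- tibble::tibble(
    chrom = "chr1", start = (0:5) * 10000, end = (1:6) * 10000, n_snps = 20,
    fst = c(0.46, 0.50, 0.10, 0.60, 0.62, 0.61),
    log2_pi_ratio = c(2.4, 3.0, 3.0, 2.6, 2.7, 2.8), capped = FALSE
  )
  # window 1 fails the ratio, window 3 fails fst; windows 2 and 4-6 pass
  reg <- call_sweep_regions(ct, merge_gap = 0)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$n_windows, c(1L, 3L))
  expect_equal(reg$start, c(10000, 30000))
  # a one-window gap merges across the failed window
  reg2 <- call_sweep_regions(ct, merge_gap = 1)
  expect_equal(nrow(reg2), 1)
  expect_equal(reg2$peak_fst, 0.62)
  # empty result is a typed empty tibble
  reg0 <- call_sweep_regions(ct, fst_min = 0.99)
  expect_equal(nrow(reg0), 0)
})

test_that("raising either threshold never increases the flagged window count", {
  set.seed(12)
  ct <- tibble::tibble(
    chrom = "chr1", start = (0:199) * 10000, end = (1:200) * 10000, n_snps = 20,
    fst = runif(200, 0, 0.8), log2_pi_ratio = runif(200, -1, 4), capped = FALSE
  )
  count <- function(f, r) sum(call_sweep_regions(ct, fst_min = f, ratio_min = r,
                                                 merge_gap = 0)$n_windows)
  for (f in c(0.2, 0.45, 0.6)) {
    expect_true(count(f, 2.5) >= count(f + 0.1, 2.5))
    expect_true(count(f, 2.0) >= count(f, 2.6))
  }
})

test_that("quantile mode flags the joint upper tail", {
  set.seed(13)
  ct <- tibble::tibble(
    chrom = "chr1", start = (0:499) * 10000, end = (1:500) * 10000, n_snps = 20,
    fst = rnorm(500, 0.1, 0.05), log2_pi_ratio = rnorm(500, 0, 1), capped = FALSE
  )
  reg <- call_sweep_regions(ct, mode = "quantile", quantile_cut = 0.05, merge_gap = 0)
  expect_lte(sum(reg$n_windows), 0.05 * 500)
})

test_that("gene overlap uses >= 1 bp and the intersection is exact", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    start = c(15000, 9000, 20001), end = c(16000, 9999, 21000),
    exons = list(tibble::tibble(start = 1, end = 1)),
    cds = list(tibble::tibble(start = 1, end = 1))
  )
  regions <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000)
  gr <- genes_in_regions(regions, genes)
  # g2 ends 1 bp before the region's first base (10001); g3 starts 1 bp after
  expect_equal(gr$genes[[1]], "g1")
  genes2 <- dplyr::mutate(genes, end = c(16000, 10001, 21000))
  expect_setequal(genes_in_regions(regions, genes2)$genes[[1]], c("g1", "g2"))
  expect_equal(common_selected_genes(list(c("a", "b", "c"), c("b", "c", "d"))),
               c("b", "c"))
  expect_equal(common_selected_genes(list("a", "b")), character(0))
})

test_that("trait extremes split with strict inequalities", {
  v <- c(a1 = 7.1, a2 = 6.0, a3 = 0.5, a4 = 3.0)
  expect_warning(sp <- trait_group_split(v), "smaller than")
  expect_equal(sp$high, "a1")   # 6.0 excluded by strict >
  expect_equal(sp$low, "a3")
  expect_warning(trait_group_split(c(a = 2, b = 3)), "empty")
})

test_that("a planted sweep is recovered as one region with focal diversity lost", {
  cfg <- sim_config(pop_sizes = c(bg = 50, focal = 50), F = 0.05,
                    chrom_lengths = c(chr1 = 5e5), snp_density = 5e-3,
                    sweep_specs = list(list(pop = "focal", chrom = "chr1",
                                            start = 200001, end = 250000,
                                            intensity = 1)),
                    missing_rate = 0.02, seed = 3)
  sim <- simulate_structured_genotypes(cfg)
  ws <- window_stats(sim$gm, sim$groups, chrom_lengths = cfg$chrom_lengths,
                     tajima = FALSE)
  ct <- window_contrast(ws, "focal", "bg")
  reg <- call_sweep_regions(ct, focal = "focal", background = "bg")
  expect_equal(nrow(reg), 1)
  expect_gte(reg$n_windows, 3)
  expect_lte(reg$start, 220000)
  perf <- sweep_performance(ct, reg, sim$truth$sweeps)
  expect_gte(perf$recall, 0.6)
  expect_equal(perf$n_false_flags, 0)
})

test_that("a large-effect causal site drives the high/low-trait divergence peak", {
  cfg <- sim_config(pop_sizes = c(pop = 200), F = 0,
                    chrom_lengths = c(chr1 = 2e5), snp_density = 2e-3,
                    missing_rate = 0, depth_mean = NULL, seed = 71)
  sim <- simulate_structured_genotypes(cfg)
  mid <- which(abs(sim$gm$sites$pos - 1e5) < 2e4)
  causal <- sim$gm$sites$id[mid[which.min(abs(alt_freq(sim$gm)[mid] - 0.5))]]
  tr <- simulate_trait(sim$gm, causal, effects = 3, h2 = 0.95, n_envs = 1,
                       mu = 0.5, env_effects = 0, seed = 72)
  vals <- stats::setNames(tr$phenotypes$value, tr$phenotypes$accession)
  sp <- trait_group_split(vals, high_min = 6, low_max = 1)
  expect_gt(length(sp$high), 10)
  expect_gt(length(sp$low), 10)
  hl <- tibble::tibble(accession = c(sp$high, sp$low),
                       group = rep(c("HS", "LS"), c(length(sp$high), length(sp$low))))
  gm_hl <- subset_geno(sim$gm, samples = hl$accession)
  ws <- window_stats(gm_hl, hl, chrom_lengths = cfg$chrom_lengths, tajima = FALSE)
  peak <- ws[which.max(ws$fst_HS_LS), ]
  causal_pos <- sim$gm$sites$pos[sim$gm$sites$id == causal]
  expect_true(causal_pos > peak$start && causal_pos <= peak$end)
})
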