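test_that("simulation is deterministic in the seed and respects the dosage domain", {
  cfg <- sim_config(pop_sizes = c(a = 20, b = 20), F = 0.1,
                    chrom_lengths = c(chr1 = 2e5), snp_density = 1e-3, seed = 5)
  s1 <- simulate_structured_genotypes(cfg)
  s2 <- simulate_structured_genotypes(cfg)
  expect_identical(s1$gm$dosage, s2$gm$dosage)
  expect_identical(s1$truth$pop_freq, s2$truth$pop_freq)
  expect_true(all(s1$gm$dosage %in% c(0L, 1L, 2L) | is.na(s1$gm$dosage)))
  s3 <- simulate_structured_genotypes(sim_config(pop_sizes = c(a = 20, b = 20),
                                                 F = 0.1, chrom_lengths = c(chr1 = 2e5),
                                                 snp_density = 1e-3, seed = 6))
  expect_false(identical(s1$gm$dosage, s3$gm$dosage))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(pop_sizes = c(a = 1)), "2 diploid")
  expect_error(sim_config(F = 1), "\\[0, 1\\)")
  expect_error(sim_config(F = -0.1), "\\[0, 1\\)")
  expect_error(sim_config(sweep_specs = list(
    list(pop = "SC", chrom = "chr1", start = 1, end = 2e6, intensity = 0.5)
  )), "bounds")
  expect_error(sim_config(sweep_specs = list(
    list(pop = "SC", chrom = "chr1", start = 1, end = 1e4, intensity = 2)
  )), "intensity")
})

test_that("sample allele frequencies converge to the truth table (LLN)", {
  cfg <- sim_config(pop_sizes = c(a = 10000), F = 0.2,
                    chrom_lengths = c(chr1 = 5e4), snp_density = 1e-3,
                    missing_rate = 0, depth_mean = NULL, seed = 21)
  sim <- simulate_structured_genotypes(cfg)
  f_hat <- alt_freq(sim$gm)
  expect_lt(max(abs(f_hat - sim$truth$pop_freq[, "a"])), 0.02)
})

test_that("F = 0 gives no differentiation and Balding-Nichols recovers F", {
  cfg0 <- sim_config(pop_sizes = c(a = 60, b = 60), F = 0,
                     chrom_lengths = c(chr1 = 2e6), snp_density = 5e-3,
                     missing_rate = 0, depth_mean = NULL, seed = 31)
  sim0 <- simulate_structured_genotypes(cfg0)
  expect_identical(sim0$truth$pop_freq[, "a"], sim0$truth$pop_freq[, "b"])
  fst0 <- wc_fst(sim0$gm, sim0$groups, c("a", "b"))
  expect_lt(abs(fst0), 0.01)

  ests <- vapply(1:20, function(r) {
    cfg <- sim_config(pop_sizes = c(a = 50, b = 50), F = 0.2,
                      chrom_lengths = c(chr1 = 1e6), snp_density = 2e-3,
                      missing_rate = 0, depth_mean = NULL, seed = 100 + r)
    sim <- simulate_structured_genotypes(cfg)
    wc_fst(sim$gm, sim$groups, c("a", "b"))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.2) / 0.2, 0.05)
})

test_that("plant_sweep fixes the focal group at full intensity and is a no-op at zero", {
  cfg <- sim_config(pop_sizes = c(bg = 40, focal = 40), F = 0.05,
                    chrom_lengths = c(chr1 = 1e5), snp_density = 3e-3,
                    missing_rate = 0, depth_mean = NULL, seed = 41)
  sim <- simulate_structured_genotypes(cfg)
  sw <- list(pop = "focal", chrom = "chr1", start = 30001, end = 60000, intensity = 1)
  swept <- plant_sweep(sim, sw)
  idx <- which(swept$gm$sites$pos >= 30001 & swept$gm$sites$pos <= 60000)
  focal_rows <- which(swept$groups$group == "focal")
  dos <- swept$gm$dosage[focal_rows, idx, drop = FALSE]
  expect_true(all(apply(dos, 2, function(x) length(unique(x)) == 1)))
  expect_equal(window_pi(subset_geno(swept$gm, samples = swept$gm$samples[focal_rows]),
                         list(chrom = "chr1", start = 40000, end = 50000)), 0)
  same <- plant_sweep(sim, modifyList(sw, list(intensity = 0)))
  expect_identical(same$gm$dosage, sim$gm$dosage)
  expect_warning(
    plant_sweep(sim, list(pop = "focal", chrom = "chr1", start = 1,
                          end = 5000, intensity = 0.5)),
    "shorter than one"
  )
})

test_that("trait simulation is exact when noiseless and anchors the mg/g scale", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L, 0L, 2L, 1L), 3, 2))
  tr <- simulate_trait(gm, causal_ids = gm$sites$id[1], effects = 2, h2 = 1,
                       n_envs = 1, mu = 3, env_effects = 0.5, seed = 9)
  expect_equal(tr$phenotypes$value,
               3 + 0.5 + 2 * c(0, 1, 2), tolerance = 1e-12)
  expect_warning(
    simulate_trait(gm, gm$sites$id[1], effects = 2, h2 = 0, n_envs = 2, seed = 9),
    "noise calibration"
  )
})

test_that("fixtures round-trip through the readers and refuse to clobber", {
  cfg <- sim_config(pop_sizes = c(a = 15, b = 15), F = 0.1,
                    chrom_lengths = c(chr1 = 6e4), snp_density = 1e-3,
                    sweep_specs = list(list(pop = "b", chrom = "chr1",
                                            start = 20001, end = 40000,
                                            intensity = 1)),
                    seed = 51)
  sim <- simulate_structured_genotypes(cfg)
  tr <- simulate_trait(sim$gm, sim$gm$sites$id[3], effects = 1, h2 = 0.8,
                       n_envs = 3, seed = 52)
  out <- withr::local_tempdir()
  paths <- write_fixtures(sim, out, phenotypes = tr$phenotypes, force = TRUE)
  gm2 <- read_vcf(paths$vcf)
  expect_identical(unname(gm2$dosage), unname(sim$gm$dosage))
  expect_equal(gm2$sites$pos, sim$gm$sites$pos)
  expect_equal(gm2$sites$ref, sim$gm$sites$ref)
  genes <- read_gff(paths$gff)
  expect_true(all(c("gene_id", "exons", "cds") %in% names(genes)))
  ref <- read_fasta(paths$fasta)
  expect_silent(check_reference(gm2, ref))
  pt <- read_phenotypes(paths$phenotypes)
  expect_equal(nrow(pt), nrow(tr$phenotypes))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(nrow(truth$sweeps), 1)
  expect_equal(truth$sweeps$start, 20001)
  expect_error(write_fixtures(sim, out), "force")
})

test_that("neutral-SFS generator has near-unbiased pi vs Watterson balance", {
  gm <- simulate_sfs_genotypes(40, 2000, chrom_length = 1e6, seed = 61)
  n <- 80
  k <- colSums(gm$dosage)
  pi_hat <- sum(k * (n - k)) / (n * (n - 1) / 2)
  theta_w <- sum(k > 0 & k < n) / sum(1 / seq_len(n - 1))
  expect_lt(abs(pi_hat - theta_w) / theta_w, 0.05)
})
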