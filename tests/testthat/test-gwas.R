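sim_panel <- function(n_per_pop = c(a = 70, b = 70, c = 60), F = 0.1,
                      m_bp = 5e5, density = 2e-3, seed = 1) {
  cfg <- sim_config(pop_sizes = n_per_pop, F = F,
                    chrom_lengths = c(chr1 = m_bp), snp_density = density,
                    missing_rate = 0, depth_mean = NULL, seed = seed)
  sim <- simulate_structured_genotypes(cfg)
  sim$gm <- filter_sites(sim$gm, depth_min = 0)
  sim
}

test_that("kinship of a duplicated sample equals its diagonal and has mean diag 1", {
  sim <- sim_panel(c(a = 30), F = 0, seed = 2)
  gm <- sim$gm
  dup <- gm$dosage
  dup[2, ] <- dup[1, ]
  gm2 <- geno_matrix(dup, gm$sites, samples = gm$samples)
  gm2 <- filter_sites(gm2, depth_min = 0)
  K <- kinship_matrix(gm2)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
  # unrelated individuals: off-diagonals concentrate at the finite-sample
  # centering value -1/(n-1) with spread shrinking in the site count
  K0 <- kinship_matrix(sim$gm)
  off <- K0[upper.tri(K0)]
  n <- nrow(K0)
  expect_lt(abs(mean(off) + 1 / (n - 1)), 0.01)
  expect_lt(sd(off), 0.1)
  expect_gt(min(eigen(unclass(K0), symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("kinship and PCA expose the simulated population structure", {
  sim <- sim_panel(seed = 3)
  K <- kinship_matrix(sim$gm)
  pcs <- pca_kinship(K, 2)
  grp <- sim$groups$group[match(pcs$accession, sim$groups$accession)]
  # nearest-centroid assignment on PC1-PC2 recovers the three groups
  cent <- stats::aggregate(cbind(PC1, PC2) ~ grp, data = cbind(pcs, grp = grp), mean)
  d <- as.matrix(dist(rbind(as.matrix(cent[, 2:3]), as.matrix(pcs[, c("PC1", "PC2")]))))
  assign <- cent$grp[apply(d[-(1:3), 1:3], 1, which.min)]
  expect_gt(mean(assign == grp), 0.95)
  # leading eigenvector of K separates populations in a two-pop panel
  sim2 <- sim_panel(c(a = 40, b = 40), F = 0.15, seed = 4)
  e1 <- eigen(unclass(kinship_matrix(sim2$gm)), symmetric = TRUE)$vectors[, 1]
  side <- e1 > 0
  grp2 <- sim2$groups$group
  expect_true(mean(side == (grp2 == "a")) > 0.95 ||
                mean(side == (grp2 == "b")) > 0.95)
  expect_error(pca_kinship(K, nrow(K) + 1), "exceeds")
})

test_that("null model recovers variance components and flags degenerate cases", {
  sim <- sim_panel(c(a = 60, b = 60), F = 0.15, m_bp = 1e6, seed = 5)
  K <- kinship_matrix(sim$gm)
  # y = u + e with u ~ (0, K): heritability should be near 0.5
  h2 <- vapply(1:10, function(r) {
    set.seed(300 + r)
    ev <- eigen(unclass(K), symmetric = TRUE)
    u <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(nrow(K)))
    y <- drop(u) + rnorm(nrow(K))
    # the profile likelihood is flat at this n; occasional boundary fits are
    # expected and handled by taking the median below
    suppressWarnings(fit_null_mlm(y, K)$heritability)
  }, numeric(1))
  expect_lt(abs(median(h2) - 0.5), 0.15)
  # pure-noise trait pushes the genetic fraction toward zero
  h2_null <- vapply(1:10, function(r) {
    set.seed(400 + r)
    suppressWarnings(fit_null_mlm(rnorm(nrow(K)), K)$heritability)
  }, numeric(1))
  expect_lt(median(h2_null), 0.1)
  expect_error(fit_null_mlm(rep(1, nrow(K)), K), "constant")
})

test_that("with identity kinship the scan reduces to per-SNP ordinary regression", {
  sim <- sim_panel(c(a = 80), F = 0, m_bp = 2e5, seed = 6)
  n <- length(sim$gm$samples)
  K <- diag(n)
  dimnames(K) <- list(sim$gm$samples, sim$gm$samples)
  class(K) <- c("kinship_matrix", class(K))
  set.seed(7)
  y <- rnorm(n)
  null <- suppressWarnings(fit_null_mlm(y, K))
  sc <- emmax_scan(sim$gm, null)
  X <- sim$gm$dosage
  p_ols <- vapply(seq_len(ncol(X)), function(j) {
    summary(stats::lm(y ~ X[, j]))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(sc$p_value, p_ols, tolerance = 1e-8)
})

test_that("EMMAX p-values track exact per-SNP REML (oracle) with rho > 0.99", {
  sim <- sim_panel(c(a = 50, b = 50), F = 0.1, m_bp = 1e5, seed = 8)
  gm <- subset_geno(sim$gm, sites = seq_len(min(200, ncol(sim$gm$dosage))))
  K <- kinship_matrix(sim$gm)
  set.seed(9)
  ev <- eigen(unclass(K), symmetric = TRUE)
  u <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(nrow(K)))
  y <- drop(u) + rnorm(nrow(K)) + 0.5 * impute_dosage_for_test(gm)[, 7]
  null <- fit_null_mlm(y, K)
  sc <- emmax_scan(gm, null)
  Kmat <- unclass(K)
  Xg <- impute_dosage_for_test(gm)
  p_oracle <- vapply(seq_len(ncol(Xg)), function(j) {
    oracle_reml_pvalue(y, cbind(1, Xg[, j]), Kmat)
  }, numeric(1))
  expect_gt(cor(sc$p_value, p_oracle, method = "spearman"), 0.99)
})

test_that("mixed model calibrates structured nulls where naive regression inflates", {
  lams <- t(vapply(1:6, function(r) {
    sim <- sim_panel(c(a = 70, b = 70, c = 60), F = 0.12, m_bp = 4e5, seed = 500 + r)
    X <- impute_dosage_for_test(sim$gm)
    m <- ncol(X)
    set.seed(600 + r)
    causal <- sample(m, 150)
    g <- drop(scale(X[, causal]) %*% rnorm(150)) / sqrt(150)
    y <- g + rnorm(nrow(X), 0, sd(g))
    K <- kinship_matrix(sim$gm)
    null <- fit_null_mlm(y, K)
    test_sites <- setdiff(seq_len(m), causal)
    sc <- emmax_scan(subset_geno(sim$gm, sites = test_sites), null)
    c(emmax = genomic_inflation(sc),
      ols = genomic_inflation(ols_scan_pvalues(X[, test_sites], y)))
  }, c(emmax = 0, ols = 0)))
  expect_lt(abs(median(lams[, "emmax"]) - 1), 0.15)
  expect_gt(median(lams[, "ols"]), 1.2)
})

test_that("significant loci use a strict threshold and collapse within the LD window", {
  res <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(100000, 130000, 400000, 50000),
    id = paste0("s", 1:4),
    beta = 1, se = 0.1,
    p_value = c(1e-7, 1e-8, 1e-6, 1e-9),
    minus_log10_p = -log10(c(1e-7, 1e-8, 1e-6, 1e-9)),
    collinear = FALSE
  )
  loci <- significant_loci(res, threshold = 6, collapse_bp = 89000)
  # the exact 1e-6 site is NOT significant (strict >): 3 significant SNPs,
  # two of which (30 kb apart) collapse to one locus
  expect_equal(nrow(loci), 2)
  expect_equal(loci$id[loci$chrom == "chr1"], "s2")
  expect_equal(loci$n_snps_in_locus[loci$chrom == "chr1"], 2L)
})

test_that("candidate windows include 1-bp overlaps and can be empty", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
    start = c(1000, 300000), end = c(11000, 310000),
    exons = list(tibble::tibble(start = 1, end = 1)),
    cds = list(tibble::tibble(start = 1, end = 1))
  )
  locus <- list(chrom = "chr1", pos = 100000)
  cw <- candidate_window(locus, genes, half_width = 89000)
  expect_equal(cw$gene_id, "gA")   # gene ends exactly at pos - 89000
  expect_equal(nrow(candidate_window(list(chrom = "chr2", pos = 1e5), genes)), 0)
})

test_that("genomic inflation is 1 under the uniform null and detects deflation of p", {
  set.seed(10)
  p <- runif(20000)
  expect_lt(abs(genomic_inflation(p) - 1), 0.05)
  expect_gt(genomic_inflation(p / 2), 1.2)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})
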