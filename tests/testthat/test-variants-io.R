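make_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    "##contig=<ID=chr1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/0:20\t0/1:15\t1/1:30",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t./.:2\t0/0:25\t0/1:18",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT:DP\t0/0:20\t0/0:21\t0/1:22",
    "chr1\t400\t.\tG\tA,T\t.\tPASS\t.\tGT:DP\t0/0:20\t0/1:21\t0/2:22",
    "chr1\t500\t.\tT\tC\t.\tPASS\t.\tGT:DP\t1/1:9\t0/1:12\t0/0:28",
    "chr1\t600\t.\tG\tC\t.\tPASS\t.\tGT:DP\t0/0:14\t1/1:16\t0/1:11"
  )
  writeLines(lines, path)
  path
}

test_that("read_vcf keeps biallelic SNPs, converts GT to dosage and captures DP", {
  path <- make_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  expect_message(gm <- read_vcf(path), "excluded 2")
  expect_equal(ncol(gm$dosage), 4)   # InDel and triallelic records dropped
  expect_equal(gm$sites$pos, c(100L, 200L, 500L, 600L))
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(gm$dosage[, 2]), c(NA_integer_, 0L, 1L))
  expect_equal(unname(gm$depth[, 1]), c(20, 15, 30))
})

test_that("filter_sites applies MAF, missing-rate and depth rules", {
  # 25 samples; MAFs 0.5, 0.04, ~0.2, 0.5, 0.3 with missing 0, 0, 0.28, 0.08, 0
  n <- 25
  make_col <- function(maf, n_miss) {
    n_ok <- n - n_miss
    n_alt <- round(2 * n_ok * maf)
    d <- integer(n_ok)
    full <- n_alt %/% 2; rem <- n_alt %% 2
    if (full > 0) d[seq_len(full)] <- 2L
    if (rem) d[full + 1] <- 1L
    c(d, rep(NA_integer_, n_miss))
  }
  dos <- cbind(make_col(0.5, 0), make_col(0.04, 0), make_col(0.2, 7),
               make_col(0.5, 2), make_col(0.3, 0))
  gm <- toy_gm(dos)
  kept <- filter_sites(gm, maf_min = 0.05, missing_max = 0.2, depth_min = 0)
  expect_equal(kept$sites$pos, gm$sites$pos[c(1, 4, 5)])
  report <- attr(kept, "filter_report")
  expect_equal(report$n[report$criterion == "kept"], 3L)
  # idempotence
  again <- filter_sites(kept, maf_min = 0.05, missing_max = 0.2, depth_min = 0)
  expect_identical(again$dosage, kept$dosage)
  # depth masking: per-genotype depths below threshold become missing first
  depth <- matrix(30, n, 5); depth[1:6, 1] <- 2
  gm_dp <- geno_matrix(dos, gm$sites, samples = gm$samples, depth = depth)
  f <- filter_sites(gm_dp, maf_min = 0, missing_max = 1, depth_min = 8)
  expect_true(all(is.na(f$dosage[1:6, 1])))
  expect_warning(filter_sites(gm, maf_min = 0.6, missing_max = 0, depth_min = 0),
                 "all sites")
})

test_that("dosage mean equals twice the alt frequency on non-missing calls", {
  set.seed(2)
  dos <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20, 10)
  gm <- toy_gm(dos)
  f <- alt_freq(gm)
  expect_equal(2 * f, colMeans(gm$dosage, na.rm = TRUE), ignore_attr = TRUE)
})

test_that("VCF round-trip preserves genotypes, sites and depth", {
  set.seed(3)
  dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE, prob = c(4, 2, 3, 1)), 6, 10)
  depth <- matrix(rpois(60, 20), 6, 10)
  gm <- geno_matrix(dos, tibble::tibble(chrom = "chr2", pos = 1:10 * 50,
                                        ref = "T", alt = "A"),
                    samples = paste0("acc", 1:6), depth = depth)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)
  expect_identical(unname(gm2$dosage), unname(gm$dosage))
  expect_equal(unname(gm2$depth), unname(depth), ignore_attr = TRUE)
  expect_equal(gm2$samples, gm$samples)
})

test_that("gene models survive a GFF3 round-trip including minus strand", {
  fx <- fixture_annotation()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fx$genes, path)
  back <- read_gff(path)
  expect_setequal(back$gene_id, fx$genes$gene_id)
  for (g in fx$genes$gene_id) {
    a <- fx$genes[fx$genes$gene_id == g, ]
    b <- back[back$gene_id == g, ]
    expect_equal(b$strand, a$strand)
    expect_equal(b$cds[[1]]$start, a$cds[[1]]$start)
    expect_equal(b$exons[[1]]$end, a$exons[[1]]$end)
  }
})

test_that("phenotype and group readers validate their invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,environment,trait,value",
               "a1,env1,sesamin,2.5", "a1,env1,sesamin,2.6"), path)
  expect_error(read_phenotypes(path), "duplicate")
  writeLines(c("accession,environment,trait,value",
               "a1,env1,sesamin,2.5", "a1,env2,sesamin,2.6"), path)
  pt <- read_phenotypes(path)
  expect_equal(pt$value, c(2.5, 2.6))
  # TSV sniffing
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgroup", "a1\tSC", "a2\tMC"), path2)
  g <- read_groups(path2)
  expect_equal(g$group, c("SC", "MC"))
  writeLines(c("accession\tgroup", "a1\tSC", "a1\tMC"), path2)
  expect_error(read_groups(path2), "duplicate")
})

test_that("check_reference reports chromosome and allele mismatches", {
  fx <- fixture_annotation()
  gm <- toy_gm(matrix(0L, 2, 1), chrom = "chrX", pos = 5)
  expect_error(check_reference(gm, fx$ref), "chrX")
  base1 <- substr(as.character(fx$ref[["chr1"]]), 5, 5)
  wrong <- setdiff(c("A", "C", "G", "T"), base1)[1]
  gm2 <- toy_gm(matrix(0L, 2, 1), chrom = "chr1", pos = 5, ref = wrong)
  expect_error(check_reference(gm2, fx$ref), "mismatch")
})
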