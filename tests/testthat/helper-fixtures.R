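# Deterministic fixtures and independent oracles used across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# small genotype matrix with known dosages
toy_gm <- function(dosage, chrom = "chr1", pos = NULL, ref = NULL, alt = NULL) {
  m <- ncol(dosage)
  geno_matrix(
    dosage,
    tibble::tibble(
      chrom = chrom,
      pos = pos %||% (seq_len(m) * 100L),
      ref = ref %||% rep("A", m),
      alt = alt %||% rep("G", m)
    ),
    samples = paste0("s", seq_len(nrow(dosage)))
  )
}

# Two hand-built gene models with a reference whose CDS sequences are known.
# chr1 gene: plus strand, exons 51-80 and 91-110, CDS 56-79 + 91-102 (36 bp).
# chr2 gene: minus strand, single exon 121-180, CDS 131-166 (36 bp on the
# minus strand; the genomic segment holds its reverse complement).
CDS_PLUS <- "ATGACAGCTCATAAAGGGTTTCCCGAGGACTACTAA"
CDS_MINUS <- "ATGCAGGTCGATTGCCTGAAGCTGATCGTAGCGTGA"

fixture_annotation <- function() {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  set.seed(99)
  s1 <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  s1[56:79] <- strsplit(substr(CDS_PLUS, 1, 24), "")[[1]]
  s1[91:102] <- strsplit(substr(CDS_PLUS, 25, 36), "")[[1]]
  s2 <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  s2[131:166] <- strsplit(revcomp(CDS_MINUS), "")[[1]]
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(s1, collapse = ""),
                                    chr2 = paste(s2, collapse = "")))
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus"),
    chrom = c("chr1", "chr2"),
    strand = c("+", "-"),
    start = c(51, 121), end = c(110, 180),
    exons = list(tibble::tibble(start = c(51, 91), end = c(80, 110)),
                 tibble::tibble(start = 121, end = 180)),
    cds = list(tibble::tibble(start = c(56, 91), end = c(79, 102)),
               tibble::tibble(start = 131, end = 166))
  )
  list(genes = genes, ref = ref)
}

# oracle: mean pairwise haplotype difference at one site by enumeration
oracle_site_pi <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (length(d) < 2) return(NA_real_)
  hap <- unlist(lapply(d, function(x) switch(as.character(x),
                                             "0" = c(0L, 0L),
                                             "1" = c(0L, 1L),
                                             "2" = c(1L, 1L))))
  n <- length(hap)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) diffs <- diffs + as.integer(hap[i] != hap[j])
  }
  diffs / (n * (n - 1) / 2)
}

# oracle: coding effect by rebuilding the whole CDS, substituting the allele,
# and diffing the two translated proteins
oracle_coding_effect <- function(site, gene, ref) {
  cc <- gene$cds[[1]]
  cc <- cc[order(cc$start), , drop = FALSE]
  seqs <- as.character(Biostrings::extractAt(
    ref[[gene$chrom]], IRanges::IRanges(cc$start, cc$end)))
  asc <- paste(seqs, collapse = "")
  prior <- 0
  k <- which(site$pos >= cc$start & site$pos <= cc$end)
  if (k > 1) prior <- sum(cc$end[seq_len(k - 1)] - cc$start[seq_len(k - 1)] + 1)
  idx <- prior + site$pos - cc$start[k] + 1
  alt_asc <- asc
  substr(alt_asc, idx, idx) <- site$alt
  orient <- function(s) {
    if (gene$strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    else s
  }
  prot <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(orient(s)),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
  }
  p_ref <- prot(asc); p_alt <- prot(alt_asc)
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(d) == 0) return("synonymous")
  aa_ref <- substr(p_ref, d, d); aa_alt <- substr(p_alt, d, d)
  if (aa_alt == "*") "stop_gain" else if (aa_ref == "*") "stop_loss" else "nonsynonymous"
}

# oracle: exact single-marker REML mixed model by direct matrix algebra
# (no eigen-rotation shortcuts; independent of the package's spectral path)
oracle_reml_pvalue <- function(y, X, K) {
  n <- length(y)
  q <- ncol(X)
  nll <- function(log10_delta) {
    V <- K + diag(10^log10_delta, n)
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    B <- XtVi %*% X
    beta <- solve(B, XtVi %*% y)
    r <- y - X %*% beta
    rss <- drop(crossprod(r, Vi %*% r))
    s2 <- rss / (n - q)
    0.5 * ((n - q) * log(s2) + determinant(V, TRUE)$modulus[1] +
             determinant(B, TRUE)$modulus[1] + (n - q))
  }
  opt <- stats::optimize(nll, c(-5, 5))
  V <- K + diag(10^opt$minimum, n)
  Vi <- solve(V)
  B <- crossprod(X, Vi) %*% X
  beta <- solve(B, crossprod(X, Vi) %*% y)
  r <- y - X %*% beta
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - q)
  covb <- s2 * solve(B)
  tt <- beta[q] / sqrt(covb[q, q])
  2 * stats::pt(-abs(tt), n - q)
}

# per-SNP ordinary least squares p-values (naive scan, for inflation contrast)
ols_scan_pvalues <- function(X, y) {
  n <- length(y)
  apply(X, 2, function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    2 * stats::pt(-abs(tt), n - 2)
  })
}

impute_dosage_for_test <- function(gm) {
  X <- gm$dosage
  mode(X) <- "numeric"
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx) > 0) X[idx] <- cm[idx[, 2]]
  X
}
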