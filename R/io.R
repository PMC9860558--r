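#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.x file into a [geno_matrix()]. Only biallelic SNP records
#' are retained (single-base REF and ALT); multi-allelic and InDel records
#' are excluded with a logged count. GT is converted to ALT-allele dosage
#' (`./.` to missing); per-genotype DP is captured when present in FORMAT.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A [geno_matrix()]; the number of excluded records is attached as
#'   attribute `n_excluded`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF has no sample genotype columns")
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF records lack a GT FORMAT field")
  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("read_vcf: excluded %d multi-allelic or non-SNP record(s)", n_excluded))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  depth <- NULL
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    )
    depth <- t(dp)
  }
  ids <- fix[keep, "ID"]
  sites <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep]
  )
  if (!all(is.na(ids)) && !all(ids == ".")) {
    sites$id <- ifelse(is.na(ids) | ids == ".", paste0(sites$chrom, "-", sites$pos), ids)
  }
  gm <- geno_matrix(t(dos), sites, samples = colnames(gt), depth = depth)
  attr(gm, "n_excluded") <- n_excluded
  gm
}

#' Write a genotype matrix to VCF v4.2
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=popgenscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("##contig=<ID=", unique(gm$sites$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$dosage + 1L],
                   nrow(gm$dosage), ncol(gm$dosage))
  gt_str[is.na(gm$dosage)] <- "./."
  has_dp <- !is.null(gm$depth)
  if (has_dp) {
    dp <- gm$depth
    dp_str <- matrix(as.character(dp), nrow(dp), ncol(dp))
    dp_str[is.na(dp)] <- "."
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow(gt_str), ncol(gt_str))
  }
  body <- vapply(seq_len(nrow(gm$sites)), function(j) {
    paste(c(gm$sites$chrom[j], gm$sites$pos[j], gm$sites$id[j],
            gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", gt_str[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Apply the study's site filters to a genotype matrix
#'
#' Per-genotype depths below `depth_min` are masked to missing first (the
#' conservative per-genotype reading of a minimum-depth rule; a per-site-mean
#' mode is available), then sites failing the minor-allele-frequency or
#' missing-rate thresholds are dropped. MAF is computed on non-missing calls.
#'
#' @param gm a [geno_matrix()].
#' @param maf_min minimum minor allele frequency (kept when MAF >= threshold).
#' @param missing_max maximum per-site missing rate (kept when <= threshold).
#' @param depth_min minimum depth; ignored when the matrix has no depths.
#' @param depth_mode `"genotype"` masks individual calls below `depth_min`;
#'   `"site_mean"` drops whole sites whose mean depth is below it.
#' @return Filtered `geno_matrix` with attribute `filter_report`, a tibble of
#'   kept/dropped counts per criterion.
#' @export
filter_sites <- function(gm, maf_min = 0.05, missing_max = 0.2, depth_min = 8,
                         depth_mode = c("genotype", "site_mean")) {
  stopifnot(inherits(gm, "geno_matrix"))
  depth_mode <- match.arg(depth_mode)
  n0 <- nrow(gm$sites)
  drop_depth <- 0L
  if (!is.null(gm$depth) && depth_min > 0) {
    if (depth_mode == "genotype") {
      low <- !is.na(gm$depth) & gm$depth < depth_min
      gm$dosage[low] <- NA_integer_
    } else {
      mean_dp <- colMeans(gm$depth, na.rm = TRUE)
      keep <- mean_dp >= depth_min
      drop_depth <- sum(!keep)
      gm <- subset_geno(gm, sites = keep)
    }
  }
  miss <- colMeans(is.na(gm$dosage))
  f <- alt_freq(gm)
  maf <- pmin(f, 1 - f)
  fail_miss <- miss > missing_max
  fail_maf <- is.na(maf) | maf < maf_min
  keep <- !fail_miss & !fail_maf
  report <- tibble::tibble(
    criterion = c("input", "depth_site_mean", "missing_rate", "maf", "kept"),
    n = c(n0, drop_depth, sum(fail_miss), sum(fail_maf & !fail_miss), sum(keep))
  )
  if (!any(keep)) warning("all sites removed by filters")
  out <- subset_geno(gm, sites = keep)
  attr(out, "filter_report") <- report
  out
}

#' Read gene models from a GFF3 file
#'
#' Assembles one gene model per gene, selecting the transcript with the
#' longest total CDS as primary. Coordinates are 1-based inclusive as in the
#' file. Exons are stored sorted by genomic coordinate regardless of strand;
#' coding sequence for minus-strand genes is assembled by reverse complement
#' downstream.
#'
#' @param path GFF3 file path.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#'   and list-columns `exons`, `cds` (tibbles of `start`, `end`).
#' @export
read_gff <- function(path) {
  cols <- c("chrom", "source", "type", "start", "end", "score", "strand",
            "phase", "attributes")
  g <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         col.names = cols, stringsAsFactors = FALSE)
  get_attr <- function(x, key) {
    m <- regmatches(x, regexec(paste0("(^|;)", key, "=([^;]+)"), x))
    vapply(m, function(mm) if (length(mm) >= 3) mm[3] else NA_character_, character(1))
  }
  g$ID <- get_attr(g$attributes, "ID")
  g$Parent <- get_attr(g$attributes, "Parent")
  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  cdss <- g[g$type == "CDS", , drop = FALSE]
  orphan <- setdiff(cdss$Parent, c(mrnas$ID, genes$ID))
  if (length(orphan) > 0) {
    stop("CDS feature(s) without a parent gene/mRNA: ", paste(orphan, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tr <- mrnas[mrnas$Parent == gid, , drop = FALSE]
    parent_ids <- if (nrow(tr) > 0) tr$ID else gid
    cds_len <- vapply(parent_ids, function(tid) {
      cc <- cdss[cdss$Parent == tid, , drop = FALSE]
      sum(cc$end - cc$start + 1)
    }, numeric(1))
    best <- parent_ids[which.max(cds_len)]
    ex <- exons[exons$Parent == best, , drop = FALSE]
    cc <- cdss[cdss$Parent == best, , drop = FALSE]
    tibble::tibble(
      gene_id = gid, chrom = genes$chrom[i], strand = genes$strand[i],
      start = genes$start[i], end = genes$end[i],
      exons = list(tibble::tibble(start = sort(ex$start), end = ex$end[order(ex$start)])),
      cds = list(tibble::tibble(start = sort(cc$start), end = cc$end[order(cc$start)]))
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

#' Write gene models to GFF3
#'
#' @param genes gene-model tibble as from [read_gff()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ch <- genes$chrom[i]; st <- genes$strand[i]
    line <- function(type, s, e, phase, attrs) {
      paste(ch, "popgenscan", type, s, e, ".", st, phase, attrs, sep = "\t")
    }
    tid <- paste0(gid, ".t1")
    rows <- c(
      line("gene", genes$start[i], genes$end[i], ".", paste0("ID=", gid)),
      line("mRNA", genes$start[i], genes$end[i], ".",
           paste0("ID=", tid, ";Parent=", gid))
    )
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      rows <- c(rows, line("exon", ex$start[j], ex$end[j], ".",
                           paste0("ID=", tid, ".e", j, ";Parent=", tid)))
    }
    cc <- genes$cds[[i]]
    ord <- if (st == "-") order(-cc$start) else order(cc$start)
    cum <- 0
    phase <- integer(nrow(cc))
    for (j in ord) {
      phase[j] <- (3 - cum %% 3) %% 3
      cum <- cum + cc$end[j] - cc$start[j] + 1
    }
    for (j in seq_len(nrow(cc))) {
      rows <- c(rows, line("CDS", cc$start[j], cc$end[j], phase[j],
                           paste0("ID=", tid, ".c", j, ";Parent=", tid)))
    }
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Check that a reference covers the chromosomes and REF alleles of a panel
#'
#' @param gm a [geno_matrix()].
#' @param ref a `DNAStringSet` from [read_fasta()].
#' @param check_alleles also verify the REF base at every site.
#' @return Invisibly `TRUE`; errors listing offenders otherwise.
#' @export
check_reference <- function(gm, ref, check_alleles = TRUE) {
  missing_chr <- setdiff(unique(gm$sites$chrom), names(ref))
  if (length(missing_chr) > 0) {
    stop("chromosome(s) in genotypes absent from reference: ",
         paste(missing_chr, collapse = ", "))
  }
  if (check_alleles) {
    for (ch in unique(gm$sites$chrom)) {
      s <- gm$sites[gm$sites$chrom == ch, ]
      bases <- strsplit(as.character(Biostrings::extractAt(
        ref[[ch]], IRanges::IRanges(s$pos, s$pos))), "")
      got <- vapply(bases, `[`, character(1), 1)
      bad <- which(got != s$ref)
      if (length(bad) > 0) {
        stop("REF allele mismatch vs reference at ",
             paste(s$id[utils::head(bad, 5)], collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

read_table_sniffed <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Read a tidy phenotype table
#'
#' Expects columns `accession`, `environment`, `trait`, `value` (CSV or TSV,
#' sniffed). Duplicate `(accession, environment, trait)` records or
#' non-finite values are errors.
#'
#' @param path file path.
#' @return Tibble with the four columns.
#' @export
read_phenotypes <- function(path) {
  pt <- read_table_sniffed(path)
  need <- c("accession", "environment", "trait", "value")
  if (!all(need %in% names(pt))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  pt <- dplyr::select(pt, dplyr::all_of(need))
  if (any(!is.finite(pt$value))) stop("non-finite phenotype values")
  dup <- duplicated(pt[, c("accession", "environment", "trait")])
  if (any(dup)) {
    stop("duplicate (accession, environment, trait) record(s), first at row ",
         which(dup)[1])
  }
  pt
}

#' Read an accession-to-group assignment table
#'
#' @param path CSV/TSV with columns `accession`, `group`.
#' @return Tibble `accession`, `group`.
#' @export
read_groups <- function(path) {
  g <- read_table_sniffed(path)
  if (!all(c("accession", "group") %in% names(g))) {
    stop("groups table must have columns accession, group")
  }
  if (any(duplicated(g$accession))) stop("duplicate accession in groups table")
  dplyr::select(g, dplyr::all_of(c("accession", "group")))
}
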