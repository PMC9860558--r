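AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify SNPs by genomic context
#'
#' Assigns each site one region class with precedence
#' `exonic > splicing > intronic > upstream/downstream > intergenic`.
#' Splicing means within 2 bp of an exon-intron boundary on the intron side;
#' upstream/downstream are within `flank` bp of the gene span on the
#' strand-appropriate side; intergenic is the fall-through.
#'
#' @param sites tibble with `chrom`, `pos` (and optionally `id`).
#' @param genes gene-model tibble from [read_gff()].
#' @param flank upstream/downstream window, bp (default 1000).
#' @param splice_bp splice-region width inside the intron (default 2).
#' @param all_overlaps if `TRUE`, return every overlapping annotation rather
#'   than one class per SNP (debugging mode).
#' @return `sites` with `region_class` and `gene_id` columns (gene of the
#'   assigned feature; `NA` for intergenic).
#' @export
classify_region <- function(sites, genes, flank = 1000, splice_bp = 2,
                            all_overlaps = FALSE) {
  sites <- tibble::as_tibble(sites)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  feat <- list()
  add <- function(class, chrom, start, end, gene_id) {
    ok <- end >= start
    if (!any(ok)) return()
    feat[[length(feat) + 1]] <<- tibble::tibble(
      class = class, chrom = chrom[ok], start = pmax(1, start[ok]),
      end = end[ok], gene_id = gene_id[ok]
    )
  }
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    gid <- genes$gene_id[i]; ch <- genes$chrom[i]; st <- genes$strand[i]
    n_ex <- nrow(ex)
    add("exonic", rep(ch, n_ex), ex$start, ex$end, rep(gid, n_ex))
    if (n_ex > 1) {
      istart <- ex$end[-n_ex] + 1
      iend <- ex$start[-1] - 1
      ok <- iend >= istart
      if (any(ok)) {
        is_ <- istart[ok]; ie <- iend[ok]
        add("intronic", rep(ch, length(is_)), is_, ie, rep(gid, length(is_)))
        add("splicing", rep(ch, length(is_)), is_, pmin(ie, is_ + splice_bp - 1),
            rep(gid, length(is_)))
        add("splicing", rep(ch, length(ie)), pmax(is_, ie - splice_bp + 1), ie,
            rep(gid, length(ie)))
      }
    }
    up <- if (st == "-") c(genes$end[i] + 1, genes$end[i] + flank) else
      c(genes$start[i] - flank, genes$start[i] - 1)
    dn <- if (st == "-") c(genes$start[i] - flank, genes$start[i] - 1) else
      c(genes$end[i] + 1, genes$end[i] + flank)
    add("upstream", ch, up[1], up[2], gid)
    add("downstream", ch, dn[1], dn[2], gid)
  }
  precedence <- c(exonic = 1, splicing = 2, intronic = 3,
                  upstream = 4, downstream = 4, intergenic = 5)
  if (length(feat) == 0) {
    sites$region_class <- "intergenic"
    sites$gene_id <- NA_character_
    return(sites)
  }
  ft <- dplyr::bind_rows(feat)
  feat_gr <- GenomicRanges::GRanges(ft$chrom, IRanges::IRanges(ft$start, ft$end))
  hits <- GenomicRanges::findOverlaps(site_gr, feat_gr)
  ov <- tibble::tibble(
    site_idx = S4Vectors::queryHits(hits),
    class = ft$class[S4Vectors::subjectHits(hits)],
    gene_id = ft$gene_id[S4Vectors::subjectHits(hits)]
  )
  if (all_overlaps) {
    out <- dplyr::bind_cols(sites[ov$site_idx, ], ov[, c("class", "gene_id")])
    return(dplyr::rename(out, region_class = "class"))
  }
  best <- ov |>
    dplyr::mutate(rank = precedence[.data$class]) |>
    dplyr::group_by(.data$site_idx) |>
    dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  sites$region_class <- "intergenic"
  sites$gene_id <- NA_character_
  sites$region_class[best$site_idx] <- best$class
  sites$gene_id[best$site_idx] <- best$gene_id
  sites
}

spliced_cds_info <- function(gene, ref) {
  cc <- gene$cds[[1]]
  cc <- cc[order(cc$start), , drop = FALSE]
  seqs <- as.character(Biostrings::extractAt(
    ref[[gene$chrom]], IRanges::IRanges(cc$start, cc$end)))
  asc_seq <- paste(seqs, collapse = "")
  list(cds = cc, asc_seq = asc_seq, len = nchar(asc_seq))
}

#' Predict the coding effect of a SNP inside a CDS
#'
#' Locates the codon of the site on the coding strand (reverse complement for
#' minus-strand genes), substitutes the ALT allele, and translates REF vs ALT
#' codon under the standard genetic code.
#'
#' @param site one-row tibble or list with `chrom`, `pos`, `ref`, `alt`.
#' @param gene one-row gene-model tibble (site must fall in its CDS).
#' @param ref reference `DNAStringSet`.
#' @return Tibble with `coding_effect` (`synonymous`, `nonsynonymous`,
#'   `stop_gain`, `stop_loss`, or `n/a`) and `aa_change` (three-letter, e.g.
#'   `"Thr->Lys"`).
#' @export
coding_effect <- function(site, gene, ref) {
  info <- spliced_cds_info(gene, ref)
  cc <- info$cds
  in_cds <- which(site$pos >= cc$start & site$pos <= cc$end)
  if (length(in_cds) != 1) stop("site ", site$chrom, ":", site$pos, " not in CDS of ", gene$gene_id)
  prior <- if (in_cds > 1) sum(cc$end[seq_len(in_cds - 1)] - cc$start[seq_len(in_cds - 1)] + 1) else 0
  asc_idx <- prior + (site$pos - cc$start[in_cds]) + 1
  ref_base_genomic <- substr(info$asc_seq, asc_idx, asc_idx)
  if (ref_base_genomic != site$ref) {
    stop("REF mismatch vs reference at ", site$chrom, ":", site$pos,
         " (FASTA has ", ref_base_genomic, ", VCF says ", site$ref, ")")
  }
  minus <- gene$strand == "-"
  coding_seq <- if (minus) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(info$asc_seq)))
  } else info$asc_seq
  coding_idx <- if (minus) info$len - asc_idx + 1 else asc_idx
  ref_cod_base <- if (minus) COMPLEMENT[[site$ref]] else site$ref
  alt_cod_base <- if (minus) COMPLEMENT[[site$alt]] else site$alt
  codon_i <- ceiling(coding_idx / 3)
  if (codon_i * 3 > info$len) {
    warning("incomplete terminal codon in ", gene$gene_id)
    return(tibble::tibble(coding_effect = "n/a", aa_change = ""))
  }
  codon <- substr(coding_seq, (codon_i - 1) * 3 + 1, codon_i * 3)
  pos_in_codon <- coding_idx - (codon_i - 1) * 3
  stopifnot(substr(codon, pos_in_codon, pos_in_codon) == ref_cod_base)
  alt_codon <- codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_cod_base
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  effect <- if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stop_gain"
  else if (aa_ref == "*") "stop_loss"
  else "nonsynonymous"
  tibble::tibble(
    coding_effect = effect,
    aa_change = if (effect == "synonymous") ""
    else paste0(AA3[[aa_ref]], "->", AA3[[aa_alt]])
  )
}

#' Annotate all SNPs of a panel
#'
#' Combines [classify_region()] with [coding_effect()] for exonic SNPs that
#' fall inside a CDS.
#'
#' @param sites site tibble (`chrom`, `pos`, `ref`, `alt`, `id`).
#' @param genes gene models from [read_gff()].
#' @param ref reference `DNAStringSet`.
#' @param flank upstream/downstream window, bp.
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `region_class`, `gene_id`,
#'   `coding_effect`, `aa_change`.
#' @export
annotate_snps <- function(sites, genes, ref, flank = 1000) {
  ann <- classify_region(sites, genes, flank = flank)
  ann$coding_effect <- "n/a"
  ann$aa_change <- ""
  ex <- which(ann$region_class == "exonic")
  for (i in ex) {
    gene <- genes[genes$gene_id == ann$gene_id[i], , drop = FALSE]
    cc <- gene$cds[[1]]
    if (nrow(cc) == 0 || !any(ann$pos[i] >= cc$start & ann$pos[i] <= cc$end)) next
    eff <- coding_effect(ann[i, ], gene, ref)
    ann$coding_effect[i] <- eff$coding_effect
    ann$aa_change[i] <- eff$aa_change
  }
  dplyr::select(ann, dplyr::any_of(c("chrom", "pos", "ref", "alt", "id",
                                     "region_class", "gene_id",
                                     "coding_effect", "aa_change")))
}

#' Transition/transversion ratio
#'
#' Transitions are `A<->G` and `C<->T`; everything else is a transversion.
#'
#' @param sites tibble with `ref`, `alt`.
#' @return `n_transitions / n_transversions` (Inf with a warning when there
#'   are no transversions).
#' @export
ts_tv_ratio <- function(sites) {
  pur <- c("A", "G")
  is_ts <- (sites$ref %in% pur) == (sites$alt %in% pur)
  n_tv <- sum(!is_ts)
  if (n_tv == 0) {
    warning("no transversions; Ts/Tv undefined")
    return(Inf)
  }
  sum(is_ts) / n_tv
}

#' Summarize SNP annotations
#'
#' @param ann annotation tibble from [annotate_snps()].
#' @return List with `region_proportions` (tibble `region_class`,
#'   `n`, `proportion`; proportions sum to 1) and `ns_s_ratio`
#'   (nonsynonymous : synonymous over CDS SNPs; `Inf` with a warning when no
#'   synonymous SNPs, `NA` when no CDS SNPs).
#' @export
annotation_summary <- function(ann) {
  if (nrow(ann) == 0) {
    return(list(region_proportions = tibble::tibble(region_class = character(),
                                                    n = integer(),
                                                    proportion = numeric()),
                ns_s_ratio = NA_real_))
  }
  props <- ann |>
    dplyr::count(.data$region_class) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
  n_s <- sum(ann$coding_effect == "synonymous")
  n_ns <- sum(ann$coding_effect == "nonsynonymous")
  ratio <- if (n_s == 0 && n_ns == 0) NA_real_
  else if (n_s == 0) {
    warning("no synonymous SNPs; ns/s ratio undefined")
    Inf
  } else n_ns / n_s
  list(region_proportions = props, ns_s_ratio = ratio)
}
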