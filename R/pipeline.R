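#' Assemble and validate a pipeline configuration
#'
#' @param vcf path to the genotype VCF (required).
#' @param gff,fasta paths to gene models and reference (optional; needed for
#'   annotation and candidate genes).
#' @param phenotypes path to the tidy phenotype table (optional; needed for
#'   BLUP, GWAS, trait-extreme scans and allele effects).
#' @param groups path to the accession-group table (optional; needed for
#'   group diversity and sweep scans).
#' @param outdir output directory.
#' @param trait trait to analyze.
#' @param focal_groups,background_group sweep-scan contrast (default: every
#'   other group against `background_group`).
#' @param maf_min,missing_max,depth_min site filters (see [filter_sites()]).
#' @param window_size scan window, bp.
#' @param fst_min,ratio_min,sweep_mode sweep thresholds (see
#'   [call_sweep_regions()]).
#' @param high_min,low_max trait-extreme thresholds, trait units.
#' @param gwas_threshold `-log10(p)` significance threshold.
#' @param candidate_half_width candidate-gene window half width, bp.
#' @param seed root seed for the seeded stages.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(vcf, gff = NULL, fasta = NULL, phenotypes = NULL,
                            groups = NULL, outdir, trait = "sesamin",
                            focal_groups = NULL, background_group = NULL,
                            maf_min = 0.05, missing_max = 0.2, depth_min = 8,
                            window_size = 10000, fst_min = 0.45,
                            ratio_min = 2.5, sweep_mode = "fixed",
                            high_min = 6, low_max = 1, gwas_threshold = 6,
                            candidate_half_width = 89000, seed = 1L) {
  for (p in c(vcf, gff, fasta, phenotypes, groups)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  stopifnot(maf_min >= 0, maf_min < 0.5, missing_max >= 0, missing_max <= 1,
            window_size > 0, gwas_threshold > 0)
  structure(as.list(environment()), class = "run_config")
}

write_stage <- function(x, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in order and as the inputs allow: site filtering, SNP annotation,
#' windowed diversity/differentiation statistics, LD decay, sweep scans for
#' each focal group against the background, multi-environment BLUP, a
#' trait-extreme (high/low) divergence scan, the EMMAX association scan with
#' candidate-gene windows, and allele-effect tests at the significant loci.
#' Every table is written as TSV (1-based inclusive coordinates) together
#' with a manifest of input hashes, parameters and output hashes; a rerun
#' with the same inputs and seed reproduces the manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  gm <- stage("filter", {
    gm0 <- read_vcf(config$vcf)
    filter_sites(gm0, maf_min = config$maf_min,
                 missing_max = config$missing_max, depth_min = config$depth_min)
  })
  results$filter_report <- attr(gm, "filter_report")
  outputs["filter_report"] <- write_stage(results$filter_report, config$outdir, "filter_report")

  genes <- NULL; ref <- NULL
  if (!is.null(config$gff)) genes <- stage("annotate", read_gff(config$gff))
  if (!is.null(config$fasta)) ref <- stage("annotate", read_fasta(config$fasta))
  if (!is.null(genes) && !is.null(ref)) {
    results$annotation <- stage("annotate", {
      check_reference(gm, ref)
      annotate_snps(gm$sites, genes, ref)
    })
    results$ts_tv <- ts_tv_ratio(gm$sites)
    outputs["annotation"] <- write_stage(results$annotation, config$outdir, "annotation")
  }

  groups <- NULL
  if (!is.null(config$groups)) {
    groups <- stage("stats", {
      g <- read_groups(config$groups)
      g[g$accession %in% gm$samples, , drop = FALSE]
    })
  }
  results$window_stats <- stage("stats", window_stats(gm, groups = groups,
                                                      size = config$window_size))
  ws_out <- dplyr::mutate(results$window_stats, start = .data$start + 1)
  outputs["window_stats"] <- write_stage(ws_out, config$outdir, "window_stats")

  results$ld_curve <- stage("ld", ld_decay_curve(gm, seed = config$seed))
  results$ld_summary <- glance.ld_curve(results$ld_curve)
  outputs["ld_curve"] <- write_stage(results$ld_curve, config$outdir, "ld_curve")

  if (!is.null(groups)) {
    glabels <- unique(groups$group)
    bg <- config$background_group %||% glabels[1]
    focal <- config$focal_groups %||% setdiff(glabels, bg)
    regions <- purrr::map_dfr(focal, function(fg) {
      ct <- window_contrast(results$window_stats, focal = fg, background = bg)
      call_sweep_regions(ct, fst_min = config$fst_min,
                         ratio_min = config$ratio_min, mode = config$sweep_mode,
                         focal = fg, background = bg)
    })
    if (!is.null(genes)) regions <- genes_in_regions(regions, genes)
    results$sweep_regions <- regions
    reg_out <- regions |>
      dplyr::mutate(start = .data$start + 1,
                    genes = if ("genes" %in% names(regions))
                      purrr::map_chr(.data$genes, paste, collapse = ";") else NULL)
    outputs["sweep_regions"] <- write_stage(reg_out, config$outdir, "sweep_regions")
  }

  if (!is.null(config$phenotypes)) {
    pt <- stage("blup", read_phenotypes(config$phenotypes))
    results$phenotype_summary <- stage("blup", phenotype_summary(pt, config$trait))
    results$blup <- stage("blup", blup_phenotype(pt, config$trait))
    outputs["phenotype_summary"] <- write_stage(results$phenotype_summary,
                                                config$outdir, "phenotype_summary")
    outputs["blup"] <- write_stage(results$blup, config$outdir, "blup")

    split <- stage("trait_divergence", trait_group_split(
      stats::setNames(results$blup$blup, results$blup$accession),
      high_min = config$high_min, low_max = config$low_max
    ))
    results$trait_groups <- split
    if (length(split$high) >= 2 && length(split$low) >= 2) {
      hl_groups <- tibble::tibble(
        accession = c(split$high, split$low),
        group = rep(c("HS", "LS"), c(length(split$high), length(split$low)))
      )
      hl_gm <- subset_geno(gm, samples = hl_groups$accession)
      results$hs_ls_stats <- stage("trait_divergence",
                                   window_stats(hl_gm, groups = hl_groups,
                                                size = config$window_size))
      outputs["hs_ls_stats"] <- write_stage(
        dplyr::mutate(results$hs_ls_stats, start = .data$start + 1),
        config$outdir, "hs_ls_stats")
    }

    y_tbl <- results$blup[match(gm$samples, results$blup$accession), , drop = FALSE]
    if (anyNA(y_tbl$blup)) stop("pipeline stage 'gwas' failed: phenotypes missing for some genotyped accessions")
    K <- stage("gwas", kinship_matrix(gm))
    null <- stage("gwas", fit_null_mlm(y_tbl$blup, K))
    scan <- stage("gwas", emmax_scan(gm, null))
    results$gwas <- scan
    results$gwas_lambda <- genomic_inflation(scan)
    outputs["gwas"] <- write_stage(scan, config$outdir, "gwas")
    loci <- stage("gwas", significant_loci(scan, threshold = config$gwas_threshold,
                                           collapse_bp = config$candidate_half_width))
    results$loci <- loci
    outputs["loci"] <- write_stage(loci, config$outdir, "loci")
    if (!is.null(genes) && nrow(loci) > 0) {
      results$candidate_genes <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
        cw <- candidate_window(loci[i, ], genes,
                               half_width = config$candidate_half_width)
        if (nrow(cw) == 0) return(NULL)
        tibble::tibble(locus_id = loci$id[i], gene_id = cw$gene_id,
                       chrom = cw$chrom, start = cw$start, end = cw$end)
      })
      if (nrow(results$candidate_genes %||% tibble::tibble()) > 0) {
        outputs["candidate_genes"] <- write_stage(results$candidate_genes,
                                                  config$outdir, "candidate_genes")
      }
    }
    if (nrow(loci) > 0) {
      ph <- tibble::tibble(accession = results$blup$accession,
                           value = results$blup$blup)
      results$allele_effects <- purrr::map_dfr(loci$id, function(sid) {
        tidy.allele_effect(allele_effect(gm, sid, ph))
      })
      outputs["allele_effects"] <- write_stage(results$allele_effects,
                                               config$outdir, "allele_effects")
    }
  }

  inputs <- purrr::compact(config[c("vcf", "gff", "fasta", "phenotypes", "groups")])
  params <- config[setdiff(names(config), c("vcf", "gff", "fasta", "phenotypes",
                                            "groups", "outdir"))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("popgenscan")),
    seed = config$seed,
    parameters = params,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    output_md5 = as.list(tools::md5sum(unname(outputs)))
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
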