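#' Per-window sweep contrast between a focal and a background group
#'
#' Extracts, from a [window_stats()] table, the FST of the focal/background
#' pair and the diversity ratio `log2(pi_background / pi_focal)` (positive
#' when diversity is reduced in the focal group). Windows with zero
#' background diversity are excluded; windows with zero focal diversity but
#' positive background diversity receive the configured cap so region peak
#' statistics stay finite.
#'
#' @param stats tibble from [window_stats()] containing `pi_<focal>`,
#'   `pi_<background>` and the pair's FST column.
#' @param focal,background group labels.
#' @param cap value assigned when `pi_focal = 0 < pi_background` (default 10).
#' @return Tibble: `chrom`, `start`, `end`, `n_snps`, `fst`,
#'   `log2_pi_ratio`, `capped`.
#' @export
window_contrast <- function(stats, focal, background, cap = 10) {
  pf <- paste0("pi_", focal); pb <- paste0("pi_", background)
  fst_col <- intersect(c(paste0("fst_", focal, "_", background),
                         paste0("fst_", background, "_", focal)), names(stats))
  if (!all(c(pf, pb) %in% names(stats)) || length(fst_col) == 0) {
    stop("window_stats table lacks columns for groups ", focal, " / ", background)
  }
  out <- stats |>
    dplyr::filter(.data[[pb]] > 0) |>
    dplyr::transmute(
      .data$chrom, .data$start, .data$end, .data$n_snps,
      fst = .data[[fst_col[1]]],
      capped = .data[[pf]] == 0,
      log2_pi_ratio = dplyr::if_else(.data[[pf]] == 0, cap,
                                     log2(.data[[pb]] / .data[[pf]]))
    )
  dplyr::relocate(out, "capped", .after = "log2_pi_ratio")
}

#' Call selective-sweep regions from joint FST / pi-ratio criteria
#'
#' In `fixed` mode a window is flagged when BOTH `fst > fst_min` and
#' `log2_pi_ratio > ratio_min` (the printed criteria of crop sweep scans,
#' defaults 0.45 and 2.5). In `quantile` mode the thresholds are the
#' empirical upper `quantile_cut` quantiles of the two statistics. Flagged
#' windows separated by at most `merge_gap` windows are merged into regions.
#'
#' @param contrasts tibble from [window_contrast()].
#' @param fst_min,ratio_min fixed thresholds.
#' @param mode `"fixed"` or `"quantile"`.
#' @param quantile_cut upper-tail mass for quantile mode (default 0.05).
#' @param merge_gap maximum number of intervening non-flagged windows merged
#'   across (default 1, i.e. adjacent or one-window gaps).
#' @param focal,background labels recorded in the output.
#' @return Tibble of regions: `chrom`, `start`, `end` (0-based half-open),
#'   `n_windows`, `peak_fst`, `peak_log2_ratio`, `focal`, `background`.
#' @export
call_sweep_regions <- function(contrasts, fst_min = 0.45, ratio_min = 2.5,
                               mode = c("fixed", "quantile"), quantile_cut = 0.05,
                               merge_gap = 1, focal = NA_character_,
                               background = NA_character_) {
  mode <- match.arg(mode)
  cx <- contrasts[!is.na(contrasts$fst) & !is.na(contrasts$log2_pi_ratio), , drop = FALSE]
  if (mode == "quantile") {
    fst_min <- stats::quantile(cx$fst, 1 - quantile_cut, names = FALSE)
    ratio_min <- stats::quantile(cx$log2_pi_ratio, 1 - quantile_cut, names = FALSE)
  }
  flagged <- cx[cx$fst > fst_min & cx$log2_pi_ratio > ratio_min, , drop = FALSE]
  if (nrow(flagged) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          n_windows = integer(), peak_fst = numeric(),
                          peak_log2_ratio = numeric(), focal = character(),
                          background = character()))
  }
  wsize <- stats::median(flagged$end - flagged$start)
  flagged <- dplyr::arrange(flagged, .data$chrom, .data$start)
  gap_ok <- c(FALSE, flagged$chrom[-1] == flagged$chrom[-nrow(flagged)] &
                (flagged$start[-1] - flagged$end[-nrow(flagged)]) <= merge_gap * wsize)
  flagged$region <- cumsum(!gap_ok)
  flagged |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(), peak_fst = max(.data$fst),
      peak_log2_ratio = max(.data$log2_pi_ratio), .groups = "drop"
    ) |>
    dplyr::select(-"region") |>
    dplyr::mutate(focal = focal, background = background)
}

#' Genes overlapping sweep regions
#'
#' A gene is included when its span overlaps a region by at least one bp.
#'
#' @param regions tibble with `chrom`, `start`, `end` (0-based half-open, as
#'   emitted by [call_sweep_regions()]).
#' @param genes gene models from [read_gff()] (1-based inclusive spans).
#' @return `regions` with a `genes` list-column of gene ids, plus attribute
#'   `all_genes`, the sorted union.
#' @export
genes_in_regions <- function(regions, genes) {
  gsets <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start <= regions$end[i] & genes$end >= regions$start[i] + 1
    sort(genes$gene_id[hit])
  })
  out <- regions
  out$genes <- gsets
  attr(out, "all_genes") <- sort(unique(unlist(gsets)))
  out
}

#' Intersection of selected-gene sets
#'
#' @param gene_sets list of >= 2 character vectors of gene ids.
#' @return Sorted character vector of genes present in every set.
#' @export
common_selected_genes <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 2)
  sort(Reduce(intersect, gene_sets))
}

#' Split accessions into high- and low-trait groups
#'
#' Strict inequalities: high when `value > high_min`, low when
#' `value < low_max`; accessions in between stay unassigned.
#'
#' @param values tibble with `accession` and `value` (one value per
#'   accession, e.g. a BLUP), or a named numeric vector.
#' @param high_min,low_max thresholds in trait units (defaults 6 and 1 mg/g,
#'   the usual high/low lignan cut).
#' @param min_group_size emit a warning when a group is smaller than this.
#' @return List with character vectors `high` and `low`.
#' @export
trait_group_split <- function(values, high_min = 6, low_max = 1,
                              min_group_size = 10) {
  if (is.numeric(values)) {
    values <- tibble::tibble(accession = names(values), value = unname(values))
  }
  if (any(duplicated(values$accession))) stop("one value per accession required")
  high <- values$accession[values$value > high_min]
  low <- values$accession[values$value < low_max]
  if (length(high) == 0 || length(low) == 0) {
    warning("empty high or low group at thresholds (", low_max, ", ", high_min, ")")
  } else if (length(high) < min_group_size || length(low) < min_group_size) {
    warning("trait group smaller than ", min_group_size, " accessions")
  }
  list(high = high, low = low)
}

#' Compare called sweep regions with planted truth
#'
#' Window-level recall and false-flag rate of a sweep scan against the truth
#' table of a simulated panel.
#'
#' @param contrasts tibble from [window_contrast()] with the flag columns.
#' @param regions called regions from [call_sweep_regions()].
#' @param truth_sweeps tibble `chrom`, `start`, `end` (1-based inclusive
#'   intervals as stored in the simulation truth table).
#' @return Tibble with `n_true_windows`, `n_recalled`, `recall`,
#'   `n_neutral_windows`, `n_false_flags`, `false_flag_rate`.
#' @export
sweep_performance <- function(contrasts, regions, truth_sweeps) {
  in_truth <- function(chrom, start, end) {
    vapply(seq_along(chrom), function(i) {
      any(truth_sweeps$chrom == chrom[i] &
            truth_sweeps$start <= start[i] + 1 & truth_sweeps$end >= end[i])
    }, logical(1))
  }
  truth_win <- in_truth(contrasts$chrom, contrasts$start, contrasts$end)
  flagged_win <- rep(FALSE, nrow(contrasts))
  for (i in seq_len(nrow(regions))) {
    flagged_win <- flagged_win | (contrasts$chrom == regions$chrom[i] &
                                    contrasts$start >= regions$start[i] &
                                    contrasts$end <= regions$end[i])
  }
  tibble::tibble(
    n_true_windows = sum(truth_win),
    n_recalled = sum(truth_win & flagged_win),
    recall = ifelse(sum(truth_win) > 0, sum(truth_win & flagged_win) / sum(truth_win), NA),
    n_neutral_windows = sum(!truth_win),
    n_false_flags = sum(!truth_win & flagged_win),
    false_flag_rate = sum(!truth_win & flagged_win) / sum(!truth_win)
  )
}
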