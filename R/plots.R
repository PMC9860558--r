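#' Plot an LD-decay curve
#'
#' @param object an `ld_curve` from [ld_decay_curve()].
#' @param ... unused.
#' @return A ggplot: mean r^2 (points) and smoothed curve (line) against
#'   distance, with the half-decay distance marked when defined.
#' @export
autoplot.ld_curve <- function(object, ...) {
  hd <- suppressWarnings(half_decay_distance(object))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$distance / 1000)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_r2), alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r2_smooth), color = "firebrick") +
    ggplot2::labs(x = "Distance (kb)", y = expression(mean~r^2)) +
    ggplot2::theme_minimal()
  if (!is.na(hd)) {
    p <- p + ggplot2::geom_vline(xintercept = hd / 1000, linetype = "dashed")
  }
  p
}

#' Manhattan plot of an association scan
#'
#' @param object an `assoc_scan` from [emmax_scan()].
#' @param threshold `-log10(p)` guide line (default 6).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.assoc_scan <- function(object, threshold = 6, ...) {
  d <- dplyr::arrange(object, .data$chrom, .data$pos)
  offs <- d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  d <- dplyr::left_join(d, offs, by = "chrom")
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$pos + .data$offset) / 1e6,
                                  y = .data$minus_log10_p,
                                  color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "blue") +
    ggplot2::labs(x = "Genome position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' QQ plot of association p-values
#'
#' @param results an `assoc_scan` or numeric p-value vector.
#' @return A ggplot of observed vs expected `-log10(p)` with the genomic
#'   inflation factor in the subtitle.
#' @export
plot_qq <- function(results) {
  p <- if (is.numeric(results)) results else results$p_value
  p <- sort(p[!is.na(p)])
  d <- tibble::tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  lam <- genomic_inflation(p)
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "firebrick") +
    ggplot2::labs(x = expression(Expected~-log[10](p)),
                  y = expression(Observed~-log[10](p)),
                  subtitle = sprintf("lambda = %.3f", lam)) +
    ggplot2::theme_minimal()
}

#' Plot a sweep-scan contrast along the genome
#'
#' @param contrasts tibble from [window_contrast()].
#' @param fst_min,ratio_min thresholds drawn as guide lines.
#' @return A ggplot with FST and log2 pi-ratio tracks (FST clamped at 0 for
#'   display only).
#' @export
plot_sweep_contrast <- function(contrasts, fst_min = 0.45, ratio_min = 2.5) {
  d <- contrasts |>
    dplyr::mutate(fst = pmax(.data$fst, 0), mid = (.data$start + .data$end) / 2) |>
    tidyr::pivot_longer(c("fst", "log2_pi_ratio"), names_to = "statistic")
  guides <- tibble::tibble(statistic = c("fst", "log2_pi_ratio"),
                           cut = c(fst_min, ratio_min))
  ggplot2::ggplot(d, ggplot2::aes(.data$mid / 1e6, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = guides, ggplot2::aes(yintercept = .data$cut),
                        linetype = "dashed", color = "blue") +
    ggplot2::facet_grid(statistic ~ chrom, scales = "free") +
    ggplot2::labs(x = "Position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}
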