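#' Group accessions by allele at a site
#'
#' Homozygous reference carriers form the REF-allele group and homozygous
#' alternate carriers the ALT-allele group. Heterozygotes are excluded by
#' default (the natural choice for a selfing, largely inbred panel) or kept
#' as their own group; missing genotypes are always excluded.
#'
#' @param gm a [geno_matrix()].
#' @param site_id site id (from `gm$sites$id`).
#' @param phenotype tibble `accession`, `value` (e.g. BLUPs).
#' @param het_policy `"exclude"` or `"own_group"`.
#' @return Tibble: `allele`, `accession`, `value`.
#' @export
split_by_allele <- function(gm, site_id, phenotype, het_policy = c("exclude", "own_group")) {
  het_policy <- match.arg(het_policy)
  j <- match(site_id, gm$sites$id)
  if (is.na(j)) stop("site not found: ", site_id)
  dos <- gm$dosage[, j]
  ref <- gm$sites$ref[j]; alt <- gm$sites$alt[j]
  allele <- dplyr::case_when(
    dos == 0L ~ ref,
    dos == 2L ~ alt,
    dos == 1L & het_policy == "own_group" ~ paste0(ref, "/", alt),
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(accession = gm$samples, allele = allele) |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::inner_join(phenotype, by = "accession") |>
    dplyr::select("allele", "accession", "value")
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @return Tibble: `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(tibble::tibble(t = 0, df = NA_real_, p_value = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Allele-effect test at a locus
#'
#' Groups phenotypes by homozygous allele class at the site and tests the
#' difference of means (Welch by default; pooled-variance Student behind the
#' flag). The superior allele is the one with the higher (or lower, per
#' `direction`) group mean, flagged significant at `p < alpha`.
#'
#' @param gm a [geno_matrix()].
#' @param site_id site id.
#' @param phenotype tibble `accession`, `value`.
#' @param het_policy passed to [split_by_allele()].
#' @param pooled use pooled-variance Student's t instead of Welch.
#' @param direction `"higher"` or `"lower"`: which mean defines superiority.
#' @param alpha significance level for the superior-allele flag.
#' @param min_group_size groups below this size skip the test.
#' @return Object of class `allele_effect`: a list with `site_id`, `groups`
#'   (tibble `allele`, `n`, `mean`, `sd`), `t`, `df`, `p_value`,
#'   `superior_allele` (`NA` when means tie or the test was skipped),
#'   `significant`.
#' @export
allele_effect <- function(gm, site_id, phenotype,
                          het_policy = c("exclude", "own_group"),
                          pooled = FALSE, direction = c("higher", "lower"),
                          alpha = 0.05, min_group_size = 2) {
  direction <- match.arg(direction)
  grp <- split_by_allele(gm, site_id, phenotype, het_policy = match.arg(het_policy))
  gsum <- grp |>
    dplyr::group_by(allele = .data$allele) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n))
  res <- list(site_id = site_id, groups = gsum, t = NA_real_, df = NA_real_,
              p_value = NA_real_, superior_allele = NA_character_,
              significant = FALSE, skipped = FALSE)
  hom <- gsum[!grepl("/", gsum$allele), , drop = FALSE]
  if (nrow(hom) < 2 || any(hom$n[1:2] < min_group_size)) {
    res$skipped <- TRUE
    class(res) <- "allele_effect"
    return(res)
  }
  va <- grp$value[grp$allele == hom$allele[1]]
  vb <- grp$value[grp$allele == hom$allele[2]]
  ht <- if (pooled) {
    h <- stats::t.test(va, vb, var.equal = TRUE)
    tibble::tibble(t = unname(h$statistic), df = unname(h$parameter), p_value = h$p.value)
  } else welch_t_test(va, vb)
  res$t <- ht$t; res$df <- ht$df; res$p_value <- ht$p_value
  if (mean(va) != mean(vb)) {
    pick <- if (direction == "higher") which.max(c(mean(va), mean(vb)))
    else which.min(c(mean(va), mean(vb)))
    res$superior_allele <- hom$allele[pick]
    res$significant <- ht$p_value < alpha
  }
  class(res) <- "allele_effect"
  res
}

#' @export
print.allele_effect <- function(x, ...) {
  cat(sprintf("<allele_effect> %s: p = %.3g, superior allele = %s%s\n",
              x$site_id, x$p_value, x$superior_allele,
              if (isTRUE(x$significant)) " (significant)" else ""))
  invisible(x)
}

#' @export
tidy.allele_effect <- function(x, ...) {
  dplyr::mutate(x$groups, site_id = x$site_id, t = x$t, df = x$df,
                p_value = x$p_value, superior_allele = x$superior_allele)
}

#' Superior allele of an allele-effect test
#'
#' @param effect an [allele_effect()] object.
#' @return The superior allele (`NA` when means tie or the test was
#'   skipped), with attribute `significant`.
#' @export
superior_allele <- function(effect) {
  stopifnot(inherits(effect, "allele_effect"))
  structure(effect$superior_allele, significant = effect$significant)
}
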