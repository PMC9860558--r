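#' Multi-environment BLUP phenotype
#'
#' Fits `value ~ environment + (1 | accession)` by REML and returns, per
#' accession, the population mean plus the shrunken (best linear unbiased
#' predictor) accession effect. With a balanced design of `r` environments
#' the accession deviations are shrunk by `sigma_a^2 / (sigma_a^2 +
#' sigma_e^2 / r)`.
#'
#' @param pt phenotype tibble (`accession`, `environment`, `trait`, `value`).
#' @param trait trait name to model.
#' @return Tibble `accession`, `blup` (trait units); the fitted model is
#'   attached as attribute `fit` (class `merMod`, or `NULL` for the
#'   single-environment fallback).
#' @export
blup_phenotype <- function(pt, trait) {
  d <- pt[pt$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for trait ", trait)
  if (length(unique(d$accession)) < 2) stop("need >= 2 accessions")
  if (length(unique(d$environment)) < 2) {
    warning("single environment: returning per-accession values without shrinkage")
    out <- tibble::tibble(accession = d$accession, blup = d$value)
    attr(out, "fit") <- NULL
    return(out)
  }
  d$environment <- factor(d$environment)
  fit <- lme4::lmer(value ~ environment + (1 | accession), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4)))
  fe <- lme4::fixef(fit)
  env_effects <- c(0, fe[grep("^environment", names(fe))])
  mu <- unname(fe[["(Intercept)"]] + mean(env_effects))
  re <- lme4::ranef(fit)$accession
  out <- tibble::tibble(
    accession = rownames(re),
    blup = mu + re[["(Intercept)"]]
  )
  attr(out, "fit") <- fit
  out
}

#' Per-environment phenotype summaries
#'
#' @param pt phenotype tibble.
#' @param trait trait name.
#' @return Tibble per environment: `n`, `min`, `max`, `mean`, `sd`, `cv_pct`
#'   (100 x sample sd / mean; `NA` with a warning when the mean is zero).
#' @export
phenotype_summary <- function(pt, trait) {
  d <- pt[pt$trait == trait, , drop = FALSE]
  out <- d |>
    dplyr::group_by(environment = .data$environment) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$value), max = max(.data$value),
      mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(cv_pct = ifelse(.data$mean == 0, NA_real_,
                                  100 * .data$sd / .data$mean))
  if (any(out$mean == 0)) warning("zero mean in some environment; CV undefined")
  out
}
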