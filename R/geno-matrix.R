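#' Genotype matrix container
#'
#' Holds diploid dosages (count of ALT alleles, `NA` for missing) for a set of
#' samples at biallelic SNP sites, together with the site table and, when
#' available, per-genotype sequencing depth. Sites are kept sorted by
#' `(chrom, pos)`; positions are stored 1-based as in VCF.
#'
#' @param dosage integer matrix, samples x sites, values in `{0, 1, 2, NA}`.
#' @param sites tibble with columns `chrom`, `pos`, `ref`, `alt` and optional
#'   `id` (defaults to `"<chrom>-<pos>"`), one row per column of `dosage`.
#' @param samples character vector of sample identifiers (rows of `dosage`).
#' @param depth optional integer matrix of per-genotype read depths, same
#'   shape as `dosage`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, sites, samples = rownames(dosage), depth = NULL) {
  dosage <- as.matrix(dosage)
  sites <- tibble::as_tibble(sites)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(nrow(sites) == ncol(dosage), length(samples) == nrow(dosage))
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(dosage)))
  }
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!"id" %in% names(sites)) {
    sites$id <- paste0(sites$chrom, "-", sites$pos)
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  rownames(dosage) <- samples
  colnames(dosage) <- sites$id
  structure(
    list(dosage = dosage, sites = sites, samples = samples, depth = depth),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d sites on %d chromosome(s)%s\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$sites$chrom)),
    if (is.null(x$depth)) "" else " (with depth)"
  ))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a [geno_matrix()].
#' @param samples character vector of sample ids or logical/integer index.
#' @param sites logical/integer index into the site table.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(gm, samples = NULL, sites = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  si <- if (is.null(samples)) {
    seq_along(gm$samples)
  } else if (is.character(samples)) {
    idx <- match(samples, gm$samples)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    idx
  } else {
    seq_along(gm$samples)[samples]
  }
  vi <- if (is.null(sites)) seq_len(nrow(gm$sites)) else seq_len(nrow(gm$sites))[sites]
  geno_matrix(
    gm$dosage[si, vi, drop = FALSE],
    gm$sites[vi, , drop = FALSE],
    samples = gm$samples[si],
    depth = if (is.null(gm$depth)) NULL else gm$depth[si, vi, drop = FALSE]
  )
}

#' Per-site ALT allele frequency on non-missing calls
#'
#' @param gm a [geno_matrix()].
#' @param samples optional subset of sample ids.
#' @return Numeric vector, one frequency per site (NaN where no calls).
#' @export
alt_freq <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[match(samples, gm$samples), , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Tidy the site table of a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param ... unused.
#' @return The site tibble with per-site ALT frequency and missing rate.
#' @export
tidy.geno_matrix <- function(x, ...) {
  dplyr::mutate(
    x$sites,
    alt_freq = alt_freq(x),
    missing_rate = colMeans(is.na(x$dosage))
  )
}
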