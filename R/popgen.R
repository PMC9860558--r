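#' Tile chromosomes with nonoverlapping windows
#'
#' @param chrom_lengths named numeric vector of chromosome lengths, bp.
#' @param size window size, bp (default 10 kb). The terminal window of each
#'   chromosome is truncated at its length.
#' @return Tibble `chrom`, `start`, `end` with 0-based half-open coordinates.
#' @export
make_windows <- function(chrom_lengths, size = 10000) {
  if (size <= 0) stop("window size must be positive")
  stopifnot(all(chrom_lengths >= 1))
  if (is.null(names(chrom_lengths))) names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = size)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + size, L))
  })
}

#' Per-site nucleotide diversity from diploid dosages
#'
#' With `m` non-missing haplotypes (2 x calls) and ALT frequency `p`,
#' per-site diversity is the unbiased expected heterozygosity
#' `2 p (1-p) m / (m-1)`, which equals the mean pairwise difference across
#' the `m` haplotypes. Sites with fewer than two calls return `NA` (they are
#' skipped by the window accumulator).
#'
#' @param dosage integer vector of diploid dosages (`NA` missing), or a
#'   matrix samples x sites for the vectorized form.
#' @return Numeric per-site diversity (vector when a matrix is supplied).
#' @export
site_pi <- function(dosage) {
  d <- if (is.matrix(dosage)) dosage else matrix(dosage, ncol = 1)
  n_call <- colSums(!is.na(d))
  m <- 2 * n_call
  p <- colMeans(d, na.rm = TRUE) / 2
  out <- ifelse(m >= 4 | m == 3, 2 * p * (1 - p) * m / (m - 1), NA_real_)
  out[n_call < 2] <- NA_real_
  if (is.matrix(dosage)) out else out[1]
}

site_stats_for_group <- function(dosage) {
  n_call <- colSums(!is.na(dosage))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  h <- colMeans(dosage == 1L, na.rm = TRUE)
  h[n_call == 0] <- NA_real_
  list(n = n_call, p = p, h = h)
}

#' Windowed nucleotide diversity per bp
#'
#' Sums [site_pi()] over the SNPs of a window and divides by the window
#' length in bp, so monomorphic positions count as invariant sites through
#' the denominator.
#'
#' @param gm a [geno_matrix()].
#' @param window one-row tibble/list with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param samples optional subset of sample ids.
#' @return Per-bp diversity (0 for an empty window).
#' @export
window_pi <- function(gm, window, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[match(samples, gm$samples), , drop = FALSE]
  in_w <- gm$sites$chrom == window$chrom &
    gm$sites$pos > window$start & gm$sites$pos <= window$end
  if (!any(in_w)) return(0)
  sp <- site_pi(d[, in_w, drop = FALSE])
  sum(sp, na.rm = TRUE) / (window$end - window$start)
}

tajima_constants <- function(n) {
  # n = haplotype count
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in a window
#'
#' Complete-case samples (no missing call at any window SNP) define a fixed
#' haplotype count `n`; `D = (pi_hat - theta_W) / sqrt(e1 S + e2 S (S-1))`
#' with Watterson's `theta_W = S / a1` and the standard normalization
#' constants, where `pi_hat` is the sum over window SNPs of the mean pairwise
#' difference (not per-bp).
#'
#' @param gm a [geno_matrix()].
#' @param window one-row tibble/list (`chrom`, `start`, `end`, 0-based
#'   half-open); omit (NULL) to use all sites.
#' @param samples optional subset of sample ids.
#' @return `D`, or `NA` when there are no segregating sites or fewer than
#'   two complete-case samples.
#' @export
tajimas_d <- function(gm, window = NULL, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[match(samples, gm$samples), , drop = FALSE]
  if (!is.null(window)) {
    in_w <- gm$sites$chrom == window$chrom &
      gm$sites$pos > window$start & gm$sites$pos <= window$end
    d <- d[, in_w, drop = FALSE]
  }
  if (ncol(d) == 0) return(NA_real_)
  complete <- rowSums(is.na(d)) == 0
  if (sum(complete) < 2) return(NA_real_)
  d <- d[complete, , drop = FALSE]
  n <- 2L * nrow(d)
  k <- colSums(d)
  seg <- k > 0 & k < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k <- k[seg]
  pi_hat <- sum(k * (n - k)) / (n * (n - 1) / 2)
  cst <- tajima_constants(n)
  theta_w <- S / cst$a1
  denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  (pi_hat - theta_w) / denom
}

wc_pair_components <- function(sa, sb) {
  # sa, sb: per-site lists (n, p, h) for the two populations
  ok <- sa$n >= 2 & sb$n >= 2
  n1 <- sa$n; n2 <- sb$n
  p1 <- sa$p; p2 <- sb$p
  h1 <- sa$h; h2 <- sb$h
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c[!ok] <- NA_real_
  # monomorphic-in-total sites have zero denominator; mark for exclusion
  zero <- !is.na(a) & (a + b + c) == 0
  a[zero] <- NA_real_; b[zero] <- NA_real_; c[zero] <- NA_real_
  list(a = a, b = b, c = c)
}

#' Weir-Cockerham FST between two populations
#'
#' Per-site variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) of Weir &
#' Cockerham (1984), combined across sites as a ratio of sums
#' `sum(a) / sum(a+b+c)` (the weighted estimator) or as a mean of per-site
#' ratios. Sites where either population has fewer than two non-missing
#' calls, or with a zero denominator, are excluded.
#'
#' @param gm a [geno_matrix()].
#' @param groups tibble `accession`, `group`.
#' @param pair character vector of two group labels.
#' @param sites optional logical/integer site index.
#' @param estimator `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return FST estimate (can be slightly negative under no differentiation).
#' @export
wc_fst <- function(gm, groups, pair, sites = NULL,
                   estimator = c("ratio_of_sums", "mean_of_ratios")) {
  estimator <- match.arg(estimator)
  stopifnot(length(pair) == 2)
  bad <- setdiff(pair, unique(groups$group))
  if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  d <- gm$dosage
  if (!is.null(sites)) d <- d[, sites, drop = FALSE]
  rows_a <- match(groups$accession[groups$group == pair[1]], gm$samples)
  rows_b <- match(groups$accession[groups$group == pair[2]], gm$samples)
  sa <- site_stats_for_group(d[rows_a, , drop = FALSE])
  sb <- site_stats_for_group(d[rows_b, , drop = FALSE])
  comp <- wc_pair_components(sa, sb)
  if (estimator == "ratio_of_sums") {
    sum(comp$a, na.rm = TRUE) /
      sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  } else {
    ratio <- comp$a / (comp$a + comp$b + comp$c)
    mean(ratio, na.rm = TRUE)
  }
}

#' Windowed diversity and differentiation statistics
#'
#' Computes, for each nonoverlapping window: segregating-site count, per-bp
#' nucleotide diversity, Watterson's theta per bp and Tajima's D for each
#' group, and Weir-Cockerham FST (ratio of sums within the window) for each
#' requested group pair.
#'
#' @param gm a [geno_matrix()].
#' @param groups tibble `accession`, `group`; omit for a single pooled group.
#' @param chrom_lengths named lengths used to tile windows; default inferred
#'   as the maximum position per chromosome.
#' @param size window size, bp.
#' @param pairs list of 2-vectors of group labels for FST; default all pairs.
#' @param tajima compute Tajima's D per group (complete-case; set `FALSE` to
#'   skip the per-window pass).
#' @return Tibble, one row per window: `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, then `pi_<group>`, `theta_<group>`,
#'   `tajd_<group>`, `fst_<g1>_<g2>` columns.
#' @export
window_stats <- function(gm, groups = NULL, chrom_lengths = NULL, size = 10000,
                         pairs = NULL, tajima = TRUE) {
  if (is.null(groups)) {
    groups <- tibble::tibble(accession = gm$samples, group = "all")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  wins <- make_windows(chrom_lengths, size = size)
  glabels <- unique(groups$group)
  if (is.null(pairs) && length(glabels) > 1) {
    pairs <- utils::combn(glabels, 2, simplify = FALSE)
  }
  # window index per site
  wkey <- paste0(wins$chrom, ":", wins$start)
  site_win <- paste0(gm$sites$chrom, ":",
                     (ceiling(gm$sites$pos / size) - 1) * size)
  win_of_site <- match(site_win, wkey)
  wlen <- wins$end - wins$start
  out <- wins
  out$n_snps <- tabulate(win_of_site, nbins = nrow(wins))
  group_rows <- lapply(glabels, function(g) {
    match(groups$accession[groups$group == g], gm$samples)
  })
  names(group_rows) <- glabels
  stats_by_group <- list()
  for (g in glabels) {
    dg <- gm$dosage[group_rows[[g]], , drop = FALSE]
    st <- site_stats_for_group(dg)
    stats_by_group[[g]] <- st
    sp <- site_pi(dg)
    pi_sum <- rep(0, nrow(wins))
    agg <- tapply(sp, win_of_site, sum, na.rm = TRUE)
    pi_sum[as.integer(names(agg))] <- agg
    out[[paste0("pi_", g)]] <- pi_sum / wlen
    # Watterson theta per bp: S / a1 / L with a1 from the mean haplotype count
    seg <- !is.na(sp) & sp > 0
    theta <- rep(0, nrow(wins))
    Sagg <- tapply(seg, win_of_site, sum)
    theta[as.integer(names(Sagg))] <- unlist(Sagg)
    nbar <- round(2 * mean(st$n[st$n >= 2]))
    a1 <- if (is.finite(nbar) && nbar >= 2) sum(1 / seq_len(nbar - 1)) else NA_real_
    out[[paste0("theta_", g)]] <- theta / a1 / wlen
    if (tajima) {
      tg <- vapply(seq_len(nrow(wins)), function(i) {
        if (out$n_snps[i] == 0) return(NA_real_)
        tajimas_d(gm, wins[i, ], samples = gm$samples[group_rows[[g]]])
      }, numeric(1))
      out[[paste0("tajd_", g)]] <- tg
    }
  }
  for (pr in pairs %||% list()) {
    comp <- wc_pair_components(stats_by_group[[pr[1]]], stats_by_group[[pr[2]]])
    num <- rep(NA_real_, nrow(wins))
    den <- rep(NA_real_, nrow(wins))
    nagg <- tapply(comp$a, win_of_site, sum, na.rm = TRUE)
    dagg <- tapply(comp$a + comp$b + comp$c, win_of_site, sum, na.rm = TRUE)
    num[as.integer(names(nagg))] <- nagg
    den[as.integer(names(dagg))] <- dagg
    out[[paste0("fst_", pr[1], "_", pr[2])]] <- num / den
  }
  out
}
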