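#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of diploid dosage vectors over shared
#' non-missing samples (the unphased-genotype r^2 of standard LD-decay
#' tools).
#'
#' @param dosage_a,dosage_b integer dosage vectors (`NA` missing).
#' @return r^2, or `NA` when fewer than two shared calls or either site is
#'   monomorphic in the shared set.
#' @export
pair_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Binned LD-decay curve
#'
#' Evaluates r^2 for all intra-chromosomal site pairs within `max_dist`
#' (uniformly subsampled with a fixed seed above `pair_budget`), averages by
#' distance bin, and smooths the binned means with a rolling median so the
#' decay features are robust to bin noise.
#'
#' @param gm a [geno_matrix()].
#' @param samples optional subset of sample ids.
#' @param max_dist maximum pair distance, bp.
#' @param bin_bp bin width, bp.
#' @param pair_budget maximum number of pairs evaluated.
#' @param smooth_bins rolling-median window (odd; default 5).
#' @param seed seed for pair subsampling.
#' @return Tibble of class `ld_curve`: `bin_start`, `bin_end`, `distance`
#'   (midpoint), `n_pairs`, `mean_r2`, `r2_smooth`; only nonempty bins are
#'   reported.
#' @export
ld_decay_curve <- function(gm, samples = NULL, max_dist = 500000, bin_bp = 1000,
                           pair_budget = 1e7, smooth_bins = 5, seed = 1L) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[match(samples, gm$samples), , drop = FALSE]
  pairs <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < 2) next
    if (length(idx) > 4000) {
      # cap the moment matrices; a seeded uniform thinning of sites keeps the
      # distance mixture of pairs unchanged in expectation
      idx <- withr::with_seed(seed, sort(sample(idx, 4000)))
    }
    pos <- gm$sites$pos[idx]
    # pairwise moment matrices with missing-data masking:
    # for each pair, r is the Pearson correlation over shared non-missing calls
    X <- d[, idx, drop = FALSE]
    mode(X) <- "numeric"
    M <- !is.na(X)
    Xz <- X; Xz[!M] <- 0
    Mn <- matrix(as.numeric(M), nrow(M), ncol(M))
    N <- crossprod(Mn)
    Sxy <- crossprod(Xz)
    Sx <- crossprod(Xz, Mn)    # Sx[i,j] = sum of x_i over samples shared with j
    Sxx <- crossprod(Xz^2, Mn)
    up <- which(upper.tri(N), arr.ind = TRUE)
    dist <- pos[up[, 2]] - pos[up[, 1]]
    keep <- dist > 0 & dist <= max_dist
    up <- up[keep, , drop = FALSE]; dist <- dist[keep]
    if (nrow(up) == 0) next
    n <- N[up]
    sx <- Sx[up]; sy <- t(Sx)[up]
    sxx <- Sxx[up]; syy <- t(Sxx)[up]
    sxy <- Sxy[up]
    cov <- sxy - sx * sy / n
    vx <- sxx - sx^2 / n
    vy <- syy - sy^2 / n
    r2 <- ifelse(n >= 2 & vx > 0 & vy > 0, cov^2 / (vx * vy), NA_real_)
    pairs[[ch]] <- tibble::tibble(dist = dist, r2 = r2)
  }
  if (length(pairs) == 0) stop("fewer than two sites on every chromosome")
  pr <- dplyr::bind_rows(pairs)
  pr <- pr[!is.na(pr$r2), , drop = FALSE]
  if (nrow(pr) > pair_budget) {
    pr <- withr::with_seed(seed, dplyr::slice_sample(pr, n = pair_budget))
  }
  pr$bin <- (ceiling(pr$dist / bin_bp) - 1) * bin_bp
  curve <- pr |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2)) |>
    dplyr::arrange(.data$bin) |>
    dplyr::transmute(bin_start = .data$bin, bin_end = .data$bin + bin_bp,
                     distance = .data$bin + bin_bp / 2,
                     n_pairs = .data$n_pairs, mean_r2 = .data$mean_r2)
  k <- min(smooth_bins, nrow(curve))
  if (k %% 2 == 0) k <- k - 1
  curve$r2_smooth <- if (k >= 3) {
    as.numeric(stats::runmed(curve$mean_r2, k, endrule = "median"))
  } else curve$mean_r2
  class(curve) <- c("ld_curve", class(curve))
  curve
}

#' LD half-decay distance
#'
#' The maximum of the smoothed curve defines `max_r2`; the half-decay
#' distance is the smallest distance at which the smoothed mean r^2 falls to
#' `max_r2 / 2`, linearly interpolated between the straddling bins.
#'
#' @param curve an `ld_curve` (any tibble with `distance` and `r2_smooth` or
#'   `mean_r2`).
#' @return Distance in bp, or `NA` with a warning when the curve never drops
#'   to half its maximum.
#' @export
half_decay_distance <- function(curve) {
  if (nrow(curve) == 0) stop("empty LD curve")
  r2 <- if ("r2_smooth" %in% names(curve)) curve$r2_smooth else curve$mean_r2
  dist <- curve$distance
  i_max <- which.max(r2)
  half <- r2[i_max] / 2
  after <- seq(i_max, length(r2))
  below <- after[r2[after] <= half]
  if (length(below) == 0) {
    warning("curve never drops to half of its maximum")
    return(NA_real_)
  }
  i2 <- below[1]
  if (r2[i2] == half || i2 == i_max) return(dist[i2])
  i1 <- i2 - 1
  dist[i1] + (r2[i1] - half) / (r2[i1] - r2[i2]) * (dist[i2] - dist[i1])
}

#' Summary of an LD curve
#'
#' @param x an `ld_curve`.
#' @param ... unused.
#' @return Tibble with `max_r2`, `half_decay_bp`, `n_pairs`.
#' @export
glance.ld_curve <- function(x, ...) {
  r2 <- if ("r2_smooth" %in% names(x)) x$r2_smooth else x$mean_r2
  tibble::tibble(
    max_r2 = max(r2),
    half_decay_bp = suppressWarnings(half_decay_distance(x)),
    n_pairs = sum(x$n_pairs)
  )
}
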