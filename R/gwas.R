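impute_dosage <- function(gm) {
  X <- gm$dosage
  mode(X) <- "numeric"
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx) > 0) X[idx] <- cm[idx[, 2]]
  X
}

#' Standardized genomic relationship (kinship) matrix
#'
#' VanRaden-type GRM: with per-site ALT frequency `p_k`, standardized dosage
#' `z_ik = (x_ik - 2 p_k) / sqrt(2 p_k (1 - p_k))` and `K = Z Z' / m` over
#' `m` sites. Missing dosages are mean-imputed per site. The result is
#' symmetric positive semi-definite with diagonal mean near 1.
#'
#' @param gm a filtered [geno_matrix()] (monomorphic sites are an error:
#'   they should have been removed by [filter_sites()]).
#' @return `n x n` matrix of class `kinship_matrix`, sample ids as dimnames.
#' @export
kinship_matrix <- function(gm) {
  X <- impute_dosage(gm)
  p <- colMeans(X) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic site(s) present; run filter_sites() first")
  }
  Z <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(gm$samples, gm$samples)
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Principal components of a kinship matrix
#'
#' Eigenvectors of `K` for the `k` largest eigenvalues, scaled by the square
#' root of the eigenvalue (so the coordinates have the variance structure of
#' the sample covariance).
#'
#' @param K a [kinship_matrix()].
#' @param k number of components (`k <= n`).
#' @return Tibble: `accession`, `PC1` ... `PCk`; eigenvalues as attribute
#'   `eigenvalues`.
#' @export
pca_kinship <- function(K, k = 2) {
  n <- nrow(K)
  if (k > n) stop("k exceeds the number of samples")
  e <- eigen(unclass(K), symmetric = TRUE)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  out <- tibble::as_tibble(stats::setNames(as.data.frame(scores),
                                           paste0("PC", seq_len(k))))
  out <- dplyr::bind_cols(tibble::tibble(accession = rownames(K)), out)
  attr(out, "eigenvalues") <- e$values[seq_len(k)]
  out
}

reml_loglik <- function(log10_delta, lambda, Xt, yt, n, q) {
  delta <- 10^log10_delta
  w <- lambda + delta
  A <- crossprod(Xt, Xt / w)
  b <- crossprod(Xt, yt / w)
  beta <- solve(A, b)
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / w)
  sigma_g2 <- rss / (n - q)
  -0.5 * ((n - q) * log(sigma_g2) + sum(log(w)) +
            determinant(A, logarithm = TRUE)$modulus[1] + (n - q))
}

#' Fit the null mixed model by spectral REML
#'
#' Model `y = X beta + u + e`, `u ~ (0, sigma_g^2 K)`, `e ~ (0, sigma_e^2 I)`.
#' `K` is eigendecomposed once; the restricted likelihood is maximized over
#' `delta = sigma_e^2 / sigma_g^2` on a 100-point grid of `log10(delta)` in
#' `[-5, 5]` followed by golden-section refinement (tolerance 1e-6). The
#' cached rotation makes per-marker tests a cheap generalized least squares.
#'
#' @param y numeric phenotype vector (one value per sample, e.g. a BLUP).
#' @param K a [kinship_matrix()] with matching order.
#' @param covariates optional numeric matrix of covariates (an intercept is
#'   always included).
#' @return Object of class `null_mlm`: variance components, `delta`,
#'   restricted log-likelihood, heritability, and the cached
#'   eigendecomposition and rotated design.
#' @export
fit_null_mlm <- function(y, K, covariates = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (stats::var(y) == 0) stop("phenotype is constant")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  q <- qr(X)$rank
  e <- eigen(unclass(K), symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) stop("K is not positive semi-definite")
  lambda <- pmax(e$values, 0)
  U <- e$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  grid <- seq(-5, 5, length.out = 100)
  ll <- vapply(grid, reml_loglik, numeric(1), lambda = lambda, Xt = Xt,
               yt = yt, n = n, q = q)
  i <- which.max(ll)
  if (i == 1 || i == length(grid)) {
    warning("delta at grid boundary; variance components may be unidentifiable")
    opt <- list(maximum = grid[i], objective = ll[i])
  } else {
    opt <- stats::optimize(reml_loglik, c(grid[i - 1], grid[i + 1]),
                           lambda = lambda, Xt = Xt, yt = yt, n = n, q = q,
                           maximum = TRUE, tol = 1e-6)
  }
  delta <- 10^opt$maximum
  w <- lambda + delta
  A <- crossprod(Xt, Xt / w)
  beta <- solve(A, crossprod(Xt, yt / w))
  r <- yt - Xt %*% beta
  sigma_g2 <- sum(r^2 / w) / (n - q)
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * delta, delta = delta,
         heritability = 1 / (1 + delta), loglik = opt$objective,
         U = U, lambda = lambda, yt = yt, Xt = Xt, X = X, n = n, q = q,
         samples = rownames(K)),
    class = "null_mlm"
  )
}

#' @export
print.null_mlm <- function(x, ...) {
  cat(sprintf("<null_mlm> n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$n, x$sigma_g2, x$sigma_e2, x$heritability))
  invisible(x)
}

#' @export
tidy.null_mlm <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_g2", "sigma_e2", "delta"),
    estimate = c(x$sigma_g2, x$sigma_e2, x$delta)
  )
}

#' @export
glance.null_mlm <- function(x, ...) {
  tibble::tibble(heritability = x$heritability, logLik = x$loglik,
                 nobs = x$n)
}

#' EMMAX-style association scan
#'
#' With the null covariance `V = sigma_g^2 K + sigma_e^2 I` held fixed, each
#' SNP is tested by generalized least squares of the phenotype on
#' `[covariates, dosage]` through the cached eigen-rotation; the dosage
#' coefficient gets a Wald t-test with `n - rank(X)` degrees of freedom and
#' a per-marker residual scale (so with `K = I` the scan reduces exactly to
#' ordinary per-SNP regression). Missing dosages are mean-imputed.
#'
#' @param gm a [geno_matrix()] (sample order must match the null fit).
#' @param null a [fit_null_mlm()] object.
#' @return Tibble of class `assoc_scan`: `chrom`, `pos`, `id`, `beta`, `se`,
#'   `p_value`, `minus_log10_p`, `collinear`.
#' @export
emmax_scan <- function(gm, null) {
  stopifnot(inherits(null, "null_mlm"))
  if (!is.null(null$samples) && !identical(gm$samples, null$samples)) {
    stop("sample order differs between genotypes and null model")
  }
  G <- impute_dosage(gm)
  Gt <- crossprod(null$U, G)
  w <- null$lambda + null$delta
  Xt <- null$Xt
  yt <- null$yt
  n <- null$n
  q0 <- ncol(Xt)
  sw <- 1 / w
  XtW <- Xt * sw
  A00 <- crossprod(Xt, XtW)       # q0 x q0
  b0 <- crossprod(XtW, yt)        # q0 x 1
  m <- ncol(Gt)
  beta <- se <- p <- rep(NA_real_, m)
  collinear <- rep(FALSE, m)
  df <- n - q0 - 1
  for (j in seq_len(m)) {
    g <- Gt[, j]
    a01 <- crossprod(XtW, g)              # q0 x 1
    a11 <- sum(g^2 * sw)
    b1 <- sum(g * sw * yt)
    A <- rbind(cbind(A00, a01), c(a01, a11))
    bb <- c(b0, b1)
    sol <- tryCatch(solve(A, bb), error = function(e) NULL)
    if (is.null(sol) || kappa(A) > 1e12) {
      collinear[j] <- TRUE
      p[j] <- 1
      next
    }
    r <- yt - cbind(Xt, g) %*% sol
    rss <- sum(r^2 * sw)
    sigma2 <- rss / df
    vinv <- solve(A)
    se_j <- sqrt(sigma2 * vinv[q0 + 1, q0 + 1])
    beta[j] <- sol[q0 + 1]
    se[j] <- se_j
    tt <- beta[j] / se_j
    p[j] <- 2 * stats::pt(-abs(tt), df)
  }
  out <- tibble::tibble(
    chrom = gm$sites$chrom, pos = gm$sites$pos, id = gm$sites$id,
    beta = beta, se = se, p_value = p,
    minus_log10_p = -log10(p), collinear = collinear
  )
  class(out) <- c("assoc_scan", class(out))
  out
}

#' Significant loci from an association scan
#'
#' Sites with `-log10(p)` strictly above the threshold; significant sites
#' whose positions lie within `collapse_bp` of the previous significant site
#' on the same chromosome are collapsed into one locus, represented by its
#' peak (smallest p) site.
#'
#' @param results an `assoc_scan` tibble.
#' @param threshold `-log10(p)` threshold (default 6, strict `>`).
#' @param collapse_bp collapsing radius, bp (default the +/- 89 kb LD
#'   window).
#' @return Tibble: peak site per locus plus `n_snps_in_locus`,
#'   `locus_start`, `locus_end`.
#' @export
significant_loci <- function(results, threshold = 6, collapse_bp = 89000) {
  sig <- results[!is.na(results$minus_log10_p) &
                   results$minus_log10_p > threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(dplyr::mutate(sig, n_snps_in_locus = integer(),
                                           locus_start = numeric(), locus_end = numeric()))
  sig <- dplyr::arrange(sig, .data$chrom, .data$pos)
  new_locus <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                   diff(sig$pos) > collapse_bp)
  sig$locus <- cumsum(new_locus)
  sig |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(n_snps_in_locus = dplyr::n(),
                  locus_start = min(.data$pos), locus_end = max(.data$pos)) |>
    dplyr::slice_max(.data$minus_log10_p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"locus")
}

#' Candidate genes around an associated locus
#'
#' Genes whose span overlaps `[pos - half_width, pos + half_width]` by at
#' least one bp.
#'
#' @param locus one-row tibble/list with `chrom`, `pos`.
#' @param genes gene models from [read_gff()].
#' @param half_width window half width, bp (default 89 kb).
#' @return Tibble of the overlapping gene models.
#' @export
candidate_window <- function(locus, genes, half_width = 89000) {
  lo <- locus$pos - half_width
  hi <- locus$pos + half_width
  genes[genes$chrom == locus$chrom & genes$start <= hi & genes$end >= lo, , drop = FALSE]
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`.
#'
#' @param results an `assoc_scan` tibble or a numeric vector of p-values.
#' @return `lambda`.
#' @export
genomic_inflation <- function(results) {
  p <- if (is.numeric(results)) results else results$p_value
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values")
  if (length(p) < 100) warning("fewer than 100 tests; lambda is noisy")
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}
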