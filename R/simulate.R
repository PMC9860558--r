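#' Simulation configuration for a structured diversity panel
#'
#' Bundles and validates the parameters of the synthetic-data generator: a
#' Balding-Nichols model of subpopulation allele frequencies around a shared
#' ancestral frequency, optional planted selective sweeps, and a quantitative
#' trait measured across environments.
#'
#' @param pop_sizes named or unnamed integer vector of diploid sample counts
#'   per subpopulation (each >= 2).
#' @param F per-population Balding-Nichols divergence in `[0, 1)`; recycled
#'   across populations. `F = 0` makes a population's frequencies equal the
#'   ancestral frequency.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param snp_density expected SNPs per bp (sites are placed uniformly).
#' @param freq_range range of the uniform ancestral-frequency law; the default
#'   `c(0.05, 0.95)` keeps simulated sites away from the MAF filter boundary.
#' @param sweep_specs list of sweep descriptions, each a list with elements
#'   `pop`, `chrom`, `start`, `end` (1-based bp, inclusive) and `intensity`
#'   in `[0, 1]`.
#' @param missing_rate per-genotype missing probability (default 0.02).
#' @param depth_mean mean of the Poisson per-genotype depth model (default 25,
#'   the scale of a deep crop resequencing panel); `NULL` disables depth.
#' @param ts_prob probability that a simulated SNP is a transition.
#' @param seed integer seed; every simulation product is deterministic in it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pop_sizes = c(SC = 61, MC = 257, NC = 92),
                       F = 0.1,
                       chrom_lengths = c(chr1 = 1e6),
                       snp_density = 2e-3,
                       freq_range = c(0.05, 0.95),
                       sweep_specs = list(),
                       missing_rate = 0.02,
                       depth_mean = 25,
                       ts_prob = 2 / 3,
                       seed = 1L) {
  if (any(pop_sizes < 2)) stop("each population needs >= 2 diploid samples")
  F <- rep_len(F, length(pop_sizes))
  if (any(F < 0 | F >= 1)) stop("F must lie in [0, 1)")
  if (is.null(names(pop_sizes))) names(pop_sizes) <- paste0("pop", seq_along(pop_sizes))
  if (is.null(names(chrom_lengths))) names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  stopifnot(all(chrom_lengths >= 1), snp_density > 0,
            length(freq_range) == 2, freq_range[1] > 0, freq_range[2] < 1)
  for (sw in sweep_specs) {
    stopifnot(sw$pop %in% names(pop_sizes), sw$chrom %in% names(chrom_lengths))
    if (sw$intensity < 0 || sw$intensity > 1) stop("sweep intensity must lie in [0, 1]")
    if (sw$start < 1 || sw$end > chrom_lengths[[sw$chrom]] || sw$start >= sw$end) {
      stop("sweep interval outside chromosome bounds")
    }
  }
  structure(
    list(pop_sizes = pop_sizes, F = F, chrom_lengths = chrom_lengths,
         snp_density = snp_density, freq_range = freq_range,
         sweep_specs = sweep_specs, missing_rate = missing_rate,
         depth_mean = depth_mean, ts_prob = ts_prob, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' SNP density that yields a target per-bp nucleotide diversity
#'
#' Under the generator's uniform ancestral-frequency law on `[a, b]`, the
#' expected heterozygosity of a site is `E[2p(1-p)] = 2(E[p] - E[p^2])`.
#' The density of segregating sites needed for a target per-bp diversity is
#' the target divided by that expectation.
#'
#' @param target_pi desired true per-bp nucleotide diversity.
#' @param freq_range uniform law support, default `c(0.05, 0.95)`.
#' @return SNPs per bp.
#' @export
calibrate_snp_density <- function(target_pi, freq_range = c(0.05, 0.95)) {
  a <- freq_range[1]; b <- freq_range[2]
  m1 <- (a + b) / 2
  m2 <- (b - a)^2 / 12 + m1^2
  e_het <- 2 * (m1 - m2)
  target_pi / e_het
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

draw_alleles <- function(n, ts_prob) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  is_ts <- stats::runif(n) < ts_prob
  alt <- character(n)
  alt[is_ts] <- transition_of[ref[is_ts]]
  ntv <- sum(!is_ts)
  if (ntv > 0) {
    tv_choices <- rbind(
      c(A = "C", C = "A", G = "C", T = "A"),
      c(A = "T", C = "G", G = "T", T = "G")
    )
    pick <- sample(1:2, ntv, replace = TRUE)
    alt[!is_ts] <- tv_choices[cbind(pick, match(ref[!is_ts], colnames(tv_choices)))]
  }
  list(ref = ref, alt = alt)
}

#' Simulate structured genotypes under the Balding-Nichols model
#'
#' For each site an ancestral ALT frequency `p` is drawn uniformly on
#' `freq_range`; each subpopulation's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance `F p(1-p)`), so that the
#' Weir-Cockerham FST between two populations simulated at divergence `F`
#' estimates `F`. Diploid genotypes are binomial in the population frequency
#' (Hardy-Weinberg within population). Any sweeps in the configuration are
#' planted afterwards via [plant_sweep()].
#'
#' @param config a [sim_config()].
#' @return A list of class `pop_sim` with elements `gm` ([geno_matrix()]),
#'   `groups` (tibble `accession`, `group`), `truth` (ancestral and
#'   per-population frequencies, planted sweeps, causal sites) and `config`.
#' @export
simulate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim <- withr::with_seed(config$seed, {
    n_pops <- length(config$pop_sizes)
    pops <- names(config$pop_sizes)
    site_list <- lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      n <- max(1L, round(L * config$snp_density))
      pos <- sort(sample.int(L, min(n, L)))
      tibble::tibble(chrom = ch, pos = pos)
    })
    sites <- dplyr::bind_rows(site_list)
    m <- nrow(sites)
    al <- draw_alleles(m, config$ts_prob)
    sites$ref <- al$ref
    sites$alt <- al$alt
    p_anc <- stats::runif(m, config$freq_range[1], config$freq_range[2])
    pop_freq <- matrix(NA_real_, m, n_pops, dimnames = list(NULL, pops))
    for (k in seq_len(n_pops)) {
      Fk <- config$F[k]
      pop_freq[, k] <- if (Fk == 0) p_anc else {
        stats::rbeta(m, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
      }
    }
    n_tot <- sum(config$pop_sizes)
    dosage <- matrix(NA_integer_, n_tot, m)
    grp <- rep(pops, config$pop_sizes)
    for (k in seq_len(n_pops)) {
      rows <- which(grp == pops[k])
      dosage[rows, ] <- matrix(
        stats::rbinom(length(rows) * m, 2L, rep(pop_freq[, k], each = length(rows))),
        length(rows), m
      )
    }
    samples <- paste0("acc", sprintf("%03d", seq_len(n_tot)))
    depth <- NULL
    if (!is.null(config$depth_mean)) {
      depth <- matrix(stats::rpois(n_tot * m, config$depth_mean), n_tot, m)
    }
    if (config$missing_rate > 0) {
      dosage[stats::runif(n_tot * m) < config$missing_rate] <- NA_integer_
    }
    gm <- geno_matrix(dosage, sites, samples = samples, depth = depth)
    # geno_matrix sorts sites; positions were generated sorted per chrom, and
    # chromosome blocks are bound in name order only if names sort; re-align truth
    ord <- order(sites$chrom, sites$pos)
    list(
      gm = gm,
      groups = tibble::tibble(accession = samples, group = grp),
      truth = list(
        ancestral_freq = p_anc[ord],
        pop_freq = pop_freq[ord, , drop = FALSE],
        site_id = gm$sites$id,
        sweeps = tibble::tibble(pop = character(), chrom = character(),
                                start = numeric(), end = numeric(),
                                intensity = numeric()),
        causal = NULL
      ),
      config = config
    )
  })
  class(sim) <- "pop_sim"
  for (i in seq_along(config$sweep_specs)) {
    sim <- plant_sweep(sim, config$sweep_specs[[i]],
                       seed = config$seed + 7919L * i)
  }
  sim
}

#' @export
print.pop_sim <- function(x, ...) {
  cat(sprintf("<pop_sim> %d samples in %d population(s), %d sites, %d planted sweep(s)\n",
              length(x$gm$samples), length(unique(x$groups$group)),
              nrow(x$gm$sites), nrow(x$truth$sweeps)))
  invisible(x)
}

#' Plant a selective sweep into a simulated panel
#'
#' Within the interval, the focal population's allele frequencies are pushed
#' a fraction `intensity` of the way to fixation (`p <- p(1-intensity)`
#' toward loss, `p <- 1-(1-p)(1-intensity)` toward fixation), and the focal
#' population's genotypes at those sites are redrawn from the distorted
#' frequencies (missingness pattern preserved). The default `"hitchhike"`
#' direction fixes the allele with probability equal to its frequency —
#' the marginal frequency effect of a single haplotype sweeping to high
#' frequency — which jointly reduces focal-group diversity and raises FST
#' against the background. The `"nearer"` policy (always toward the closer
#' boundary) reduces diversity but produces much weaker differentiation,
#' because the focal frequency moves to the boundary the background is
#' already nearest to; it is kept for comparison.
#'
#' @param sim a `pop_sim` from [simulate_structured_genotypes()].
#' @param spec list with `pop`, `chrom`, `start`, `end`, `intensity`, and
#'   optionally `direction`.
#' @param direction `"hitchhike"` (default) or `"nearer"`; overridden by
#'   `spec$direction` when present.
#' @param seed seed for the genotype redraw (default derived from the
#'   simulation seed and the number of sweeps already planted).
#' @param window_size used only to warn when the interval is shorter than one
#'   scan window.
#' @return The modified `pop_sim` with the truth table updated.
#' @export
plant_sweep <- function(sim, spec, direction = c("hitchhike", "nearer"),
                        seed = NULL, window_size = 10000) {
  direction <- spec$direction %||% match.arg(direction)
  stopifnot(inherits(sim, "pop_sim"))
  if (spec$intensity == 0) return(sim)
  if (spec$end - spec$start + 1 < window_size) {
    warning("sweep interval shorter than one scan window; it may not be called")
  }
  if (is.null(seed)) seed <- sim$config$seed + 7919L * (nrow(sim$truth$sweeps) + 1L)
  gm <- sim$gm
  idx <- which(gm$sites$chrom == spec$chrom &
                 gm$sites$pos >= spec$start & gm$sites$pos <= spec$end)
  rows <- which(sim$groups$group == spec$pop)
  if (length(rows) == 0) stop("unknown focal population: ", spec$pop)
  if (length(idx) > 0) {
    p <- sim$truth$pop_freq[idx, spec$pop]
    keep <- 1 - spec$intensity
    withr::with_seed(seed, {
      toward_one <- if (direction == "hitchhike") {
        stats::runif(length(p)) < p
      } else {
        p >= 0.5
      }
      p_new <- ifelse(toward_one, 1 - (1 - p) * keep, p * keep)
      sim$truth$pop_freq[idx, spec$pop] <- p_new
      redraw <- matrix(
        stats::rbinom(length(rows) * length(idx), 2L,
                      rep(p_new, each = length(rows))),
        length(rows), length(idx)
      )
      old <- gm$dosage[rows, idx, drop = FALSE]
      redraw[is.na(old)] <- NA_integer_
      gm$dosage[rows, idx] <- redraw
    })
    sim$gm <- gm
  }
  sim$truth$sweeps <- dplyr::bind_rows(
    sim$truth$sweeps,
    tibble::tibble(pop = spec$pop, chrom = spec$chrom, start = spec$start,
                   end = spec$end, intensity = spec$intensity)
  )
  sim
}

#' True expected per-window diversity from the simulation truth table
#'
#' Expected per-bp diversity of a window is the sum over its sites of the
#' population-level heterozygosity `2p(1-p)` divided by the window length.
#'
#' @param sim a `pop_sim`.
#' @param size window size in bp.
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open) and one
#'   `pi_<pop>` column per population.
#' @export
true_window_pi <- function(sim, size = 10000) {
  wins <- make_windows(sim$config$chrom_lengths, size = size)
  het <- 2 * sim$truth$pop_freq * (1 - sim$truth$pop_freq)
  sites <- sim$gm$sites
  out <- wins
  for (pop in colnames(het)) {
    out[[paste0("pi_", pop)]] <- vapply(seq_len(nrow(wins)), function(i) {
      in_w <- sites$chrom == wins$chrom[i] &
        sites$pos > wins$start[i] & sites$pos <= wins$end[i]
      sum(het[in_w, pop]) / (wins$end[i] - wins$start[i])
    }, numeric(1))
  }
  out
}

#' Simulate genotypes with a neutral site-frequency spectrum
#'
#' Draws, for each segregating site, a derived-allele count `i` among the
#' `2n` haplotypes with probability proportional to `1/i` (the standard
#' neutral SFS), assigns the derived alleles to haplotypes at random, and
#' pairs haplotypes into diploids. Both the pairwise estimator of theta and
#' Watterson's estimator are unbiased under this law, so Tajima's D over
#' many unlinked windows is centred at zero; this is the null generator for
#' frequency-spectrum tests.
#'
#' @param n_samples diploid sample count.
#' @param n_sites number of segregating sites.
#' @param chrom_length chromosome length in bp over which sites are placed.
#' @param seed integer seed.
#' @return A [geno_matrix()].
#' @export
simulate_sfs_genotypes <- function(n_samples, n_sites, chrom_length = 1e6, seed = 1L) {
  withr::with_seed(seed, {
    m_hap <- 2L * n_samples
    pr <- 1 / seq_len(m_hap - 1L)
    counts <- sample.int(m_hap - 1L, n_sites, replace = TRUE, prob = pr)
    hap <- matrix(0L, m_hap, n_sites)
    for (j in seq_len(n_sites)) {
      hap[sample.int(m_hap, counts[j]), j] <- 1L
    }
    dosage <- hap[seq(1, m_hap, by = 2), , drop = FALSE] +
      hap[seq(2, m_hap, by = 2), , drop = FALSE]
    pos <- sort(sample.int(chrom_length, n_sites))
    al <- draw_alleles(n_sites, 2 / 3)
    geno_matrix(dosage,
                tibble::tibble(chrom = "chr1", pos = pos, ref = al$ref, alt = al$alt),
                samples = paste0("acc", sprintf("%03d", seq_len(n_samples))))
  })
}

#' Simulate genotypes with distance-decaying linkage disequilibrium
#'
#' Haplotypes are mosaics of a small founder pool: each haplotype starts on a
#' random founder and, between adjacent sites at distance `d` bp, switches to
#' a random founder with probability `1 - (1 - recomb_prob)^d`. Mean r^2
#' between sites decays with distance at a scale set by `recomb_prob` and the
#' founder count; `recomb_prob = 0` gives complete LD within founder classes.
#'
#' @param n_founders founder haplotype count (>= 2).
#' @param recomb_prob per-bp switch probability.
#' @param n_samples diploid samples to emit.
#' @param n_sites number of sites.
#' @param chrom_length chromosome length in bp.
#' @param freq_range uniform law for founder allele frequencies.
#' @param seed integer seed.
#' @return A [geno_matrix()].
#' @export
simulate_haplotype_ld <- function(n_founders, recomb_prob, n_samples,
                                  n_sites = 200, chrom_length = 5e5,
                                  freq_range = c(0.05, 0.95), seed = 1L) {
  if (n_founders < 2) stop("need at least 2 founder haplotypes")
  if (recomb_prob < 0) stop("recomb_prob must be >= 0")
  withr::with_seed(seed, {
    pos <- sort(sample.int(chrom_length, n_sites))
    p <- stats::runif(n_sites, freq_range[1], freq_range[2])
    founders <- matrix(
      stats::rbinom(n_founders * n_sites, 1L, rep(p, each = n_founders)),
      n_founders, n_sites
    )
    n_hap <- 2L * n_samples
    cur <- sample.int(n_founders, n_hap, replace = TRUE)
    hap <- matrix(0L, n_hap, n_sites)
    hap[, 1] <- founders[cbind(cur, 1L)]
    if (n_sites > 1) {
      d <- diff(pos)
      p_switch <- 1 - (1 - recomb_prob)^d
      for (j in 2:n_sites) {
        sw <- stats::runif(n_hap) < p_switch[j - 1]
        if (any(sw)) cur[sw] <- sample.int(n_founders, sum(sw), replace = TRUE)
        hap[, j] <- founders[cbind(cur, j)]
      }
    }
    dosage <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
      hap[seq(2, n_hap, by = 2), , drop = FALSE]
    al <- draw_alleles(n_sites, 2 / 3)
    geno_matrix(dosage,
                tibble::tibble(chrom = "chr1", pos = pos, ref = al$ref, alt = al$alt),
                samples = paste0("acc", sprintf("%03d", seq_len(n_samples))))
  })
}

#' Simulate a quantitative trait over multiple environments
#'
#' Genetic value of accession `i` is the dosage-weighted sum of causal-site
#' effects; the phenotype in environment `j` is
#' `y_ij = mu + env_j + g_i + e_ij`, with residual variance set so that the
#' single-environment heritability `var(g) / (var(g) + var(e))` equals `h2`.
#' Defaults put the trait on the mg/g scale of seed lignan content.
#'
#' @param gm a [geno_matrix()] (missing dosages are mean-imputed for the
#'   genetic value).
#' @param causal_ids site ids (from `gm$sites$id`) of causal SNPs.
#' @param effects per-ALT-allele effects, trait units; recycled to
#'   `length(causal_ids)`.
#' @param h2 single-environment heritability in `[0, 1]`.
#' @param n_envs number of environments.
#' @param mu grand mean, trait units (default 3 mg/g).
#' @param env_effects fixed environment effects; default drawn `N(0, 0.5)`.
#' @param trait trait label for the output table.
#' @param seed integer seed.
#' @return List with `phenotypes` (tibble `accession`, `environment`,
#'   `trait`, `value`) and `truth` (tibble `accession`, `g`; plus the causal
#'   map as attributes `causal_ids`, `effects`).
#' @export
simulate_trait <- function(gm, causal_ids, effects, h2 = 0.5, n_envs = 6,
                           mu = 3, env_effects = NULL, trait = "sesamin",
                           seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"), h2 >= 0, h2 <= 1)
  miss <- setdiff(causal_ids, gm$sites$id)
  if (length(miss) > 0) stop("causal ids not in site table: ", paste(miss, collapse = ", "))
  effects <- rep_len(effects, length(causal_ids))
  withr::with_seed(seed, {
    X <- gm$dosage[, match(causal_ids, gm$sites$id), drop = FALSE]
    for (j in seq_len(ncol(X))) {
      xm <- mean(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- xm
    }
    g <- drop(X %*% effects)
    var_g <- stats::var(g)
    if (h2 == 0 || var_g == 0) {
      if (any(effects != 0) && h2 == 0) {
        warning("h2 = 0: residual variance set to 1; effects ignored in noise calibration")
      }
      sigma_e <- 1
    } else {
      sigma_e <- sqrt(var_g * (1 - h2) / h2)
    }
    if (is.null(env_effects)) env_effects <- stats::rnorm(n_envs, 0, 0.5)
    env_effects <- rep_len(env_effects, n_envs)
    envs <- paste0("env", seq_len(n_envs))
    n <- length(gm$samples)
    ph <- tidyr::expand_grid(accession = gm$samples, environment = envs)
    ph$trait <- trait
    ph$value <- mu + env_effects[match(ph$environment, envs)] +
      unname(g[match(ph$accession, gm$samples)]) +
      stats::rnorm(nrow(ph), 0, sigma_e)
    truth <- tibble::tibble(accession = gm$samples, g = g)
    attr(truth, "causal_ids") <- causal_ids
    attr(truth, "effects") <- effects
    list(phenotypes = ph, truth = truth)
  })
}

#' Synthesize gene models tiling given intervals
#'
#' Builds a deterministic set of two-exon protein-coding gene models that tile
#' the supplied intervals (e.g. planted sweep regions) plus regularly spaced
#' background genes, so interval-to-gene queries have known truth.
#'
#' @param chrom_lengths named chromosome lengths, bp.
#' @param focal_intervals tibble with `chrom`, `start`, `end` (1-based); genes
#'   are placed every `focal_spacing` bp inside each interval.
#' @param focal_spacing spacing of genes inside focal intervals.
#' @param background_spacing spacing of background genes elsewhere.
#' @param gene_length span of each synthesized gene, bp.
#' @return A gene-model tibble as returned by [read_gff()].
#' @export
simulate_gene_models <- function(chrom_lengths, focal_intervals = NULL,
                                 focal_spacing = 10000, background_spacing = 50000,
                                 gene_length = 3000) {
  rows <- list()
  k <- 0L
  add_gene <- function(chrom, start, strand, tag) {
    k <<- k + 1L
    end <- start + gene_length - 1
    # two exons; CDS length divisible by 3
    e1 <- c(start, start + 899)
    e2 <- c(start + 1500, end)
    cds1 <- c(start + 300, start + 899)       # 600 bp
    cds2 <- c(start + 1500, start + 2399)     # 900 bp
    rows[[k]] <<- tibble::tibble(
      gene_id = sprintf("G%s_%03d_%s", chrom, k, tag),
      chrom = chrom, strand = strand, start = start, end = end,
      exons = list(tibble::tibble(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))),
      cds = list(tibble::tibble(start = c(cds1[1], cds2[1]), end = c(cds1[2], cds2[2])))
    )
  }
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    focal <- if (is.null(focal_intervals)) NULL else
      focal_intervals[focal_intervals$chrom == ch, , drop = FALSE]
    if (!is.null(focal) && nrow(focal) > 0) {
      for (i in seq_len(nrow(focal))) {
        starts <- seq(focal$start[i], focal$end[i] - gene_length, by = focal_spacing)
        for (s in starts) add_gene(ch, s, if (s %% 2 == 0) "+" else "-", "sweep")
      }
    }
    bg <- seq(1, L - gene_length, by = background_spacing)
    if (!is.null(focal) && nrow(focal) > 0) {
      in_focal <- vapply(bg, function(s) {
        any(s <= focal$end & (s + gene_length - 1) >= focal$start)
      }, logical(1))
      bg <- bg[!in_focal]
    }
    for (s in bg) add_gene(ch, s, "+", "bg")
  }
  dplyr::arrange(dplyr::bind_rows(rows), chrom, start)
}

#' Write a simulated panel to standard file formats
#'
#' Emits VCF v4.2 (GT:DP), GFF3 gene models, a FASTA reference consistent
#' with the VCF REF alleles, phenotype and group CSVs, and a JSON truth table
#' (planted sweeps, causal sites, per-population frequencies omitted for
#' size). The files round-trip through the package's readers.
#'
#' @param sim a `pop_sim`.
#' @param outdir output directory (created if needed).
#' @param phenotypes optional phenotype tibble from [simulate_trait()].
#' @param genes optional gene-model tibble; default synthesizes models tiling
#'   the planted sweeps via [simulate_gene_models()].
#' @param truth_extra named list merged into the truth JSON.
#' @param force overwrite an existing non-empty directory.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixtures <- function(sim, outdir, phenotypes = NULL, genes = NULL,
                           truth_extra = list(), force = FALSE) {
  stopifnot(inherits(sim, "pop_sim"))
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genes)) {
    genes <- simulate_gene_models(sim$config$chrom_lengths,
                                  focal_intervals = sim$truth$sweeps)
  }
  paths <- list(
    vcf = file.path(outdir, "genotypes.vcf"),
    gff = file.path(outdir, "genes.gff3"),
    fasta = file.path(outdir, "reference.fa"),
    phenotypes = file.path(outdir, "phenotypes.csv"),
    groups = file.path(outdir, "groups.csv"),
    truth = file.path(outdir, "truth.json")
  )
  write_vcf(sim$gm, paths$vcf)
  write_gff3(genes, paths$gff)
  ref <- withr::with_seed(sim$config$seed + 104729L, {
    seqs <- lapply(names(sim$config$chrom_lengths), function(ch) {
      L <- sim$config$chrom_lengths[[ch]]
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      here <- sim$gm$sites$chrom == ch
      s[sim$gm$sites$pos[here]] <- sim$gm$sites$ref[here]
      paste(s, collapse = "")
    })
    names(seqs) <- names(sim$config$chrom_lengths)
    seqs
  })
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(ref)), paths$fasta)
  if (!is.null(phenotypes)) {
    readr::write_csv(phenotypes, paths$phenotypes)
  } else {
    paths$phenotypes <- NULL
  }
  readr::write_csv(sim$groups, paths$groups)
  truth <- c(list(
    sweeps = sim$truth$sweeps,
    ancestral_freq = sim$truth$ancestral_freq,
    site_id = sim$truth$site_id,
    seed = sim$config$seed
  ), truth_extra)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
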