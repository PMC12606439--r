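#' Cross design for the synthetic segregant panel
#'
#' Bundles the parameters of a simulated haploid two-parent cross: panel
#' size, additive QTLs with per-environment multipliers, trait noise,
#' sorted-tail fraction and sequencing depth. Per-environment multipliers in
#' {-1, 0, +1} construct sign-change, presence/absence and no-GxE loci by
#' design.
#'
#' @param n_segregants number of haploid segregants in the panel.
#' @param qtls data.frame with columns `chrom`, `pos` (bp), `effect`
#'   (additive effect in trait SD units) and one numeric multiplier column
#'   per environment name. `NULL` for a null cross with no QTLs.
#' @param residual_sd trait noise SD (default 1).
#' @param tail_fraction fraction of the panel sorted into each phenotypic
#'   tail (default 0.02, the 2% high/low sort).
#' @param mean_depth expected sequencing reads per marker per pool.
#' @param sort_noise_sd optional SD of per-cell noise added to the trait at
#'   sorting time only (FACS sorts single cells, not segregant means);
#'   default 0 selects on the trait directly.
#' @return object of class `cross_design`.
#' @export
cross_design <- function(n_segregants, qtls = NULL, residual_sd = 1,
                         tail_fraction = 0.02, mean_depth = 100,
                         sort_noise_sd = 0) {
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must be in (0, 0.5)")
  }
  if (n_segregants < 2 / tail_fraction) {
    stop("n_segregants too small for the requested tail_fraction")
  }
  if (residual_sd <= 0) stop("residual_sd must be positive")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  structure(
    list(n_segregants = n_segregants, qtls = qtls,
         residual_sd = residual_sd, tail_fraction = tail_fraction,
         mean_depth = mean_depth, sort_noise_sd = sort_noise_sd),
    class = "cross_design"
  )
}

#' Simulate segregant genotypes under Haldane recombination
#'
#' Each segregant is one meiotic product. Per chromosome the parental phase
#' at the left end is BY or RM with probability 1/2; crossover breakpoints
#' follow a Poisson process with expected count `length_bp / bp_per_cM / 100`
#' (Haldane model, no interference); the phase alternates at each breakpoint
#' and every marker inherits the phase of its interval.
#'
#' @param genome a `genome_map`.
#' @param n number of segregants (>= 1).
#' @param seed integer seed.
#' @return integer matrix (`n` x markers), 0 = BY, 1 = RM; column names are
#'   `chrom:pos`.
#' @export
simulate_segregant_genotypes <- function(genome, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(inherits(genome, "genome_map"))
  set.seed(seed)
  cols <- lapply(names(genome$chrom_lengths), function(chrom) {
    len <- genome$chrom_lengths[[chrom]]
    markers <- genome$markers[[chrom]]
    morgans <- len / genome$bp_per_cM / 100
    geno <- matrix(0L, nrow = n, ncol = length(markers))
    start_phase <- stats::rbinom(n, 1, 0.5)
    n_breaks <- stats::rpois(n, morgans)
    for (i in seq_len(n)) {
      if (n_breaks[i] == 0) {
        geno[i, ] <- start_phase[i]
      } else {
        breaks <- sort(stats::runif(n_breaks[i], 0, len))
        crossings <- findInterval(markers, breaks)
        geno[i, ] <- (start_phase[i] + crossings) %% 2L
      }
    }
    colnames(geno) <- paste0(chrom, ":", markers)
    geno
  })
  do.call(cbind, cols)
}

# Column index of the marker nearest a QTL position (ties -> left marker).
nearest_marker_index <- function(genome, chrom, pos) {
  markers <- genome$markers[[chrom]]
  if (is.null(markers)) stop("unknown chromosome ", chrom)
  j <- which.min(abs(markers - pos))
  offset <- 0L
  for (c2 in names(genome$markers)) {
    if (c2 == chrom) break
    offset <- offset + length(genome$markers[[c2]])
  }
  offset + j
}

#' Simulate a quantitative trait with environment-dependent additive QTLs
#'
#' `trait_i = sum_q effect_q * mult_q(env) * s_iq + eps_i` with
#' `s_iq = +1/2` for RM at the marker nearest QTL q, `-1/2` for BY, and
#' `eps ~ N(0, residual_sd^2)`. A positive effect times the RM genotype
#' raises the trait (trait = UPS activity).
#'
#' @param genotypes matrix from [simulate_segregant_genotypes()].
#' @param genome the `genome_map` used to generate `genotypes`.
#' @param design a `cross_design`.
#' @param environment environment name; must match a multiplier column of
#'   `design$qtls` when QTLs are present.
#' @param seed integer seed.
#' @return numeric trait vector, one value per segregant.
#' @export
simulate_trait <- function(genotypes, genome, design, environment, seed = 1) {
  set.seed(seed)
  n <- nrow(genotypes)
  trait <- stats::rnorm(n, 0, design$residual_sd)
  qtls <- design$qtls
  if (!is.null(qtls) && nrow(qtls) > 0) {
    if (!environment %in% names(qtls)) {
      stop("unknown environment name: ", environment)
    }
    for (q in seq_len(nrow(qtls))) {
      j <- nearest_marker_index(genome, qtls$chrom[q], qtls$pos[q])
      s <- genotypes[, j] - 0.5
      trait <- trait + qtls$effect[q] * qtls[[environment]][q] * s
    }
  }
  trait
}

#' Select the phenotypic tails of a trait distribution
#'
#' High pool = the `ceiling(tail_fraction * n)` largest trait values, low
#' pool = the same count of smallest values. Ties are broken by index order
#' (stable sort on value then index), which keeps the two pools disjoint
#' even on constant traits.
#'
#' @param trait numeric vector.
#' @param tail_fraction fraction per tail, in (0, 0.5).
#' @return list with integer index vectors `high` and `low`.
#' @export
select_tails <- function(trait, tail_fraction) {
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must be in (0, 0.5): tails would overlap")
  }
  n <- length(trait)
  k <- ceiling(tail_fraction * n)
  if (2 * k > n) stop("tails overlap for this panel size")
  ord <- order(trait, seq_len(n))
  list(high = sort(ord[(n - k + 1):n]), low = sort(ord[1:k]))
}

#' Simulate pooled sequencing read counts for sorted pools
#'
#' Per marker and pool: the true pool RM frequency is the RM fraction among
#' pool members; depth is Poisson(`mean_depth`) and the RM read count is
#' Binomial(depth, frequency). Zero-depth markers are permitted and handled
#' downstream.
#'
#' @param genotypes segregant genotype matrix (0/1).
#' @param high,low integer vectors of pool member indices.
#' @param genome the `genome_map` (provides chrom/pos labels).
#' @param mean_depth expected reads per marker.
#' @param seed integer seed.
#' @return data.frame `chrom, pos, high_BY, high_RM, low_BY, low_RM`
#'   (an allele-count track).
#' @export
simulate_read_counts <- function(genotypes, high, low, genome, mean_depth,
                                 seed = 1) {
  if (length(high) == 0 || length(low) == 0) stop("pools must be non-empty")
  set.seed(seed)
  f_high <- colMeans(genotypes[high, , drop = FALSE])
  f_low <- colMeans(genotypes[low, , drop = FALSE])
  m <- ncol(genotypes)
  d_high <- stats::rpois(m, mean_depth)
  d_low <- stats::rpois(m, mean_depth)
  rm_high <- stats::rbinom(m, d_high, f_high)
  rm_low <- stats::rbinom(m, d_low, f_low)
  lab <- strsplit(colnames(genotypes), ":", fixed = TRUE)
  data.frame(
    chrom = vapply(lab, `[`, "", 1),
    pos = as.numeric(vapply(lab, `[`, "", 2)),
    high_BY = d_high - rm_high, high_RM = rm_high,
    low_BY = d_low - rm_low, low_RM = rm_low,
    stringsAsFactors = FALSE
  )
}

#' Simulate one replicate of a full cross in several environments
#'
#' Generates one segregant panel (a biological replicate = an independent
#' cross), then per environment: the trait, the sorted 2% tails (with
#' optional per-cell sorting noise) and pooled read counts.
#'
#' @param genome a `genome_map`.
#' @param design a `cross_design`.
#' @param environments character vector of environment names.
#' @param seed master seed; stage seeds are derived by fixed offsets.
#' @return list with `genotypes`, and per environment `trait`, `pools`,
#'   `counts`; plus `truth` (the QTL table).
#' @export
simulate_cross <- function(genome, design, environments, seed = 1) {
  genotypes <- simulate_segregant_genotypes(genome, design$n_segregants,
                                            seed = seed)
  envs <- lapply(seq_along(environments), function(e) {
    env <- environments[e]
    trait <- simulate_trait(genotypes, genome, design, env,
                            seed = seed + 1000L * e)
    sort_value <- trait
    if (design$sort_noise_sd > 0) {
      set.seed(seed + 1000L * e + 500L)
      sort_value <- trait + stats::rnorm(length(trait), 0,
                                         design$sort_noise_sd)
    }
    pools <- select_tails(sort_value, design$tail_fraction)
    counts <- simulate_read_counts(genotypes, pools$high, pools$low, genome,
                                   design$mean_depth,
                                   seed = seed + 1000L * e + 1L)
    list(trait = trait, pools = pools, counts = counts)
  })
  names(envs) <- environments
  list(genotypes = genotypes, environments = envs, truth = design$qtls)
}

#' Simulate per-cell cytometry events for one replicate sample
#'
#' Events carry an acquisition time (uniform over the sample window), a
#' log-normal forward scatter, a log-normal GFP level and
#' `RFP = GFP * 2^-(activity + drift * time + noise)`, so that the raw
#' per-cell `-log2(RFP/GFP)` equals the configured activity plus drift and
#' noise. A low-nitrogen flag splits the FSC distribution into two modes
#' (the upper at twice the size scale), emulating incompletely budded cells.
#'
#' @param activity configured mean activity (time-corrected units).
#' @param gfp_level median GFP level (> 0).
#' @param n_events number of events (>= 100).
#' @param drift_slope drift of the raw ratio per second (default 0).
#' @param noise_sd per-cell activity noise SD (default 0.3).
#' @param fsc_scale size scale of the main FSC mode (default 100).
#' @param fsc_sdlog log-scale SD of FSC (default 0.1).
#' @param gfp_sdlog log-scale SD of GFP (default 0.2).
#' @param window_s acquisition window in seconds (default 60).
#' @param low_nitrogen if TRUE, FSC is a 50/50 mixture of modes at
#'   `fsc_scale` and `2 * fsc_scale`.
#' @param seed integer seed.
#' @return data.frame `time_s, fsc, ssc, gfp, rfp` (an event table).
#' @export
simulate_cytometry_events <- function(activity, gfp_level, n_events = 5000,
                                      drift_slope = 0, noise_sd = 0.3,
                                      fsc_scale = 100, fsc_sdlog = 0.1,
                                      gfp_sdlog = 0.2, window_s = 60,
                                      low_nitrogen = FALSE, seed = 1) {
  if (gfp_level <= 0) stop("gfp_level must be positive")
  if (n_events < 100) stop("need at least 100 events")
  set.seed(seed)
  time_s <- stats::runif(n_events, 0, window_s)
  scale <- rep(fsc_scale, n_events)
  if (low_nitrogen) {
    upper <- stats::rbinom(n_events, 1, 0.5) == 1
    scale[upper] <- 2 * fsc_scale
  }
  fsc <- stats::rlnorm(n_events, log(scale), fsc_sdlog)
  ssc <- stats::rlnorm(n_events, log(scale / 2), fsc_sdlog)
  gfp <- stats::rlnorm(n_events, log(gfp_level), gfp_sdlog)
  noise <- if (noise_sd > 0) stats::rnorm(n_events, 0, noise_sd) else 0
  rfp <- gfp * 2^(-(activity + drift_slope * time_s + noise))
  data.frame(time_s = time_s, fsc = fsc, ssc = ssc, gfp = gfp, rfp = rfp)
}
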