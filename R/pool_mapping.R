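#' Parameters of the hidden-state allele-frequency model
#'
#' The hidden state is the pool's RM allele frequency on a discrete grid;
#' the chain moves along the chromosome in fixed physical bins, with a
#' Gaussian random-walk transition whose variance scales with the per-bin
#' recombination fraction, and binomial-kernel emissions from the
#' (overdispersion-corrected) allele counts.
#'
#' @param grid strictly increasing frequencies inside (0, 1); default 100
#'   points 0.005..0.995.
#' @param bin_bp physical bin size in bp (default 100).
#' @param bp_per_cM physical distance per centiMorgan (default 2200).
#' @param effective_pool_size overdispersion pool size N (default 1000):
#'   counts are shrunk to an effective depth `d * N / (d + N)`.
#' @param walk_scale multiplier c on the transition variance
#'   `c * r * p * (1 - p)` (default 1).
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(grid = seq(0.005, 0.995, by = 0.01), bin_bp = 100,
                       bp_per_cM = 2200, effective_pool_size = 1000,
                       walk_scale = 1) {
  if (any(grid <= 0) || any(grid >= 1) || is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing inside (0, 1)")
  }
  if (bin_bp <= 0 || bp_per_cM <= 0 || effective_pool_size <= 0) {
    stop("bin_bp, bp_per_cM and effective_pool_size must be positive")
  }
  structure(
    list(grid = grid, bin_bp = bin_bp, bp_per_cM = bp_per_cM,
         effective_pool_size = effective_pool_size,
         walk_scale = walk_scale),
    class = "hmm_params"
  )
}

#' Filter variants on extreme allele frequencies
#'
#' Removes markers whose RM fraction `RM / (RM + BY)` in the summed counts
#' of both pools is below `min_af` or above `max_af` (strict inequalities),
#' plus markers with zero depth in either pool. This targets globally
#' distorted markers (segregation distortion, alignment artifacts) while
#' sparing loci where divergent selection legitimately pushes a single pool
#' beyond the bounds. With `per_pool = TRUE` the frequency rule is instead
#' applied to each pool separately.
#'
#' @param track allele-count track (`chrom, pos, high_BY, high_RM, low_BY,
#'   low_RM`).
#' @param min_af,max_af frequency bounds (defaults 0.1 and 0.9).
#' @param per_pool apply the rule per pool instead of to pooled counts
#'   (default FALSE).
#' @return the filtered track, with attribute `n_removed`.
#' @export
filter_variants <- function(track, min_af = 0.1, max_af = 0.9,
                            per_pool = FALSE) {
  dh <- track$high_BY + track$high_RM
  dl <- track$low_BY + track$low_RM
  if (per_pool) {
    fh <- track$high_RM / dh
    fl <- track$low_RM / dl
    bad <- dh == 0 | dl == 0 |
      fh < min_af | fh > max_af | fl < min_af | fl > max_af
  } else {
    f <- (track$high_RM + track$low_RM) / (dh + dl)
    bad <- dh == 0 | dl == 0 | f < min_af | f > max_af
  }
  out <- track[!bad, , drop = FALSE]
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Bin allele counts into fixed-width physical bins
#'
#' Markers are assigned to half-open bins `[k * bin_bp, (k + 1) * bin_bp)`
#' in 0-based coordinates (1-based positions shifted by -1) and counts are
#' summed within bins. Empty bins are retained as zero-count bins so the
#' chain's genetic distance stays uniform along the chromosome.
#'
#' @param track allele-count track for one chromosome.
#' @param bin_bp bin size in bp.
#' @param chrom_length chromosome length in bp (defaults to the last marker
#'   position).
#' @return data.frame `bin` (0-based), `center` (1-based bp), `high_BY,
#'   high_RM, low_BY, low_RM` with one row per bin.
#' @export
bin_counts <- function(track, bin_bp, chrom_length = NULL) {
  if (is.null(chrom_length)) chrom_length <- max(track$pos)
  n_bins <- max(1, ceiling(chrom_length / bin_bp))
  k <- (track$pos - 1) %/% bin_bp
  agg <- function(x) {
    v <- numeric(n_bins)
    s <- tapply(x, k, sum)
    v[as.integer(names(s)) + 1] <- s
    v
  }
  data.frame(
    bin = seq_len(n_bins) - 1,
    center = (seq_len(n_bins) - 1) * bin_bp + (bin_bp + 1) / 2,
    high_BY = agg(track$high_BY), high_RM = agg(track$high_RM),
    low_BY = agg(track$low_BY), low_RM = agg(track$low_RM)
  )
}

#' Shrink counts to an effective pool size
#'
#' A sequenced pool of finite size N carries less information than the raw
#' read depth suggests; counts are scaled so the total equals
#' `d_eff = d * N / (d + N)` (real-valued pseudo-counts; zero depth stays
#' zero).
#'
#' @param by,rm non-negative count vectors.
#' @param N effective pool size.
#' @return list with scaled `by` and `rm`.
#' @export
effective_counts <- function(by, rm, N) {
  if (N <= 0) stop("N must be positive")
  if (any(by < 0) || any(rm < 0)) stop("counts must be non-negative")
  d <- by + rm
  scale <- ifelse(d > 0, N / (d + N), 0)
  list(by = by * scale, rm = rm * scale)
}

# Row-stochastic transition matrix of the frequency random walk for one bin
# step. Variance floor of one grid step squared keeps the kernel proper near
# the boundaries.
transition_matrix <- function(params) {
  grid <- params$grid
  step <- min(diff(grid))
  d_morgan <- params$bin_bp / (100 * params$bp_per_cM)
  r <- (1 - exp(-2 * d_morgan)) / 2
  v <- pmax(params$walk_scale * r * grid * (1 - grid), step^2)
  Tm <- outer(grid, grid, function(p, q) q - p)
  Tm <- exp(-Tm^2 / (2 * v)) / sqrt(v)
  Tm / rowSums(Tm)
}

# Grid-normalized binomial-kernel emission matrix (bins x grid); zero-count
# bins get a flat row.
emission_matrix <- function(by, rm, grid) {
  lp <- log(grid)
  lq <- log1p(-grid)
  le <- outer(rm, lp) + outer(by, lq)
  le <- le - apply(le, 1, max)
  e <- exp(le)
  e / rowSums(e)
}

#' Forward-backward posteriors of pool allele frequency along a chromosome
#'
#' Runs the scaled forward-backward algorithm for one pool over the binned,
#' overdispersion-corrected counts: uniform initial distribution, Gaussian
#' random-walk transitions per bin, grid-normalized binomial emissions.
#' Returns the per-bin smoothed posterior (normalized `alpha * beta`), the
#' scaled messages, and the log-evidence.
#'
#' @param by,rm effective count vectors, one value per bin.
#' @param params an `hmm_params`.
#' @return list: `posterior` (bins x grid, rows sum to 1), `alpha`, `beta`
#'   (scaled messages), `log_evidence`, `mean` (posterior mean frequency per
#'   bin), `grid`.
#' @export
pool_posteriors <- function(by, rm, params) {
  n <- length(by)
  if (n < 1) stop("empty chromosome")
  stopifnot(length(rm) == n)
  grid <- params$grid
  G <- length(grid)
  Tm <- transition_matrix(params)
  E <- emission_matrix(by, rm, grid)
  alpha <- matrix(0, n, G)
  beta <- matrix(0, n, G)
  log_ev <- 0
  a <- rep(1 / G, G) * E[1, ]
  s <- sum(a)
  log_ev <- log(s)
  alpha[1, ] <- a / s
  if (n > 1) {
    for (t in 2:n) {
      a <- as.vector(alpha[t - 1, ] %*% Tm) * E[t, ]
      s <- sum(a)
      log_ev <- log_ev + log(s)
      alpha[t, ] <- a / s
    }
  }
  beta[n, ] <- 1
  if (n > 1) {
    for (t in (n - 1):1) {
      b <- as.vector(Tm %*% (E[t + 1, ] * beta[t + 1, ]))
      beta[t, ] <- b / sum(b)
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, alpha = alpha, beta = beta, log_evidence = log_ev,
       mean = as.vector(post %*% grid), grid = grid)
}

#' Per-bin contrast LOD between high and low pools
#'
#' At each bin the smoothed posterior of each pool summarizes that pool's
#' full-chromosome evidence about the local allele frequency. The LOD is the
#' log10 Bayes factor of the two-population model (pool frequencies free)
#' against the one-population model (frequencies tied at that bin), which
#' with grid-normalized posteriors and a uniform prior reduces to
#' `-log10(G * sum_p A_H(p) * A_L(p))`. Identical pools give non-positive
#' values; fully informative discordant pools give large positive values;
#' data-free bins give exactly 0.
#'
#' @param post_high,post_low results of [pool_posteriors()] for the two
#'   pools over the same bins.
#' @return numeric LOD vector, one value per bin.
#' @export
contrast_lod <- function(post_high, post_low) {
  A <- post_high$posterior
  B <- post_low$posterior
  if (!all(dim(A) == dim(B))) stop("mismatched bin structure between pools")
  G <- ncol(A)
  -log10(G * rowSums(A * B))
}

#' Loess-smoothed allele-frequency difference along a chromosome
#'
#' Per pool, the raw per-marker RM fraction is smoothed by a loess
#' regression on position (span as a fraction of the chromosome's markers)
#' and evaluated at the requested bin centers; the smoothed difference
#' `high - low` is the QTL effect-size track (positive = RM allele raises
#' the trait). Chromosomes with fewer than 10 markers fall back to a
#' Gaussian-kernel weighted moving average (flagged).
#'
#' @param track filtered allele-count track for one chromosome.
#' @param centers positions (bp) at which to evaluate.
#' @param span loess span (default 0.1).
#' @return list: `af_high`, `af_low`, `daf` at `centers`; `fallback`
#'   logical.
#' @export
smooth_daf <- function(track, centers, span = 0.1) {
  fh <- track$high_RM / (track$high_RM + track$high_BY)
  fl <- track$low_RM / (track$low_RM + track$low_BY)
  pos <- track$pos
  eval_at <- pmin(pmax(centers, min(pos)), max(pos))
  fallback <- length(pos) < 10
  smooth_one <- function(f) {
    ok <- is.finite(f)
    if (fallback || sum(ok) < 10) {
      bw <- max(span * (max(pos) - min(pos)), 1)
      vapply(eval_at, function(x) {
        w <- exp(-0.5 * ((pos[ok] - x) / bw)^2)
        sum(w * f[ok]) / sum(w)
      }, 0)
    } else {
      df <- data.frame(f = f[ok], pos = pos[ok])
      # keep at least 8 markers in every local window so the quadratic
      # fit stays determined on sparse chromosomes
      span_eff <- max(span, min(1, 8 / nrow(df)))
      fit <- stats::loess(f ~ pos, data = df, span = span_eff, degree = 2,
                          surface = "direct")
      stats::predict(fit, newdata = data.frame(pos = eval_at))
    }
  }
  af_high <- unname(smooth_one(fh))
  af_low <- unname(smooth_one(fl))
  list(af_high = af_high, af_low = af_low, daf = af_high - af_low,
       fallback = fallback)
}

#' Call QTLs from a LOD track with 2-LOD support intervals
#'
#' A QTL is a maximal run of contiguous bins with LOD at or above the
#' threshold. The peak is the leftmost LOD maximum within the run; the
#' support interval is the contiguous stretch around the peak where the LOD
#' stays within 2 units of the peak LOD (it may extend beyond the run and is
#' clipped at the chromosome ends). The allele-frequency difference and its
#' sign are taken at the peak bin.
#'
#' @param lod_track data.frame with `chrom`, `center`, `lod`, `daf` (one
#'   row per bin, bins ordered within chromosome).
#' @param threshold LOD calling threshold (default 4.5).
#' @param ci_drop LOD drop defining the support interval (default 2).
#' @return data.frame `chrom, peak, ci_left, ci_right, lod, daf, sign` (one
#'   row per QTL; zero rows when nothing exceeds the threshold).
#' @export
call_qtls <- function(lod_track, threshold = 4.5, ci_drop = 2) {
  out <- list()
  for (chrom in unique(lod_track$chrom)) {
    d <- lod_track[lod_track$chrom == chrom, , drop = FALSE]
    above <- d$lod >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      run <- starts[j]:ends[j]
      peak_i <- run[which.max(d$lod[run])]
      peak_lod <- d$lod[peak_i]
      lo <- peak_i
      while (lo > 1 && d$lod[lo - 1] >= peak_lod - ci_drop) lo <- lo - 1
      hi <- peak_i
      while (hi < nrow(d) && d$lod[hi + 1] >= peak_lod - ci_drop) hi <- hi + 1
      daf <- d$daf[peak_i]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, peak = d$center[peak_i],
        ci_left = d$center[lo], ci_right = d$center[hi],
        lod = peak_lod, daf = daf,
        sign = if (daf >= 0) "+" else "-",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), peak = numeric(),
                      ci_left = numeric(), ci_right = numeric(),
                      lod = numeric(), daf = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Map QTLs from an allele-count track
#'
#' Full per-replicate mapping chain: variant filtering, physical binning,
#' effective-count shrinkage, forward-backward posteriors for both pools,
#' per-bin contrast LOD, loess-smoothed allele-frequency difference, and
#' QTL calling with 2-LOD support intervals.
#'
#' @param track allele-count track (`chrom, pos, high_BY, high_RM, low_BY,
#'   low_RM`), possibly spanning several chromosomes.
#' @param genome a `genome_map` (chromosome lengths for binning bounds).
#' @param params an `hmm_params` (default settings: 100-bp bins, 2200
#'   bp/cM, effective pool size 1000).
#' @param threshold LOD calling threshold (default 4.5).
#' @param daf_span loess span for the allele-frequency difference track.
#' @return list: `lod_track` (per-bin `chrom, center, lod, af_high, af_low,
#'   daf`), `qtls` (QTL table), `n_filtered` (markers removed).
#' @export
map_qtls <- function(track, genome, params = hmm_params(), threshold = 4.5,
                     daf_span = 0.1) {
  filtered <- filter_variants(track)
  n_removed <- attr(filtered, "n_removed")
  tracks <- list()
  for (chrom in unique(filtered$chrom)) {
    tc <- filtered[filtered$chrom == chrom, , drop = FALSE]
    if (nrow(tc) == 0) next
    len <- genome$chrom_lengths[[chrom]]
    binned <- bin_counts(tc, params$bin_bp, chrom_length = len)
    eh <- effective_counts(binned$high_BY, binned$high_RM,
                           params$effective_pool_size)
    el <- effective_counts(binned$low_BY, binned$low_RM,
                           params$effective_pool_size)
    ph <- pool_posteriors(eh$by, eh$rm, params)
    pl <- pool_posteriors(el$by, el$rm, params)
    lod <- contrast_lod(ph, pl)
    sm <- smooth_daf(tc, binned$center, span = daf_span)
    tracks[[chrom]] <- data.frame(
      chrom = chrom, center = binned$center, lod = lod,
      af_high = sm$af_high, af_low = sm$af_low, daf = sm$daf,
      stringsAsFactors = FALSE
    )
  }
  lod_track <- do.call(rbind, tracks)
  rownames(lod_track) <- NULL
  list(lod_track = lod_track, qtls = call_qtls(lod_track, threshold),
       n_filtered = n_removed)
}
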