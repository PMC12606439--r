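track_df <- function(pos, h_by, h_rm, l_by, l_rm, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, high_BY = h_by, high_RM = h_rm,
             low_BY = l_by, low_RM = l_rm, stringsAsFactors = FALSE)
}

test_that("variant filter removes extreme and zero-depth markers", {
  tr <- track_df(pos = c(100, 200, 300, 400),
                 h_by = c(5, 50, 90, 0), h_rm = c(95, 50, 10, 0),
                 l_by = c(50, 50, 90, 10), l_rm = c(50, 50, 10, 10))
  # per-pool rule: high-pool fraction 0.95 removed; 0.5/0.5 retained;
  # exactly 0.10 retained (strict inequality); zero-depth removed
  pp <- filter_variants(tr, per_pool = TRUE)
  expect_equal(pp$pos, c(200, 300))
  expect_equal(attr(pp, "n_removed"), 2)
  # pooled-count default: marker 1 has combined fraction 0.725, retained
  pooled <- filter_variants(tr)
  expect_equal(pooled$pos, c(100, 200, 300))
  # combined-extreme marker removed under the default too
  tr2 <- track_df(pos = 1:2 * 100, h_by = c(2, 50), h_rm = c(98, 50),
                  l_by = c(3, 50), l_rm = c(97, 50))
  expect_equal(filter_variants(tr2)$pos, 200)
})

test_that("binning is half-open on 0-based coordinates and conserves counts", {
  tr <- track_df(pos = c(50, 100, 150), h_by = c(1, 2, 4), h_rm = c(8, 16, 32),
                 l_by = c(1, 1, 1), l_rm = c(2, 2, 2))
  b <- bin_counts(tr, 100, chrom_length = 300)
  expect_equal(b$bin, c(0, 1, 2))
  # positions 50 and 100 share bin 0 (0-based coords 49 and 99); 150 in bin 1
  expect_equal(b$high_BY, c(3, 4, 0))
  expect_equal(b$high_RM, c(24, 32, 0))
  expect_equal(sum(b$low_RM), sum(tr$low_RM))
})

test_that("effective counts shrink with depth toward the pool size", {
  e <- effective_counts(5, 5, 1000)
  expect_equal(e$by + e$rm, 10 * 1000 / 1010)
  expect_equal(e$by, 5 * 1000 / 1010)
  half <- effective_counts(400, 600, 1000)
  expect_equal(half$by + half$rm, 500)
  expect_equal(half$rm, 300)
  huge <- effective_counts(7, 13, 1e12)
  expect_equal(huge$by, 7, tolerance = 1e-9)
  zero <- effective_counts(0, 0, 50)
  expect_equal(zero$by, 0)
  expect_error(effective_counts(-1, 2, 10), "non-negative")
})

test_that("single-bin posterior is the normalized binomial kernel", {
  p <- hmm_params()
  post <- pool_posteriors(by = 2, rm = 8, p)
  # the continuous mode 0.8 sits midway between grid points 0.795/0.805;
  # the kernel is fractionally higher at 0.795
  expect_equal(p$grid[which.max(post$posterior[1, ])], 0.795)
  direct <- p$grid^8 * (1 - p$grid)^2
  expect_equal(post$posterior[1, ], direct / sum(direct), tolerance = 1e-12)
  # with no data the posterior stays at the uniform prior up to the tiny
  # boundary leakage of the row-normalized walk kernel
  flat <- pool_posteriors(by = c(0, 0, 0), rm = c(0, 0, 0), p)
  expect_true(all(abs(flat$posterior - 1 / length(p$grid)) < 5e-3))
  expect_error(pool_posteriors(numeric(0), numeric(0), p), "empty")
})

test_that("forward-backward equals exhaustive path enumeration", {
  grids <- list(seq(0.1, 0.9, by = 0.2),            # 5 states, 3 bins
                seq(0.125, 0.875, length.out = 7))  # 7 states, 4 bins
  counts <- list(list(by = c(2, 0, 7), rm = c(8, 0, 3)),
                 list(by = c(1, 4, 0, 9.5), rm = c(9, 6, 0, 0.5)))
  for (k in 1:2) {
    p <- hmm_params(grid = grids[[k]], bin_bp = 5000)
    by <- counts[[k]]$by; rm <- counts[[k]]$rm
    fb <- pool_posteriors(by, rm, p)
    oracle <- oracle_enumerate(by, rm, p)
    expect_lt(max(abs(log(fb$posterior) - log(oracle$posterior))), 1e-9)
    expect_lt(abs(fb$log_evidence - oracle$log_evidence), 1e-9)
  }
})

test_that("contrast LOD is a tied-versus-free Bayes factor", {
  p <- hmm_params()
  # fully discordant single bin: decisive evidence for two populations
  h <- pool_posteriors(10, 90, p)
  l <- pool_posteriors(90, 10, p)
  expect_gt(contrast_lod(h, l)[1], 4.5)
  # identical counts: tied model favored or near-neutral
  p3 <- hmm_params(grid = seq(0.1, 0.9, by = 0.1), bin_bp = 5000)
  same <- pool_posteriors(c(5, 3, 8), c(5, 7, 2), p3)
  expect_true(all(contrast_lod(same, same) <= 0.5))
  # no data anywhere: zero up to the boundary leakage of the walk kernel
  none <- pool_posteriors(c(0, 0), c(0, 0), p)
  expect_equal(contrast_lod(none, none), c(0, 0), tolerance = 1e-3)
  expect_error(
    contrast_lod(none, pool_posteriors(0, 0, p)), "mismatched")
})

test_that("LOD matches enumeration-based posterior overlap on a short chain", {
  p <- hmm_params(grid = seq(0.125, 0.875, length.out = 7), bin_bp = 5000)
  hi <- list(by = c(1, 2, 0, 4), rm = c(9, 8, 0, 6))
  lo <- list(by = c(6, 5, 0, 9), rm = c(4, 5, 0, 1))
  fh <- pool_posteriors(hi$by, hi$rm, p)
  fl <- pool_posteriors(lo$by, lo$rm, p)
  oh <- oracle_enumerate(hi$by, hi$rm, p)
  ol <- oracle_enumerate(lo$by, lo$rm, p)
  oracle_lod <- -log10(7 * rowSums(oh$posterior * ol$posterior))
  expect_lt(max(abs(contrast_lod(fh, fl) - oracle_lod)), 1e-9)
})

test_that("pool label swap preserves LOD and flips the smoothed difference", {
  g <- genome_map(c(chr1 = 6e4), marker_spacing = 2000)
  set.seed(55)
  pos <- g$markers$chr1
  m <- length(pos)
  tr <- track_df(pos, h_by = rbinom(m, 60, 0.35), h_rm = rbinom(m, 60, 0.65),
                 l_by = rbinom(m, 60, 0.6), l_rm = rbinom(m, 60, 0.4))
  fwd <- map_qtls(tr, g, params = hmm_params(bin_bp = 1000))
  swapped <- tr
  names(swapped) <- c("chrom", "pos", "low_BY", "low_RM", "high_BY",
                      "high_RM")
  rev <- map_qtls(swapped[, names(tr)], g,
                  params = hmm_params(bin_bp = 1000))
  expect_equal(rev$lod_track$lod, fwd$lod_track$lod, tolerance = 1e-9)
  expect_equal(rev$lod_track$daf, -fwd$lod_track$daf, tolerance = 1e-9)
})

test_that("down-scaling counts never raises the peak LOD", {
  g <- genome_map(c(chr1 = 6e4), marker_spacing = 2000)
  pos <- g$markers$chr1
  m <- length(pos)
  for (seed in 1:3) {
    set.seed(seed)
    tr <- track_df(pos, h_by = rbinom(m, 80, 0.3), h_rm = rbinom(m, 80, 0.7),
                   l_by = rbinom(m, 80, 0.7), l_rm = rbinom(m, 80, 0.3))
    scaled <- tr
    for (cc in c("high_BY", "high_RM", "low_BY", "low_RM")) {
      scaled[[cc]] <- tr[[cc]] * 0.4
    }
    p <- hmm_params(bin_bp = 1000)
    full <- max(map_qtls(tr, g, params = p)$lod_track$lod)
    less <- max(map_qtls(scaled, g, params = p)$lod_track$lod)
    expect_lte(less, full + 1e-9)
  }
})

test_that("smoothed allele-frequency differences follow the pool tracks", {
  pos <- seq(500, 50000, by = 500)
  m <- length(pos)
  flat <- track_df(pos, h_by = rep(50, m), h_rm = rep(50, m),
                   l_by = rep(50, m), l_rm = rep(50, m))
  sm <- smooth_daf(flat, centers = c(1000, 25000, 49000))
  expect_equal(sm$daf, c(0, 0, 0), tolerance = 1e-9)
  split <- track_df(pos, h_by = rep(30, m), h_rm = rep(70, m),
                    l_by = rep(70, m), l_rm = rep(30, m))
  sm2 <- smooth_daf(split, centers = c(10000, 40000))
  expect_equal(sm2$daf, c(0.4, 0.4), tolerance = 1e-9)
  expect_false(sm2$fallback)
  # sparse chromosome: weighted-moving-average fallback, flagged
  sparse <- split[1:5, ]
  sm3 <- smooth_daf(sparse, centers = 1000)
  expect_true(sm3$fallback)
  expect_equal(sm3$daf, 0.4, tolerance = 1e-9)
})

test_that("QTL calling segments runs and takes 2-LOD support intervals", {
  centers <- (0:100) * 100 + 50.5
  none <- data.frame(chrom = "chr1", center = centers, lod = 0, daf = 0)
  expect_equal(nrow(call_qtls(none)), 0)
  # triangle peaking at 6.0 on bin 50, slope 0.1 per bin
  tri <- data.frame(chrom = "chr1", center = centers,
                    lod = 6 - 0.1 * abs(0:100 - 50), daf = 0.3)
  q <- call_qtls(tri, threshold = 4.5)
  expect_equal(nrow(q), 1)
  expect_equal(q$peak, centers[51])
  expect_equal(q$ci_left, centers[31])   # lod >= 4.0 from bin 30
  expect_equal(q$ci_right, centers[71])
  expect_equal(q$sign, "+")
  # two runs separated by a sub-threshold valley give two records
  two <- tri
  two$lod <- pmax(6 - 0.1 * abs(0:100 - 20), 6 - 0.1 * abs(0:100 - 80))
  two$daf <- -0.2
  q2 <- call_qtls(two, threshold = 4.5)
  expect_equal(nrow(q2), 2)
  expect_equal(q2$peak, centers[c(21, 81)])
  expect_equal(q2$sign, c("-", "-"))
})
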