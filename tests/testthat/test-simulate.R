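test_that("no-recombination limit keeps chromosomes intact", {
  # 220 bp at 2200 bp/cM is 0.1 cM: expected crossovers 0.001 per meiosis
  g <- genome_map(c(chr1 = 220), markers = list(chr1 = c(10, 110, 210)),
                  bp_per_cM = 2200)
  geno <- simulate_segregant_genotypes(g, 500, seed = 11)
  intact <- apply(geno, 1, function(x) length(unique(x)) == 1)
  expect_gte(mean(intact), 0.99)
})

test_that("recombinant fractions follow Haldane's map function", {
  # three marker spacings on one chromosome; r = (1 - exp(-2d))/2
  spac <- c(2200, 22000, 110000)  # 1, 10, 50 cM
  pos <- cumsum(c(1, spac))
  g <- genome_map(c(chr1 = 140000), markers = list(chr1 = pos),
                  bp_per_cM = 2200)
  n <- 10000
  geno <- simulate_segregant_genotypes(g, n, seed = 42)
  for (k in seq_along(spac)) {
    d <- spac[k] / 2200 / 100
    r <- (1 - exp(-2 * d)) / 2
    obs <- mean(geno[, k] != geno[, k + 1])
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / n) + 1e-12)
  }
})

test_that("markers segregate 50/50 in the unselected panel", {
  g <- genome_map(c(chr1 = 2e5), marker_spacing = 5000)
  n <- 10000
  geno <- simulate_segregant_genotypes(g, n, seed = 7)
  se <- sqrt(0.25 / n)
  expect_true(all(abs(colMeans(geno) - 0.5) < 4 * se + 0.01))
  expect_lt(abs(mean(geno) - 0.5), 4 * se)
  expect_error(simulate_segregant_genotypes(g, 0), ">= 1")
})

test_that("trait model gives the analytic variance decomposition", {
  g <- genome_map(c(chr1 = 1e5), marker_spacing = 5000)
  n <- 5000
  geno <- simulate_segregant_genotypes(g, n, seed = 3)
  d0 <- cross_design(n, qtls = NULL)
  tr0 <- simulate_trait(geno, g, d0, "SC", seed = 5)
  expect_lt(abs(var(tr0) - 1), 0.1)
  qt <- data.frame(chrom = "chr1", pos = 50000, effect = 1, SC = 1, E0 = 0)
  d1 <- cross_design(n, qtls = qt)
  # multiplier 0: identical in law to the no-QTL case (same seed, same draws)
  expect_identical(simulate_trait(geno, g, d1, "E0", seed = 5), tr0)
  # variance of the +/-1/2 allele score is 1/4: h2 = 0.25/1.25 = 0.2
  tr1 <- simulate_trait(geno, g, d1, "SC", seed = 5)
  j <- which.min(abs(g$markers$chr1 - 50000))
  h2 <- summary(lm(tr1 ~ geno[, j]))$r.squared
  expect_lt(abs(h2 - 0.2), 0.04)
  expect_error(simulate_trait(geno, g, d1, "nope", seed = 1),
               "unknown environment")
})

test_that("tail selection is deterministic, disjoint and correctly sized", {
  tails <- select_tails(1:100, 0.02)
  expect_equal(tails$high, c(99, 100))
  expect_equal(tails$low, c(1, 2))
  tied <- select_tails(rep(1, 100), 0.02)
  expect_equal(tied$low, c(1, 2))
  expect_equal(tied$high, c(99, 100))
  expect_length(intersect(tied$high, tied$low), 0)
  big <- select_tails(rnorm(1000), 0.02)
  expect_length(big$high, 20)
  expect_length(big$low, 20)
  expect_error(select_tails(1:10, 0.5), "0.5")
})

test_that("read counts are binomial draws around pool frequencies", {
  g <- genome_map(c(chr1 = 1e5), marker_spacing = 100)
  n_mark <- length(g$markers$chr1)
  geno_rm <- matrix(1L, nrow = 4, ncol = n_mark,
                    dimnames = list(NULL, paste0("chr1:", g$markers$chr1)))
  cnt <- simulate_read_counts(geno_rm, 1:2, 3:4, g, 50, seed = 2)
  expect_true(all(cnt$high_BY == 0))
  expect_true(all(cnt$low_BY == 0))
  # a 50/50 pool: mean RM read fraction 0.5 within 3 SE over ~1000 markers
  geno_half <- geno_rm
  geno_half[1:2, ] <- 0L
  cnt2 <- simulate_read_counts(geno_half, 1:4, 1:4, g, 100, seed = 9)
  fr <- cnt2$high_RM / (cnt2$high_RM + cnt2$high_BY)
  expect_lt(abs(mean(fr) - 0.5), 3 * sd(fr) / sqrt(n_mark))
  expect_error(simulate_read_counts(geno_rm, integer(0), 1:2, g, 10),
               "non-empty")
})

test_that("cytometry events encode the configured activity exactly", {
  ev <- simulate_cytometry_events(activity = 1.5, gfp_level = 1000,
                                  n_events = 200, drift_slope = 0,
                                  noise_sd = 0, seed = 4)
  expect_equal(-log2(ev$rfp / ev$gfp), rep(1.5, 200), tolerance = 1e-12)
  expect_error(simulate_cytometry_events(1, gfp_level = 0, n_events = 200),
               "positive")
  expect_error(simulate_cytometry_events(1, 100, n_events = 50), "100")
})

test_that("configured activity differences survive the event pipeline", {
  act <- c(a = 0.5, b = 2.0)
  med <- vapply(act, function(a) {
    ev <- simulate_cytometry_events(a, 1000, n_events = 4000,
                                    drift_slope = 0.02, noise_sd = 0.3,
                                    seed = round(a * 100))
    s <- summarize_replicate(ev, "BY", "R", "SC", 1)
    s$activity
  }, 0)
  expect_lt(abs((med["b"] - med["a"]) - 1.5), 0.05)
})

test_that("low-nitrogen events are FSC-bimodal and cross replicates recover pools", {
  ev <- simulate_cytometry_events(1, 1000, n_events = 5000,
                                  low_nitrogen = TRUE, seed = 6)
  lower <- select_lower_fsc_mode(ev)
  expect_lt(nrow(lower), nrow(ev))
  expect_lt(median(lower$fsc), median(ev$fsc))
  # full cross wrapper: pool sizes and truth plumbing
  g <- genome_map(c(chr1 = 1e5), marker_spacing = 2000)
  qt <- data.frame(chrom = "chr1", pos = 5e4, effect = 1, SC = 1)
  cr <- simulate_cross(g, cross_design(500, qtls = qt, mean_depth = 20),
                       "SC", seed = 10)
  expect_length(cr$environments$SC$pools$high, 10)
  expect_equal(nrow(cr$environments$SC$counts), length(g$markers$chr1))
  expect_identical(cr$truth, qt)
})
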