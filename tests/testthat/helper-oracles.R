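# Independent oracles, written from the model definitions with plain loops
# so they share no code path with the package implementation.

# Transition density of the frequency random walk, row-normalized.
oracle_transition <- function(grid, bin_bp, bp_per_cM, walk_scale = 1) {
  step <- min(diff(grid))
  d_morgan <- bin_bp / (100 * bp_per_cM)
  r <- (1 - exp(-2 * d_morgan)) / 2
  G <- length(grid)
  Tm <- matrix(0, G, G)
  for (i in seq_len(G)) {
    v <- max(walk_scale * r * grid[i] * (1 - grid[i]), step^2)
    for (j in seq_len(G)) {
      Tm[i, j] <- exp(-(grid[j] - grid[i])^2 / (2 * v)) / sqrt(v)
    }
    Tm[i, ] <- Tm[i, ] / sum(Tm[i, ])
  }
  Tm
}

# Grid-normalized binomial-kernel emission for one bin.
oracle_emission <- function(by, rm, grid) {
  e <- grid^rm * (1 - grid)^by
  e / sum(e)
}

# Exhaustive path enumeration: marginal posteriors and total evidence for
# one pool's chain. Feasible for length(grid)^n_bins up to ~1e5 paths.
oracle_enumerate <- function(by, rm, params) {
  grid <- params$grid
  G <- length(grid)
  n <- length(by)
  Tm <- oracle_transition(grid, params$bin_bp, params$bp_per_cM,
                          params$walk_scale)
  E <- t(vapply(seq_len(n), function(t) oracle_emission(by[t], rm[t], grid),
                numeric(G)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(G)), n)))
  probs <- apply(paths, 1, function(s) {
    p <- (1 / G) * E[1, s[1]]
    if (n > 1) {
      for (t in 2:n) p <- p * Tm[s[t - 1], s[t]] * E[t, s[t]]
    }
    p
  })
  Z <- sum(probs)
  post <- matrix(0, n, G)
  for (t in seq_len(n)) {
    for (g in seq_len(G)) {
      post[t, g] <- sum(probs[paths[, t] == g]) / Z
    }
  }
  list(posterior = post, log_evidence = log(Z))
}

# Closed-form Welch two-sample t-test.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Small QTL-table builder for catalog/classification tests.
qtl_row <- function(chrom, peak, lod = 6, daf = 0.2, sign = NULL,
                    width = 2e4) {
  if (is.null(sign)) sign <- if (daf >= 0) "+" else "-"
  data.frame(chrom = chrom, peak = peak, ci_left = peak - width,
             ci_right = peak + width, lod = lod, daf = daf, sign = sign,
             stringsAsFactors = FALSE)
}

qtl_table <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(qtl_row("chr0", 0)[0, ])
  }
  do.call(rbind, rows)
}

# match_replicates output split into both-support and single-support parts.
split_support <- function(merged) {
  list(both = merged[merged$replicate_support == "both", , drop = FALSE],
       single = merged[merged$replicate_support == "single", , drop = FALSE])
}
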