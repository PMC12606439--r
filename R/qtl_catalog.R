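#' Reconcile QTLs across two biological replicates
#'
#' A locus detected in both replicates is a pair of QTLs on the same
#' chromosome with peaks within `max_dist` (100 kb) and the same effect
#' direction (sign of the allele-frequency difference). Candidate pairs are
#' matched greedily by increasing peak distance, each QTL used at most once.
#' Matched pairs get `replicate_support = "both"` with peak, support
#' interval, LOD and effect averaged between the replicates; unmatched QTLs
#' keep their values with `replicate_support = "single"`.
#'
#' @param rep1,rep2 QTL tables (from [call_qtls()] / [map_qtls()]) of the
#'   two replicates of one reporter/environment.
#' @param max_dist maximum peak separation in bp (default 1e5).
#' @return data.frame of merged QTLs: `chrom, peak, ci_left, ci_right, lod,
#'   daf, sign, replicate_support, peak_rep1, peak_rep2, source`.
#' @export
match_replicates <- function(rep1, rep2, max_dist = 1e5) {
  empty <- data.frame(
    chrom = character(), peak = numeric(), ci_left = numeric(),
    ci_right = numeric(), lod = numeric(), daf = numeric(),
    sign = character(), replicate_support = character(),
    peak_rep1 = numeric(), peak_rep2 = numeric(), source = character(),
    stringsAsFactors = FALSE
  )
  single_row <- function(q, which_rep) {
    data.frame(
      chrom = q$chrom, peak = q$peak, ci_left = q$ci_left,
      ci_right = q$ci_right, lod = q$lod, daf = q$daf, sign = q$sign,
      replicate_support = "single",
      peak_rep1 = if (which_rep == 1) q$peak else NA_real_,
      peak_rep2 = if (which_rep == 2) q$peak else NA_real_,
      source = paste0("rep", which_rep),
      stringsAsFactors = FALSE
    )
  }
  n1 <- nrow(rep1); n2 <- nrow(rep2)
  pairs <- NULL
  if (n1 > 0 && n2 > 0) {
    cand <- expand.grid(i = seq_len(n1), j = seq_len(n2))
    cand$dist <- abs(rep1$peak[cand$i] - rep2$peak[cand$j])
    keep <- rep1$chrom[cand$i] == rep2$chrom[cand$j] &
      cand$dist <= max_dist &
      rep1$sign[cand$i] == rep2$sign[cand$j]
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$i, cand$j), , drop = FALSE]
    used1 <- logical(n1); used2 <- logical(n2)
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used1[i] && !used2[j]) {
        sel[k] <- TRUE
        used1[i] <- TRUE; used2[j] <- TRUE
      }
    }
    pairs <- cand[sel, , drop = FALSE]
  } else {
    used1 <- logical(n1); used2 <- logical(n2)
  }
  rows <- list()
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      q1 <- rep1[pairs$i[k], ]; q2 <- rep2[pairs$j[k], ]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = q1$chrom,
        peak = (q1$peak + q2$peak) / 2,
        ci_left = (q1$ci_left + q2$ci_left) / 2,
        ci_right = (q1$ci_right + q2$ci_right) / 2,
        lod = (q1$lod + q2$lod) / 2,
        daf = (q1$daf + q2$daf) / 2,
        sign = q1$sign,
        replicate_support = "both",
        peak_rep1 = q1$peak, peak_rep2 = q2$peak,
        source = "rep1+rep2",
        stringsAsFactors = FALSE
      )
    }
  }
  for (i in which(!used1)) rows[[length(rows) + 1]] <- single_row(rep1[i, ], 1)
  for (j in which(!used2)) rows[[length(rows) + 1]] <- single_row(rep2[j, ], 2)
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$peak), , drop = FALSE]
}

#' Flag loci shared with a previous study
#'
#' A locus is shared when some QTL of at least one replicate of the prior
#' study lies on the same chromosome with a peak within `max_dist` (100
#' kb). Sign concordance with the nearest such prior QTL is recorded
#' separately.
#'
#' @param merged merged QTL table (present study).
#' @param prior_rep1,prior_rep2 QTL tables of the prior study's replicates.
#' @param max_dist maximum peak separation in bp (default 1e5).
#' @return `merged` with logical `shared` and `sign_concordant` columns
#'   (`sign_concordant` is NA for unshared loci).
#' @export
cross_study_overlap <- function(merged, prior_rep1, prior_rep2,
                                max_dist = 1e5) {
  prior <- rbind(prior_rep1[, c("chrom", "peak", "sign")],
                 prior_rep2[, c("chrom", "peak", "sign")])
  merged$shared <- FALSE
  merged$sign_concordant <- NA
  if (nrow(prior) == 0 || nrow(merged) == 0) return(merged)
  for (i in seq_len(nrow(merged))) {
    same <- prior$chrom == merged$chrom[i] &
      abs(prior$peak - merged$peak[i]) <= max_dist
    if (any(same)) {
      merged$shared[i] <- TRUE
      nearest <- which(same)[which.min(abs(prior$peak[same] -
                                             merged$peak[i]))]
      merged$sign_concordant[i] <- prior$sign[nearest] == merged$sign[i]
    }
  }
  merged
}

#' Compare LOD and effect magnitude between shared and study-unique loci
#'
#' Two-sided two-sample (Welch) t-tests on the LOD score and on the
#' absolute allele-frequency difference between loci shared with a prior
#' study and loci unique to this one. Groups with fewer than two members
#' make the comparison not computable.
#'
#' @param merged merged QTL table with a logical `shared` column.
#' @return list with elements `lod` and `abs_daf`, each a list
#'   `t, p, computable`.
#' @export
compare_shared_vs_unique <- function(merged) {
  cmp <- function(x, g) {
    a <- x[g]; b <- x[!g]
    if (length(a) < 2 || length(b) < 2) {
      return(list(t = NA_real_, p = NA_real_, computable = FALSE))
    }
    if (stats::sd(c(a, b)) == 0) {
      return(list(t = 0, p = 1, computable = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(t = unname(tt$statistic), p = tt$p.value, computable = TRUE)
  }
  list(lod = cmp(merged$lod, merged$shared),
       abs_daf = cmp(abs(merged$daf), merged$shared))
}
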