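# Per-replicate peak list of one environment: replicate-level peaks with
# signs, from the merged (both-support) and single-support records.
replicate_peaks <- function(merged, singles) {
  rows <- list()
  if (nrow(merged) > 0) {
    for (i in seq_len(nrow(merged))) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = merged$chrom[i],
        peak = c(merged$peak_rep1[i], merged$peak_rep2[i]),
        sign = merged$sign[i], locus = paste0("both_", i),
        support = "both", stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(singles) > 0) {
    for (i in seq_len(nrow(singles))) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = singles$chrom[i], peak = singles$peak[i],
        sign = singles$sign[i], locus = paste0("single_", i),
        support = "single", stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), peak = numeric(),
                      sign = character(), locus = character(),
                      support = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify locus-level GxE between two environments for one reporter
#'
#' Anchors are loci detected in both replicates of an environment. For each
#' anchor: if some QTL of either replicate of the other environment has a
#' peak within 100 kb, the pair is classified `sign_change` when the effect
#' directions differ and `no_gxe` when they agree (magnitude differences
#' are not classified); if no peak of either replicate of the other
#' environment lies within 100 kb, the call is `presence_absence`. When an
#' anchor of one environment pairs with an anchor of the other, the nearest
#' peak defines the pair and the comparison is deduplicated so the pair
#' yields one call. Loci with single-replicate support in both environments
#' are never anchors and are dropped.
#'
#' @param base_merged,base_singles merged (both-support) and single-support
#'   QTL tables of the baseline environment.
#' @param env_merged,env_singles the same for the comparison environment.
#' @param reporter reporter label carried into the output.
#' @param env_pair character(2): names of the two environments
#'   (baseline first).
#' @param max_dist maximum peak separation in bp (default 1e5).
#' @return data.frame of GxE calls: `reporter, env_base, env_other, chrom,
#'   anchor_peak, anchor_env, category, support_base, support_other,
#'   sign_base, sign_other`.
#' @export
classify_pairwise <- function(base_merged, base_singles, env_merged,
                              env_singles, reporter = NA_character_,
                              env_pair = c("SC", "env"), max_dist = 1e5) {
  pk_base <- replicate_peaks(base_merged, base_singles)
  pk_env <- replicate_peaks(env_merged, env_singles)
  consumed_env <- character(0)
  consumed_base <- character(0)
  calls <- list()
  classify_anchor <- function(anchor, other_peaks, anchor_env_name,
                              other_env_name, skip_loci) {
    cand <- other_peaks[other_peaks$chrom == anchor$chrom &
                          abs(other_peaks$peak - anchor$peak) <= max_dist &
                          !(other_peaks$locus %in% skip_loci), ,
                        drop = FALSE]
    if (nrow(cand) == 0) {
      return(list(category = "presence_absence", matched_locus = NA,
                  sign_other = NA_character_, support_other = "none"))
    }
    nearest <- cand[which.min(abs(cand$peak - anchor$peak)), ]
    category <- if (nearest$sign != anchor$sign) "sign_change" else "no_gxe"
    list(category = category, matched_locus = nearest$locus,
         sign_other = nearest$sign, support_other = nearest$support)
  }
  if (nrow(base_merged) > 0) {
    for (i in seq_len(nrow(base_merged))) {
      anchor <- base_merged[i, ]
      res <- classify_anchor(anchor, pk_env, env_pair[1], env_pair[2],
                             character(0))
      if (!is.na(res$matched_locus) &&
            startsWith(res$matched_locus, "both_")) {
        consumed_env <- c(consumed_env, res$matched_locus)
      }
      calls[[length(calls) + 1]] <- data.frame(
        reporter = reporter, env_base = env_pair[1], env_other = env_pair[2],
        chrom = anchor$chrom, anchor_peak = anchor$peak,
        anchor_env = env_pair[1], category = res$category,
        support_base = "both", support_other = res$support_other,
        sign_base = anchor$sign, sign_other = res$sign_other,
        stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(env_merged) > 0) {
    for (i in seq_len(nrow(env_merged))) {
      if (paste0("both_", i) %in% consumed_env) next
      anchor <- env_merged[i, ]
      res <- classify_anchor(anchor, pk_base, env_pair[2], env_pair[1],
                             consumed_base)
      calls[[length(calls) + 1]] <- data.frame(
        reporter = reporter, env_base = env_pair[1], env_other = env_pair[2],
        chrom = anchor$chrom, anchor_peak = anchor$peak,
        anchor_env = env_pair[2], category = res$category,
        support_base = res$support_other, support_other = "both",
        sign_base = res$sign_other, sign_other = anchor$sign,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(calls) == 0) {
    return(data.frame(
      reporter = character(), env_base = character(),
      env_other = character(), chrom = character(),
      anchor_peak = numeric(), anchor_env = character(),
      category = character(), support_base = character(),
      support_other = character(), sign_base = character(),
      sign_other = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
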