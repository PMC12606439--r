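#' Nuclear chromosome lengths of the sacCer3 yeast reference genome
#'
#' Named integer vector of the 16 nuclear chromosome lengths (bp) of the
#' Saccharomyces cerevisiae sacCer3 assembly, used as the default coordinate
#' system for genome binning and for full-scale simulated crosses.
#'
#' @format Named integer vector of length 16 (chrI..chrXVI).
#' @export
SACCER3_CHROM_LENGTHS <- c(
  chrI    = 230218L,
  chrII   = 813184L,
  chrIII  = 316620L,
  chrIV   = 1531933L,
  chrV    = 576874L,
  chrVI   = 270161L,
  chrVII  = 1090940L,
  chrVIII = 562643L,
  chrIX   = 439888L,
  chrX    = 745751L,
  chrXI   = 666816L,
  chrXII  = 1078177L,
  chrXIII = 924431L,
  chrXIV  = 784333L,
  chrXV   = 1091291L,
  chrXVI  = 948066L
)

#' Construct a genome map
#'
#' A genome map holds the chromosome coordinate system, the marker positions
#' genotyped in the cross, and the physical-to-genetic distance scale used by
#' both the cross simulator and the allele-frequency hidden-state model.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param markers named list (one element per chromosome, same names as
#'   `chrom_lengths`) of strictly increasing 1-based marker positions in bp.
#'   If `NULL`, markers are placed on a regular grid with `marker_spacing`.
#' @param bp_per_cM physical distance per centiMorgan (default 2200, the
#'   scale conventionally used for the BY x RM cross).
#' @param marker_spacing spacing in bp for auto-generated markers. The
#'   default of 640 bp reproduces the genome-wide density of the 18,871
#'   marker panel on the 12.07-Mb nuclear genome.
#'
#' @return An object of class `genome_map`: list with `chrom_lengths`,
#'   `markers`, `bp_per_cM`.
#' @export
genome_map <- function(chrom_lengths, markers = NULL, bp_per_cM = 2200,
                       marker_spacing = 640) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths))) {
    stop("chrom_lengths must have unique names")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (bp_per_cM <= 0) stop("bp_per_cM must be positive")
  if (is.null(markers)) {
    markers <- lapply(chrom_lengths, function(len) {
      pos <- seq(from = marker_spacing %/% 2, to = len, by = marker_spacing)
      as.numeric(pos)
    })
    names(markers) <- names(chrom_lengths)
  }
  if (!setequal(names(markers), names(chrom_lengths))) {
    stop("markers must be named by chromosome")
  }
  markers <- markers[names(chrom_lengths)]
  for (chrom in names(markers)) {
    pos <- markers[[chrom]]
    if (length(pos) == 0) stop("empty marker set on chromosome ", chrom)
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("marker positions must be strictly increasing on ", chrom)
    }
    if (pos[1] < 1 || pos[length(pos)] > chrom_lengths[[chrom]]) {
      stop("marker positions outside chromosome ", chrom)
    }
  }
  structure(
    list(chrom_lengths = chrom_lengths, markers = markers,
         bp_per_cM = bp_per_cM),
    class = "genome_map"
  )
}

#' Default full-scale yeast genome map
#'
#' sacCer3 nuclear chromosomes with regularly spaced markers at the density
#' of the cross's 18,871-marker panel.
#'
#' @param marker_spacing spacing between markers in bp (default 640).
#' @param bp_per_cM physical distance per centiMorgan (default 2200).
#' @return A `genome_map`.
#' @export
saccer3_genome <- function(marker_spacing = 640, bp_per_cM = 2200) {
  genome_map(SACCER3_CHROM_LENGTHS, bp_per_cM = bp_per_cM,
             marker_spacing = marker_spacing)
}

#' Tile a genome into fixed-width bins
#'
#' Half-open bins `[k*width, (k+1)*width)` in 0-based coordinates, with a
#' final partial bin per chromosome, so the total number of bins is
#' `sum(ceiling(length / width))`. On the 16 sacCer3 nuclear chromosomes
#' with the default 100-kb width this yields 128 bins.
#'
#' @param genome a `genome_map` (or named vector of chromosome lengths).
#' @param width bin width in bp (default 1e5).
#' @return data.frame with columns `chrom`, `bin` (0-based index within
#'   chromosome), `start`, `end` (1-based inclusive bp).
#' @export
make_genome_bins <- function(genome, width = 1e5) {
  if (width <= 0) stop("bin width must be positive")
  lens <- if (inherits(genome, "genome_map")) genome$chrom_lengths else genome
  out <- lapply(names(lens), function(chrom) {
    n <- ceiling(lens[[chrom]] / width)
    k <- seq_len(n) - 1
    data.frame(
      chrom = chrom, bin = k,
      start = k * width + 1,
      end = pmin((k + 1) * width, lens[[chrom]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Count peaks per genome bin
#'
#' Each peak increments exactly one half-open bin (its 0-based coordinate
#' `pos - 1` integer-divided by the bin width).
#'
#' @param bins data.frame from [make_genome_bins()].
#' @param peaks data.frame with columns `chrom` and `peak` (1-based bp).
#' @return `bins` with an added `count` column.
#' @export
count_per_bin <- function(bins, peaks) {
  width <- bins$end[1] - bins$start[1] + 1
  bins$count <- 0L
  if (nrow(peaks) == 0) return(bins)
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    pos <- peaks$peak[i]
    sel <- bins$chrom == chrom
    if (!any(sel)) stop("peak record ", i, " on unknown chromosome ", chrom)
    chrom_end <- max(bins$end[sel])
    if (pos < 1 || pos > chrom_end) {
      stop("peak record ", i, " at ", chrom, ":", pos,
           " lies outside the chromosome")
    }
    k <- (pos - 1) %/% width
    bins$count[sel & bins$bin == k] <- bins$count[sel & bins$bin == k] + 1L
  }
  bins
}

#' Spearman correlation between QTL and GxE counts across occupied bins
#'
#' Restricts to bins containing at least one QTL and correlates total QTL
#' count with GxE-call count (average ranks for ties, p-value by the
#' t-approximation).
#'
#' @param qtl_counts,gxe_counts integer vectors over the same bins.
#' @return list with `rho`, `p`, `n_bins` (bins with >= 1 QTL).
#' @export
bin_correlation <- function(qtl_counts, gxe_counts) {
  stopifnot(length(qtl_counts) == length(gxe_counts))
  keep <- qtl_counts >= 1
  if (sum(keep) < 3) stop("need at least 3 bins with a QTL")
  ct <- suppressWarnings(
    stats::cor.test(qtl_counts[keep], gxe_counts[keep],
                    method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n_bins = sum(keep))
}

#' Exact binomial test for the direction of allelic effects
#'
#' Tests whether QTLs where the RM allele increases the trait (positive
#' smoothed allele-frequency difference) occur more or less often than half
#' the time, with the exact two-sided (minimum-likelihood) binomial test.
#'
#' @param daf numeric vector of per-QTL allele-frequency differences.
#' @return list with `k` (positive-effect count), `n`, `p`.
#' @export
direction_binomial_test <- function(daf) {
  if (length(daf) < 1) stop("need at least one QTL")
  k <- sum(daf > 0)
  n <- length(daf)
  list(k = k, n = n, p = stats::binom.test(k, n, p = 0.5)$p.value)
}
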