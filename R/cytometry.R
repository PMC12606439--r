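#' Gate events to within +/-10% of the median forward scatter
#'
#' Retains cells with `fsc` in `[0.9 * m, 1.1 * m]` where `m` is the median
#' FSC of the input (midpoint of the middle two for even counts, R's
#' default). Removes debris and aggregates; idempotent on its own output.
#'
#' @param events event table with an `fsc` column.
#' @return the gated event table.
#' @export
gate_size <- function(events) {
  if (nrow(events) == 0) stop("empty event table")
  m <- stats::median(events$fsc)
  events[events$fsc >= 0.9 * m & events$fsc <= 1.1 * m, , drop = FALSE]
}

#' Select the lower-FSC mode of a bimodal size distribution
#'
#' Low-nitrogen samples show two FSC peaks (incompletely budded daughter
#' cells); only the smaller-cell mode is analyzed. The FSC density is
#' estimated on the log scale (Gaussian kernel, Silverman's rule); if two or
#' more local maxima exist, events below the deepest local minimum between
#' the two highest maxima are returned. Unimodal input passes unchanged.
#'
#' @param events event table with an `fsc` column.
#' @return event table restricted to the lower-FSC mode.
#' @export
select_lower_fsc_mode <- function(events) {
  if (nrow(events) == 0) stop("empty event table")
  x <- log(events$fsc)
  if (length(x) < 3 || stats::sd(x) == 0) return(events)
  d <- stats::density(x, bw = "nrd0")
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
              FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) return(events)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  split_at <- d$x[between[which.min(y[between])]]
  events[x < split_at, , drop = FALSE]
}

#' Time-corrected per-cell activity
#'
#' The raw per-cell activity is `-log2(rfp/gfp)`. Instrument drift over the
#' acquisition window is removed with the residuals of a local-linear loess
#' regression of the raw ratio on time; the residuals are recentred and the
#' sample mean of the raw ratio is added back, so between-sample activity
#' differences survive the correction and the sample mean is preserved
#' exactly. Events with non-positive fluorescence are dropped and counted.
#'
#' @param events gated event table with `time_s`, `gfp`, `rfp`.
#' @param span loess span (default 0.75).
#' @return numeric vector of corrected activities, with attribute
#'   `n_dropped` (events removed for non-positive fluorescence).
#' @export
time_corrected_activity <- function(events, span = 0.75) {
  ok <- events$rfp > 0 & events$gfp > 0
  n_dropped <- sum(!ok)
  events <- events[ok, , drop = FALSE]
  if (nrow(events) < 30) {
    stop("fewer than 30 usable events: drift fit unstable")
  }
  raw <- -log2(events$rfp / events$gfp)
  if (stats::sd(raw) == 0) {
    corrected <- raw
  } else {
    fit <- stats::loess(raw ~ time_s, data = data.frame(raw = raw,
                                                        time_s = events$time_s),
                        span = span, degree = 1, family = "gaussian")
    res <- raw - stats::predict(fit, newdata = data.frame(time_s = events$time_s))
    corrected <- res - mean(res) + mean(raw)
  }
  attr(corrected, "n_dropped") <- n_dropped
  corrected
}

#' Summarize one cytometry replicate
#'
#' Applies the gating chain (lower-FSC mode selection for low-nitrogen
#' samples, then the +/-10% FSC gate), drift correction, and reports the
#' median (and mean) corrected activity together with the median GFP of the
#' gated events.
#'
#' @param events raw event table.
#' @param strain,reporter,environment,replicate,plate metadata fields.
#' @param low_nitrogen whether to select the lower FSC mode first.
#' @param span loess span for drift correction.
#' @return one-row data.frame: metadata, `n_events_gated`, `median_gfp`,
#'   `activity` (median corrected), `mean_activity`, `excluded`, `reason`.
#' @export
summarize_replicate <- function(events, strain, reporter, environment,
                                replicate, plate = 1L, low_nitrogen = FALSE,
                                span = 0.75) {
  if (nrow(events) < 100) stop("need at least 100 events to summarize")
  if (low_nitrogen) events <- select_lower_fsc_mode(events)
  gated <- gate_size(events)
  corrected <- time_corrected_activity(gated, span = span)
  data.frame(
    strain = strain, reporter = reporter, environment = environment,
    replicate = replicate, plate = plate,
    n_events_gated = nrow(gated),
    median_gfp = stats::median(gated$gfp),
    activity = stats::median(corrected),
    mean_activity = mean(corrected),
    excluded = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Exclude reporter/environment groups with GFP below the negative control
#'
#' If any replicate in a (reporter, environment) group has a median GFP
#' strictly below the negative control's, the reporter cannot be measured in
#' that environment and every replicate of the group is excluded.
#'
#' @param summaries data.frame of replicate summaries
#'   (from [summarize_replicate()]).
#' @param control_median_gfp median GFP of the no-reporter control strain.
#' @return `summaries` with `excluded` / `reason` updated.
#' @export
apply_negative_control_exclusion <- function(summaries, control_median_gfp) {
  key <- interaction(summaries$reporter, summaries$environment, drop = TRUE)
  for (g in levels(key)) {
    idx <- key == g
    if (any(summaries$median_gfp[idx] < control_median_gfp)) {
      summaries$excluded[idx] <- TRUE
      summaries$reason[idx] <- "gfp_below_control"
    }
  }
  summaries
}
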