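#' Fit the strain-by-environment interaction model for one reporter
#'
#' Fits `activity ~ strain * environment + (1 | replicate)` on the records
#' of one reporter in the baseline environment and one comparison
#' environment. The random intercept groups biological replicates
#' (independent transformants) within strain; by default replicate IDs are
#' shared across environments (the same transformant measured everywhere).
#' ANOVA p-values (type II, Satterthwaite) are reported for the strain,
#' environment and interaction terms. If the random-effect variance is
#' estimated at zero or the mixed fit is degenerate, a fixed-effects two-way
#' ANOVA (type II) is used instead and flagged.
#'
#' @param records data.frame with columns `strain`, `reporter`,
#'   `environment`, `replicate`, `activity` (one row per replicate).
#' @param reporter reporter to test.
#' @param env comparison environment.
#' @param baseline baseline environment (default "SC").
#' @param replicate_within_strain if TRUE (default) the random-intercept
#'   group is the strain:replicate combination (replicates are independent
#'   transformants per strain).
#' @return one-row data.frame: `reporter`, `environment`, `p_strain`,
#'   `p_environment`, `p_interaction`, `fallback_used`.
#' @export
fit_interaction_model <- function(records, reporter, env, baseline = "SC",
                                  replicate_within_strain = TRUE) {
  d <- records[records$reporter == reporter &
                 records$environment %in% c(baseline, env), , drop = FALSE]
  d$strain <- factor(d$strain)
  d$environment <- factor(d$environment, levels = c(baseline, env))
  cell_n <- table(d$strain, d$environment)
  if (any(dim(cell_n) != c(2, 2)) || any(cell_n < 2)) {
    stop("need both strains and both environments with >= 2 replicates")
  }
  d$rep_group <- if (replicate_within_strain) {
    interaction(d$strain, d$replicate, drop = TRUE)
  } else {
    factor(d$replicate)
  }
  fallback <- FALSE
  p <- NULL
  est <- NULL
  fit <- if (stats::sd(d$activity) == 0) NULL else tryCatch(
    suppressMessages(lmerTest::lmer(
      activity ~ strain * environment + (1 | rep_group), data = d)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    an <- suppressMessages(stats::anova(fit, type = 2))
    p <- an[["Pr(>F)"]]
    names(p) <- rownames(an)
    est <- lme4::fixef(fit)
  } else {
    fallback <- TRUE
    lmfit <- stats::lm(activity ~ strain * environment, data = d)
    est <- stats::coef(lmfit)
    if (stats::sd(d$activity) == 0) {
      # constant response: all effects are exactly zero, no test to run
      est[] <- c(d$activity[1], 0, 0, 0)
      p <- c(strain = NA_real_, environment = NA_real_,
             "strain:environment" = NA_real_)
    } else {
      an <- car::Anova(lmfit, type = 2)
      p <- an[["Pr(>F)"]]
      names(p) <- rownames(an)
    }
  }
  data.frame(
    reporter = reporter, environment = env,
    p_strain = unname(p["strain"]),
    p_environment = unname(p["environment"]),
    p_interaction = unname(p["strain:environment"]),
    est_strain = unname(est[2]),
    est_environment = unname(est[3]),
    est_interaction = unname(est[4]),
    fallback_used = fallback,
    stringsAsFactors = FALSE
  )
}

#' Flag Bonferroni-significant interaction tests within one family
#'
#' The family size is the number of tests actually fitted after exclusions;
#' a test is significant when `p_interaction < alpha / m`.
#'
#' @param results data.frame of interaction-test rows.
#' @param alpha family-wise error rate (default 0.05).
#' @return `results` with `m`, `threshold`, `significant` columns added.
#' @export
bonferroni_family <- function(results, alpha = 0.05) {
  m <- nrow(results)
  if (m == 0) stop("empty test family")
  results$m <- m
  results$threshold <- alpha / m
  results$significant <- results$p_interaction < alpha / m
  results
}

#' Environment effect on activity for one strain and reporter
#'
#' `delta = mean(activity in env) - mean(activity in baseline)`; negative
#' values mean the environment lowered activity. For plate-paired reporters
#' (those whose plates each carry their own baseline samples) the baseline
#' mean is taken from the same plate as each environment record, so plate
#' offsets cancel.
#'
#' @param records activity record data.frame.
#' @param strain,reporter,env selection.
#' @param baseline baseline environment (default "SC").
#' @param plate_paired use same-plate baselines (default FALSE).
#' @return the delta (numeric scalar).
#' @export
environment_effect <- function(records, strain, reporter, env,
                               baseline = "SC", plate_paired = FALSE) {
  d <- records[records$strain == strain & records$reporter == reporter, ,
               drop = FALSE]
  e <- d[d$environment == env, , drop = FALSE]
  b <- d[d$environment == baseline, , drop = FALSE]
  if (nrow(b) == 0) stop("missing baseline records")
  if (nrow(e) == 0) stop("missing environment records")
  if (!plate_paired) {
    return(mean(e$activity) - mean(b$activity))
  }
  base_by_plate <- tapply(b$activity, b$plate, mean)
  if (any(!as.character(e$plate) %in% names(base_by_plate))) {
    stop("missing same-plate baseline")
  }
  mean(e$activity - base_by_plate[as.character(e$plate)])
}

#' Per-strain Welch t-tests of each environment against baseline
#'
#' Two-tailed Welch (unequal-variance) t-tests comparing activity between
#' the baseline and every other environment, separately for each strain and
#' reporter. The Bonferroni family is twice the interaction-model family
#' (one test per strain).
#'
#' @param records activity record data.frame.
#' @param baseline baseline environment (default "SC").
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame `strain, reporter, environment, t, p, m, threshold,
#'   significant`.
#' @export
per_strain_ttests <- function(records, baseline = "SC", alpha = 0.05) {
  combos <- unique(records[records$environment != baseline,
                           c("strain", "reporter", "environment")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$strain[i]; r <- combos$reporter[i]; e <- combos$environment[i]
    x <- records$activity[records$strain == s & records$reporter == r &
                            records$environment == e]
    y <- records$activity[records$strain == s & records$reporter == r &
                            records$environment == baseline]
    if (length(x) < 2 || length(y) < 2) {
      stop("need >= 2 replicates per group for ", s, "/", r, "/", e)
    }
    if (stats::sd(c(x, y)) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
    }
    data.frame(strain = s, reporter = r, environment = e,
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$m <- nrow(out)
  out$threshold <- alpha / nrow(out)
  out$significant <- out$p < out$threshold
  out
}
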