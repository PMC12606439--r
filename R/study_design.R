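#' Reporters and environments of the UPS GxE study design
#'
#' Six degron/reporter constructs and eight media environments (SC is the
#' baseline). The 4xUb and UFD reporters cannot be measured in low
#' nitrogen (GFP below the negative control), which the simulated study
#' reproduces.
#'
#' @name study_design
#' @export
UPS_REPORTERS <- c("Asn", "Phe", "Thr", "Rpn4", "4xUb", "UFD")

#' @rdname study_design
#' @export
UPS_ENVIRONMENTS <- c("SC", "low_glucose", "low_nitrogen", "YNB",
                      "4NQO", "AZC", "BTZ", "LiAc")

#' Simulate replicate-level activity summaries for a full study
#'
#' Generates one activity record per (strain, reporter, environment,
#' replicate) with the variance structure of replicate-summarized cytometry
#' data: a per-transformant (replicate-within-strain) random intercept
#' shared across environments, plus residual noise. Strain, environment and
#' interaction effects are configurable per reporter/environment. Reporter
#' and environment combinations listed in `gfp_failures` get a median GFP
#' below the negative control so the downstream exclusion rule fires.
#'
#' @param reporters,environments design labels (defaults: the 6 reporters
#'   and 8 environments of the study).
#' @param n_replicates biological replicates per combination (default 8).
#' @param strain_effect,env_effect fixed effect sizes (activity units).
#' @param interaction_effect strain-by-environment interaction effect
#'   applied to non-baseline environments of the RM strain (default 0).
#' @param replicate_sd SD of the transformant random intercept
#'   (default 0.85).
#' @param residual_sd residual SD per record (default 0.5). The defaults
#'   split a unit total SD between transformant identity and measurement
#'   noise; replicate medians over tens of thousands of cells are precise,
#'   so most replicate-to-replicate scatter is biological.
#' @param gfp_level,control_gfp median GFP of measurable samples and of the
#'   negative control.
#' @param gfp_failures data.frame with `reporter`, `environment` columns
#'   naming combinations whose GFP falls below the control (default: 4xUb
#'   and UFD in low nitrogen).
#' @param baseline baseline environment name (default "SC").
#' @param seed integer seed.
#' @return data.frame of activity records with `median_gfp`, `excluded`,
#'   `reason` columns ready for [apply_negative_control_exclusion()].
#' @export
simulate_activity_study <- function(reporters = UPS_REPORTERS,
                                    environments = UPS_ENVIRONMENTS,
                                    n_replicates = 8,
                                    strain_effect = 0.5, env_effect = -0.5,
                                    interaction_effect = 0,
                                    replicate_sd = 0.85, residual_sd = 0.5,
                                    gfp_level = 2000, control_gfp = 150,
                                    gfp_failures = data.frame(
                                      reporter = c("4xUb", "UFD"),
                                      environment = c("low_nitrogen",
                                                      "low_nitrogen")),
                                    baseline = "SC", seed = 1) {
  set.seed(seed)
  strains <- c("BY", "RM")
  grid <- expand.grid(
    replicate = seq_len(n_replicates), environment = environments,
    strain = strains, reporter = reporters,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  rep_key <- paste(grid$reporter, grid$strain, grid$replicate)
  u <- stats::rnorm(length(unique(rep_key)), 0, replicate_sd)
  names(u) <- unique(rep_key)
  non_base <- grid$environment != baseline
  mu <- strain_effect * (grid$strain == "RM") +
    env_effect * non_base +
    interaction_effect * (grid$strain == "RM") * non_base
  grid$activity <- mu + u[rep_key] +
    stats::rnorm(nrow(grid), 0, residual_sd)
  grid$plate <- 1L
  grid$median_gfp <- stats::rlnorm(nrow(grid), log(gfp_level), 0.1)
  if (nrow(gfp_failures) > 0) {
    for (i in seq_len(nrow(gfp_failures))) {
      hit <- grid$reporter == gfp_failures$reporter[i] &
        grid$environment == gfp_failures$environment[i]
      grid$median_gfp[hit] <- stats::rlnorm(sum(hit), log(control_gfp / 2),
                                            0.1)
    }
  }
  grid$excluded <- FALSE
  grid$reason <- NA_character_
  grid[, c("strain", "reporter", "environment", "replicate", "plate",
           "activity", "median_gfp", "excluded", "reason")]
}

#' Enumerate the interaction-test family after exclusions
#'
#' The model-test family contains one strain-by-environment interaction
#' test per (reporter, non-baseline environment) combination that survives
#' the negative-control exclusion; the per-strain t-test family is twice
#' that size. Bonferroni thresholds follow from the family sizes.
#'
#' @param summaries activity records after
#'   [apply_negative_control_exclusion()].
#' @param baseline baseline environment (default "SC").
#' @param alpha family-wise error rate (default 0.05).
#' @return list: `tests` (data.frame reporter x environment), `n_model_tests`,
#'   `model_threshold`, `n_ttests`, `ttest_threshold`.
#' @export
gxe_test_family <- function(summaries, baseline = "SC", alpha = 0.05) {
  keep <- !summaries$excluded & summaries$environment != baseline
  tests <- unique(summaries[keep, c("reporter", "environment")])
  rownames(tests) <- NULL
  m <- nrow(tests)
  list(tests = tests, n_model_tests = m, model_threshold = alpha / m,
       n_ttests = 2 * m, ttest_threshold = alpha / (2 * m))
}

#' Simulate activity records for one reporter's 2x2 interaction design
#'
#' Minimal generator for calibration and power studies of the interaction
#' model: two strains by two environments with `n_replicates` transformant
#' replicates shared across environments.
#'
#' @param n_replicates replicates per strain (default 8).
#' @param interaction_effect interaction coefficient (activity units;
#'   default 0 for the null).
#' @param strain_effect,env_effect main effects (default 0).
#' @param replicate_sd,residual_sd variance components (defaults 0.85 and
#'   0.5, as in [simulate_activity_study()]).
#' @param seed integer seed.
#' @return data.frame `strain, reporter, environment, replicate, activity`.
#' @export
simulate_interaction_records <- function(n_replicates = 8,
                                         interaction_effect = 0,
                                         strain_effect = 0, env_effect = 0,
                                         replicate_sd = 0.85,
                                         residual_sd = 0.5, seed = 1) {
  simulate_activity_study(
    reporters = "R1", environments = c("SC", "E1"),
    n_replicates = n_replicates, strain_effect = strain_effect,
    env_effect = env_effect, interaction_effect = interaction_effect,
    replicate_sd = replicate_sd, residual_sd = residual_sd,
    gfp_failures = data.frame(reporter = character(),
                              environment = character()),
    seed = seed
  )[, c("strain", "reporter", "environment", "replicate", "activity")]
}
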