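#!/usr/bin/env Rscript
# Stage 2: strain-level GxE from replicate activity summaries.
#
# Simulates the full measurement design (6 reporters x 8 environments x 2
# strains x 8 transformant replicates), applies the negative-control GFP
# exclusion (4xUb and UFD cannot be measured in low nitrogen), counts the
# resulting test families, fits the strain x environment interaction model
# per reporter/environment, and runs the per-strain environment t-tests.
# Writes results/gxe_tests.tsv and results/strain_ttests.tsv.

suppressPackageStartupMessages(library(gxemap))

seed <- 20250929L
dir.create("results", showWarnings = FALSE)

# one reporter/environment pair (Thr in low glucose) carries a constructed
# 3-unit interaction so the pipeline has a clear true positive to find
study <- simulate_activity_study(seed = seed)
hit <- simulate_activity_study(reporters = "Thr",
                               environments = c("SC", "low_glucose"),
                               interaction_effect = 3, seed = seed + 1L)
key <- function(d) paste(d$strain, d$environment, d$replicate)
sel <- study$reporter == "Thr" & study$environment %in% c("SC", "low_glucose")
study$activity[sel] <- hit$activity[match(key(study[sel, ]), key(hit))]

study <- apply_negative_control_exclusion(study, control_median_gfp = 150)
fam <- gxe_test_family(study)
cat(sprintf("test family after exclusions: %d interaction tests (threshold %.5g), %d t-tests (threshold %.5g)\n",
            fam$n_model_tests, fam$model_threshold,
            fam$n_ttests, fam$ttest_threshold))

usable <- study[!study$excluded, ]
fits <- do.call(rbind, lapply(seq_len(nrow(fam$tests)), function(i) {
  fit_interaction_model(usable, fam$tests$reporter[i],
                        fam$tests$environment[i])
}))
fits <- bonferroni_family(fits)
write.table(fits, "results/gxe_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d of %d interaction tests Bonferroni-significant (expected: the constructed Thr/low_glucose interaction)\n",
            sum(fits$significant), nrow(fits)))
print(fits[fits$significant,
           c("reporter", "environment", "p_interaction", "threshold")])

tt <- per_strain_ttests(usable)
write.table(tt, "results/strain_ttests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d of %d per-strain environment contrasts significant at %.5g\n",
            sum(tt$significant), nrow(tt), tt$threshold[1]))

delta <- environment_effect(usable, "BY", "Thr", "low_glucose")
cat(sprintf("environment effect (BY, Thr, low_glucose vs SC): %.3f activity units\n",
            delta))
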