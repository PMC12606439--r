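---
title: "Models and methods behind gxemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gxemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gxemap implements the computational chain used to detect
genotype-by-environment interactions (GxE) in ubiquitin–proteasome-system
(UPS) activity in a BY x RM yeast cross: processing of tandem-fluorescent-
timer cytometry into replicate activity summaries, strain-level interaction
tests, bulk-segregant QTL mapping from sorted-pool sequencing, replicate
reconciliation, and rule-based locus-level GxE classification. This
vignette records the models, the parameter choices, and the reasoning
behind decisions the method descriptions leave open.

## Cytometry processing

Each replicate sample is a table of per-cell events (acquisition time,
forward/side scatter, GFP, RFP). The reporter is a GFP–RFP timer fusion:
because the two fluorophores mature at different rates, `-log2(RFP/GFP)`
increases with the substrate's degradation rate, and we call its
time-corrected version *UPS activity*.

Processing steps, in order:

1. **Lower-FSC mode selection** (low-nitrogen samples only). These samples
   show two cell-size modes, attributed to incomplete budding. The FSC
   density is estimated on the log scale with a Gaussian kernel
   (Silverman's bandwidth); when at least two local maxima exist, events
   below the deepest minimum between the two highest maxima are kept. We
   read "the smaller of the two peaks" as the lower-FSC mode (not the less
   populated one): the method text notes that the retained mode's median
   FSC resembles the other samples', which only the lower-FSC reading
   guarantees.
2. **Size gate**: events within ±10% of the sample's median FSC. The gate
   is not exactly idempotent on skewed samples — regating shifts the
   retained median slightly — but in practice a second pass retains >98%
   of events; the exact invariant holds for symmetric samples.
3. **Drift correction**: the raw ratio drifts over the acquisition window,
   so we take residuals of a local-linear loess of the raw ratio on time
   (span 0.75 by default — wide enough to track instrument drift without
   absorbing cell-level noise), recentre them, and add back the sample
   mean. Plain residuals would centre every sample at zero and erase the
   between-sample differences the analysis needs; the recentring makes
   mean preservation exact rather than approximate. A consequence worth
   stating plainly: the *time-average* of the drift stays in the reported
   level (it cannot be distinguished from baseline within a single
   sample); what correction removes is the trend and the drift-induced
   spread. Events with non-positive fluorescence are dropped (and counted)
   before the log-ratio; fewer than 30 usable events is an error.
4. **Summary**: activity = median of corrected values (mean also
   reported), with the gated event count and median GFP.
5. **Negative-control exclusion**: if any replicate of a
   (reporter, environment) group has median GFP strictly below the
   no-reporter control, the whole group is excluded — the reporter cannot
   be measured in that environment. In the full 6-reporter x 8-environment
   design this removes 4xUb and UFD in low nitrogen, leaving 40
   interaction tests and 80 per-strain t-tests; the Bonferroni thresholds
   0.05/40 = 0.00125 and 0.05/80 = 0.000625 fall out of this family
   counting rather than being hard-coded.

## Strain-level GxE

For one reporter and one environment pair (baseline SC versus a stress
environment) we fit

    activity ~ strain * environment + (1 | replicate)

with `lme4`/`lmerTest` and report type-II Satterthwaite ANOVA p-values for
the three fixed terms. Replicates are independent transformants per
strain, so the random intercept groups strain:replicate; we assume the
same transformant is measured in all environments (the IDs are shared),
with a switch for the alternative. If the random-effect variance is
estimated at zero or the fit is otherwise degenerate, we fall back to a
fixed-effects two-way ANOVA (type II via `car::Anova`) and flag it; with
balanced designs the SS types coincide. Per-strain environment contrasts
use Welch t-tests (the method descriptions say "two-tailed t-test" without
specifying pooling; unequal variances are the safer default).
Environment effects are `mean(env) - mean(SC)` per strain; for reporters
whose plates carry their own SC baseline the same-plate baseline is used,
so plate offsets cancel.

The replicate-summary generator used in tests splits a unit total SD into
a transformant intercept of 0.85 and residual noise of 0.5. Replicate
medians are computed from tens of thousands of cells and are very precise,
so most replicate-to-replicate scatter is biological (transformant
identity) rather than measurement error; the interaction contrast cancels
the shared intercept, which is what gives the design its power (a 3-SD
interaction with 8 replicates is detected at the 0.00125 threshold
essentially always, while the null test size stays at 5%).

## Sorted-pool QTL mapping

Segregant pools from the 2% high/low tails of the activity distribution
are sequenced, giving BY/RM read counts at each marker for both pools. The
mapping model is our own implementation of the familiar contrast between a
one-population model (both pools share an allele frequency) and a
two-population model (frequencies differ), expressed per genomic bin:

* **Variant filter**: markers whose RM fraction in the *pooled* counts of
  both pools falls below 0.1 or above 0.9 (strict), or with zero depth in
  either pool, are removed. Applying the 0.1/0.9 rule per pool is exposed
  as an option but is not the default: truncation selection legitimately
  pushes a single pool's frequency past 0.9 at a strong QTL, so a per-pool
  filter deletes exactly the most informative markers and punches gaps
  into the LOD track; the pooled version targets what the rule is for —
  globally distorted markers.
* **Binning**: 100-bp half-open bins on 0-based coordinates; empty bins
  are kept so genetic distance per step is constant.
* **Effective pool size**: counts are shrunk so a bin's total equals
  `d * N / (d + N)` — read depth cannot convey more information about the
  pool than the `N` segregants it contains. `N` defaults to 1000, the
  conventional conservative setting for experimental pools of ~20,000
  sorted cells. When mapping *simulated* pools whose segregant count is
  known, analyses set `N` to that count (40–100 in the test conditions):
  that is what the parameter means, and leaving it at 1000 overstates the
  information in a small pool and miscalibrates the null.
* **Hidden-state model**: the pool's RM frequency lives on a 100-point
  grid (0.005–0.995). The chain moves bin to bin with a Gaussian kernel of
  variance `c * r * p(1-p)` (`c` = 1, `r` = per-bin recombination fraction
  from the 2,200 bp/cM map scale via Haldane), floored at one grid step
  squared so the kernel stays proper near the boundaries; rows are
  normalized. Emissions are binomial kernels `p^RM (1-p)^BY` with
  real-valued exponents, normalized over the grid. Forward–backward runs
  with per-bin rescaling (equivalent to log-space scaling); posteriors are
  the normalized products of the scaled messages. Exhaustive path
  enumeration on small chains pins the implementation to 1e-9.
* **Contrast LOD**: with grid-normalized smoothed posteriors `A_H`, `A_L`
  and a uniform prior, `lod = -log10(G * sum_p A_H(p) A_L(p))` — the
  log10 Bayes factor of "frequencies free" against "frequencies tied at
  this bin". Identical pools give non-positive values; bins with no data
  give 0 up to a ~2e-4 boundary leakage of the row-normalized kernel
  (the walk kernel does not leave the uniform distribution exactly
  invariant; we accept this rather than re-balancing the kernel away from
  its definition).
* **Effect size**: the allele-frequency difference (dAF) track is the
  difference of per-pool loess smooths of raw marker fractions (span 0.1
  of a chromosome's markers, floored so every local window keeps at least
  8 markers; chromosomes with fewer than 10 markers fall back to a
  Gaussian-kernel moving average, flagged). Positive dAF means the RM
  allele raises activity.
* **Calling**: QTLs are maximal runs of bins with LOD >= 4.5; the peak is
  the leftmost maximum in the run; the support interval extends
  contiguously around the peak while LOD stays within 2 of the peak
  (clipped at chromosome ends); dAF and its sign are read at the peak.

A property of this bin-wise statistic worth knowing: under a strong QTL
the LOD stays above threshold over long linked flanks and jitters bin to
bin (posteriors tighten at marker bins and relax between them), so one
locus can fragment into several runs. The genome-wide top call localizes
well (within a few kb of a simulated 0.75-SD QTL at these problem sizes);
the replicate-reconciliation step, not the single-track run structure, is
the pipeline's unit of evidence.

## Replicate reconciliation and GxE classification

QTLs are called per biological replicate. Loci are "present in both
replicates" when peaks lie on the same chromosome within 100 kb with the
same dAF sign; candidate pairs are matched greedily by increasing peak
distance (each QTL used once; the tie-break is ours — the rule's source
does not state one), and matched pairs average peak, interval bounds, LOD
and dAF. Cross-study overlap uses the same 100-kb peak rule against either
replicate of a prior study, and shared-versus-unique loci are compared on
LOD and |dAF| with Welch t-tests.

Locus-level GxE between SC and another environment is classified from
both-replicate loci ("anchors"):

* **presence/absence** — no peak of either replicate of the other
  environment within 100 kb;
* **sign change** — a peak within 100 kb with the opposite sign (the
  other environment may contribute one or both replicates);
* **no GxE** — a peak within 100 kb with the same sign (magnitude
  differences are deliberately not classified).

When anchors of both environments pair up, the nearest peak defines the
pair and it yields a single call; loci with single-replicate support on
both sides are dropped. Genome-wide context uses 100-kb bins (the 16
nuclear chromosomes tile into exactly 128), Spearman correlation between
per-bin QTL and GxE counts over bins with any QTL (t-approximation
p-value), and an exact binomial test of whether positive-dAF loci
outnumber half.

## What the simulator emulates — and what it does not

The generator produces: haploid segregants with 50/50 marker segregation
and Haldane (no-interference) crossovers at 2,200 bp/cM; additive QTL
effects whose per-environment multipliers in {+1, 0, -1} construct no-GxE,
presence/absence and sign-change loci by design; truncation selection of
the 2% phenotypic tails (selection acts on the trait directly, with an
optional per-cell noise term — the realized selection differential of
FACS on noisy single-cell ratios is not asserted); Poisson depth and
binomial read sampling at ~640-bp marker spacing (the density of the real
18,871-marker panel); and cytometry event streams with log-normal scatter
and fluorescence, configurable drift, and a bimodal-FSC low-nitrogen mode.
Defaults are the study's conditions (2% tails; 8 replicates; the
6-reporter x 8-environment design with the two low-nitrogen exclusions).

It does not emulate: diploid intermediates or sporulation, crossover
interference, sequencing errors beyond binomial sampling, read alignment
artifacts, spectral spillover or doublets, or cell-to-cell reporter
dynamics. Passing tests therefore demonstrate the *pipeline's* behavior
under its stated statistical assumptions, not robustness to the
real data's full error structure.

One honest consequence of small simulated pools (40–100 segregants):
segregant sampling creates real chromosome-scale allele-frequency
differences between pools, so a single replicate occasionally shows a
spurious call with |dAF| ≈ 0.2–0.4 even without any QTL. The two-replicate
requirement is what controls these — both-replicate false calls are
absent in most 10-genome null studies, though a rare seed produces one —
and the same effect occasionally places a single-replicate spurious call
within 100 kb of a true presence/absence locus, downgrading it to no-GxE
(the classification is conservative by construction).

## Problem sizes used by the tests

The packaged studies use scaled-down genomes chosen to keep the relevant
length scales intact (chromosomes of 350–600 kb versus 100-kb matching
windows and ~50-kb support intervals): null calibration on 10 two-
chromosome genomes (n = 2,000 segregants, depth 50); single-QTL recovery
and GxE-category recovery on 10 seeds each (effect 0.75 SD, n = 5,000,
depth 100, two environments, two replicates); 200 null and 100 alternative
datasets for the interaction-model calibration; 20,000-event samples for
drift correction. `scripts/acceptance.R` re-runs the same studies from a
command-line seed.
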