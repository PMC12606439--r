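# gxemap

Genotype-by-environment interactions (GxE) in quantitative cellular traits,
mapped by bulk segregant analysis of a yeast cross. The package implements
the full computational chain used to study how natural variation between a
laboratory (BY) and a vineyard (RM) strain of *Saccharomyces cerevisiae*
shapes ubiquitin–proteasome-system (UPS) activity across environments:

1. **Cytometry processing** — per-cell tandem-timer event tables
   (time, FSC, GFP, RFP) are gated to ±10% of median cell size, the
   `-log2(RFP/GFP)` degradation-rate ratio is corrected for acquisition-time
   drift with loess residuals (sample mean preserved exactly), and
   reporter/environment groups whose GFP falls below the negative control
   are excluded.
2. **Strain-level GxE** — `activity ~ strain * environment + (1|replicate)`
   mixed models per reporter (Satterthwaite type-II ANOVA, fixed-effects
   fallback for degenerate fits), Bonferroni families counted from the
   design itself, per-strain Welch t-tests and environment-effect deltas.
3. **Pool mapping** — per-bin LOD scores contrasting the high- and
   low-activity sorted pools' allele frequencies under a discretized
   hidden-state random-walk model (100-bp bins, 2,200 bp/cM, effective pool
   size correction), loess-smoothed allele-frequency differences (ΔAF),
   and QTL calls at LOD ≥ 4.5 with 2-LOD support intervals. Positive ΔAF
   means the RM allele raises activity.
4. **Replicate reconciliation** — loci detected in both biological
   replicates (peaks within 100 kb, same ΔAF sign) are merged by averaging;
   100-kb overlap against prior studies; Welch comparisons of shared versus
   study-unique loci.
5. **GxE classification** — both-replicate loci are classified against the
   other environment as presence/absence (no peak within 100 kb in either
   replicate), sign change (opposite ΔAF within 100 kb), or no GxE;
   genome-wide clustering uses 100-kb bins (the 16 nuclear sacCer3
   chromosomes tile into exactly 128), Spearman bin correlations and an
   exact binomial test of effect direction.
6. **Synthetic crosses** — a first-class generator (Haldane recombination,
   additive QTLs with per-environment multipliers in {+1, 0, −1},
   truncation selection of 2% phenotypic tails, Poisson/binomial read
   sampling, cytometry event streams with drift) so every stage is testable
   without external data.

The LOD at a bin is the log10 Bayes factor of "pool frequencies free"
against "frequencies tied at this bin", computed from grid-normalized
forward–backward posteriors `A_H`, `A_L` over a 100-point frequency grid:
`lod = -log10(G * Σ_p A_H(p) A_L(p))`. Forward–backward is verified against
exhaustive path enumeration to 1e-9.

## Worked example

The `analysis/` scripts run a complete demonstration: a two-replicate,
three-chromosome cross with one constructed locus of each GxE category
(effect 0.75 SD, n = 5,000 segregants, 2% tails, 100× depth), mapped and
classified end to end.

```sh
Rscript analysis/01_simulate_cross.R      # cross, pools, read counts
Rscript analysis/02_cytometry_gxe.R       # strain-level interaction tests
Rscript analysis/03_map_qtls.R            # LOD tracks and QTL calls
Rscript analysis/04_reconcile_classify.R  # merging, GxE calls, binning
```

Stage 2 prints the design arithmetic and finds the one constructed
interaction (Thr in low glucose, 3 activity-unit interaction):

```
test family after exclusions: 40 interaction tests (threshold 0.00125), 80 t-tests (threshold 0.000625)
1 of 40 interaction tests Bonferroni-significant (expected: the constructed Thr/low_glucose interaction)
   reporter environment p_interaction threshold
15      Thr low_glucose  9.599257e-06   0.00125
```

The 40 comes from 6 reporters × 7 environment contrasts minus the two
combinations the GFP exclusion removes (4xUb and UFD in low nitrogen).

Stage 3 maps each replicate/environment track:

```
SC rep 1: 0 markers filtered, 17 QTL calls; top chr1:292750  LOD 76.6  dAF +0.73
SC rep 2: 0 markers filtered, 25 QTL calls; top chr2:298550  LOD 69.7  dAF +0.71
ENV rep 1: 0 markers filtered, 12 QTL calls; top chr1:292750  LOD 76.8  dAF +0.73
ENV rep 2: 0 markers filtered, 17 QTL calls; top chr3:311950  LOD 64.4  dAF -0.69
```

All three constructed loci (truth at 300 kb) are found within ~12 kb with
the constructed signs — positive dAF on chr1/chr2 (RM allele raises
activity), negative on chr3 in the stress environment. A strong locus
fragments into several threshold runs along its linked flanks; replicate
reconciliation, not the raw run count, is the unit of evidence.

Stage 4 merges replicates and classifies the SC-versus-environment pairs:

```
SC: 11 loci in both replicates, 20 in one
ENV: 5 loci in both replicates, 19 in one
GxE classification of locus comparisons:
          no_gxe presence_absence      sign_change
               4                4                4
  chrom anchor_peak anchor_env    category sign_base sign_other
1  chr1    295000.5         SC      no_gxe         +          +
5  chr2    296950.5         SC      no_gxe         +          +
8  chr3    300150.5         SC sign_change         +          -
RM allele raises activity at 13 of 16 both-replicate loci (binomial p = 0.0213)
```

chr1 (no GxE) and chr3 (sign change) are classified as constructed. The
chr2 presence/absence locus is downgraded to no-GxE in this particular
simulation because one stress-environment replicate carries a spurious
single-replicate call (LOD 5.0, dAF +0.19) within 100 kb — exactly the
conservatism the classification rule is designed to have: across 10 seeds
the constructed category is recovered for ~97% of loci (see
`results/acceptance.json`).

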