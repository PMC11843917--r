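# greenprot

Quantitative proteomics and antioxidant screening for green-biorefinery
protein fractions.

Green biorefining presses fresh leafy biomass (e.g. perennial ryegrass)
into a fibrous pulp and a protein-rich green juice. The juice is a
promising food-protein stream, but after pressing it becomes a highly
reactive mixture whose oxidative stability depends on its endogenous
antioxidant proteins. `greenprot` implements the downstream analysis
that connects three kinds of bench data into a shortlist of candidate
antioxidant proteins:

1. **Label-free proteomics** — MaxQuant-style protein-group tables for
   crude fractions (grass / pulp / juice triplicates) and
   size-exclusion chromatography (SEC) fractions of the juice.
2. **SEC calibration** — standards and fraction elution volumes, giving
   a per-fraction molecular-weight estimate.
3. **Microplate antioxidant assays** — DPPH radical scavenging (517 nm)
   and ferrozine iron chelation (562 nm) dilution series, giving
   EC50 values in mass and molar units.

A synthetic-data module generates every input with recorded ground
truth (true molar abundances, fragment/isoform structure, true EC50s,
planted enrichment), so the whole pipeline is testable offline.

## Methods at a glance

- **iBAQ / riBAQ / TriBAQ.** iBAQ divides a protein's summed intensity
  by its number of theoretically observable tryptic peptides (cleavage
  after K/R not before P; length ≥ 7 residues, monoisotopic mass
  ≤ 4600 Da by default), making it proportional to molar amount.
  riBAQ<sub>is</sub> = iBAQ<sub>is</sub> / Σ<sub>i</sub> iBAQ<sub>is</sub>
  is the within-sample molar fraction; TriBAQ<sub>i</sub> =
  Σ<sub>f</sub> riBAQ<sub>if</sub> / F summarizes a protein's share
  across all F SEC fractions.
- **Fragment iBAQ recalculation.** Lead proteins annotated
  `"(Fragment)"` carry truncated database sequences that inflate iBAQ.
  Their value is recalculated as iBAQ<sub>rec</sub> = ΣI<sub>p</sub> /
  TP<sub>max</sub>, where TP<sub>max</sub> is the theoretical-peptide
  count of a resolved full-length counterpart (same-name group member →
  same-name lead elsewhere → user-supplied surrogate, e.g. a BLAST
  hit). Recalculated entries are marked `*`; isoforms with identical
  names are merged by summing riBAQ.
- **SEC molecular weight.** K<sub>d</sub> = (V<sub>e</sub> −
  V<sub>0</sub>) / (V<sub>c</sub> − V<sub>0</sub>) is regressed on
  log₁₀(MW) over the standards; fraction MW inverts the line at the
  fraction's mean elution volume. Fractions at or before the void
  volume have no defined MW; estimates outside the standards' range are
  flagged as extrapolated.
- **EC50.** Activity% = (1 − (A_S − A_B)/A_C) · 100 from sample, blank
  and negative-control absorbances; negative-activity points are
  excluded. If any point exceeds 80% activity the series has left the
  locally linear part of the sigmoid and activity is fitted against
  ln(concentration), otherwise against concentration; EC50 solves the
  fit at 50%. EC50[µM] = EC50[µg/mL] / MW[kDa] exactly.
- **Screening.** Candidates are predicted from 4 GO terms and 15
  annotation keywords, then filtered three ways: cross-reference
  against crude-fraction identifications (≥ 2 of 3 replicates),
  a 3-of-4 confidence rule (score ≥ 40; MS/MS, coverage ≥ 5%, unique
  peptides ≥ 2, each in ≥ 2 of 3 juice replicates), and abundance
  (TriBAQ > 0.5% or riBAQ > 1% in any fraction).
- **Crude-fraction statistics.** Crude protein = N% × 6.25; mass/DM/CP
  balances across grass → pulp + juice; LFQ log2 median-centering, NMAR
  imputation from a downshifted normal (mean position factor 1.8, SD
  factor 0.3), Welch t + Benjamini–Hochberg differential calls
  (FDR < 0.05 and |log2FC| > 1), Welch ANOVA with pairwise Welch/Holm
  contrasts for candidate-family riBAQ, and row-Z-score hierarchical
  clustering for reporting.

## Worked example

```r
library(greenprot)

# Mass balance from fresh masses and mean compositions
m <- tibble::tibble(fraction = c("grass", "pulp", "juice"),
                    mass_g  = c(75.2, 32.9, 34.4),
                    dm_pct  = c(19.2, 27.7, 15.5),
                    cp_pct  = c(11.2, 10.4, 12.5))
bal <- mass_balance(m)
bal$mass_loss_g
#> [1] 7.9
dplyr::select(bal$fractions, fraction, dm_distribution_pct, cp_distribution_pct)
#> # A tibble: 3 × 3
#>   fraction dm_distribution_pct cp_distribution_pct
#>   <chr>                  <dbl>               <dbl>
#> 1 grass                  100                 100
#> 2 pulp                    63.1                58.6
#> 3 juice                   36.9                41.2

# EC50 from a synthetic DPPH plate with known truth (40 µg/mL)
plate <- generate_plate(true_ec50_ugml = 40, regime = "logarithmic",
                        noise_sd = 0.01, seed = 3)
fit <- fit_ec50(build_series(plate, "S1", assay = "DPPH"))
c(fit_kind = fit$fit_kind, ec50_ugml = round(fit$ec50_ugml, 2))
#>      fit_kind     ec50_ugml
#> "logarithmic"       "40.79"
ec50_molar(fit$ec50_ugml, mw_kda = 278)$ec50_um
#> [1] 0.1467396
```

About 10% of the fresh mass (7.9 g, mostly water) is lost in
fractionation while 41% of the crude protein and 37% of the dry matter
partition into the juice; the noisy plate recovers the generating EC50
within 2%, and dividing a mass EC50 by the fraction's MW in kDa gives
the molar EC50 in µM directly.

An end-to-end run on simulated inputs:

```r
paths <- simulate_inputs(tempfile(), n_proteins = 100, seed = 1)
cfg <- pipeline_config(paths$sec_protein_groups, paths$crude_protein_groups,
                       paths$fasta, paths$annotations, seed = 1)
res <- run_pipeline(cfg)
res$funnel        # per-stage row counts
```

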