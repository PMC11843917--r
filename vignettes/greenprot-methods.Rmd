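---
title: "Methods: from protein-group tables and plate assays to an antioxidant shortlist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from protein-group tables and plate assays to an antioxidant shortlist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenprot)
```

`greenprot` analyses wet-fractionated leafy biomass: a grass input
pressed into pulp and green juice, the juice fractionated by
size-exclusion chromatography (SEC), each fraction assayed for
antioxidant activity and profiled by label-free bottom-up proteomics.
This vignette explains the models and rules the package implements,
the parameters that matter, what the synthetic-data generators do and
do not emulate, and the design decisions taken where the procedure was
genuinely open.

## Quantification model

### Theoretical peptides and iBAQ

Intensity-based absolute quantification divides a protein group's
summed peptide intensity by the number of theoretically observable
tryptic peptides, yielding a quantity proportional to molar amount.
`count_theoretical_peptides()` cleaves after K or R unless followed by
P, assembles peptides with at most `missed_cleavages` retained internal
sites, and counts distinct sequences of at least `min_length` residues
(default 7) and at most `max_mass_da` monoisotopic mass (default
4600 Da, residue masses plus one water). The defaults mirror common
search-engine limits; search engines differ across versions in the
exact counting window used internally for iBAQ, so the window is fully
configurable rather than hard-coded. Counting with 0 missed cleavages
is the default for iBAQ denominators; the count is monotone
non-decreasing in the missed-cleavage allowance, which the tests assert.

### Fragment lead proteins

Database entries annotated `"(Fragment)"` carry truncated sequences:
their theoretical-peptide count understates the real protein, inflating
iBAQ. `mark_fragment_groups()` splits groups into `full`,
`fragment_with_same_name_full` (a full-length namesake exists in the
dataset) and `fragment_orphan`. For both fragment classes the iBAQ is
recalculated protein- and sample-wise as raw intensity divided by
TP~max~, the theoretical-peptide count of a resolved full-length
counterpart. `resolve_tp_max()` searches in a fixed order: a same-name
full-length member inside the group, then a same-name full-length lead
elsewhere in the dataset, then a caller-supplied surrogate sequence
(in practice a BLAST hit for the fragment). For orphans the
counterpart's molecular weight also replaces the group MW, keeping MW
consistent with the peptide count used. Recalculated entries carry a
`*` suffix in the working name so they remain visible downstream.

### riBAQ, isoform merging, TriBAQ

riBAQ divides each iBAQ value by its sample-column total over observed
entries, giving molar fractions that sum to 1 per sample (asserted to
1e-9). Distinct accessions with exactly the same protein name are
treated as isoforms of one functional protein: their riBAQ values are
summed per sample and the merged row is labelled with the isoform count
in parentheses. Merging happens on the riBAQ scale after fragment
recalculation; fragment-marked (`*`) names never merge with unmarked
ones, since their quantification provenance differs. TriBAQ is defined
here as the mean per-fraction riBAQ (sum over fractions divided by the
number of fractions, missing as zero). The divisor keeps TriBAQ on the
riBAQ scale and makes it sum to 1 over proteins; any other positive
constant would rank proteins identically. Abundance thresholds are
strict inequalities: `global` keeps TriBAQ > 0.5%, `fractional` keeps
max riBAQ > 2%, and the screening `shortlist` rule keeps TriBAQ > 0.5%
or riBAQ > 1% in any fraction; all three are config-overridable.

Missing versus zero: an intensity of 0 in a MaxQuant-style table means
"not quantified", so readers store intensity-like zeros as `NA` and
writers emit `NA` as 0. Counts and coverage keep literal zeros.

## SEC calibration and molecular weight

The distribution coefficient K~d~ = (V~e~ − V~0~)/(V~c~ − V~0~) is
linear in log MW within a column's resolving range.
`fit_calibration()` regresses K~d~ on log~10~(MW) over the standards by
ordinary least squares, as the calibration is conventionally plotted;
the regression direction is a recorded choice (the inverse regression
would differ slightly under jitter, identically without). Base 10 is
cosmetic — any base yields identical MW estimates. `estimate_mw()`
inverts the line at a fraction's mean elution volume, taken as the
midpoint of its collected volume window (4 mL by default). Fractions
with V~e~ ≤ V~0~ are part of the void volume: K~d~ ≤ 0 and MW is
reported missing with status `"void"`. Estimates whose K~d~ falls
outside the standards' range are reported but flagged
`"extrapolated"`: sub-kDa "MW" values for late fractions are echoes of
small metabolites, not credible protein sizes, and downstream tables
carry the flag instead of suppressing the value.

## Activity assays and EC50

Activity% = (1 − (A~S~ − A~B~)/A~C~) · 100, with A~S~ the sample
absorbance, A~B~ the matched blank and A~C~ the negative control.
Blanks are matched per dilution step by default (a single averaged
blank is available by configuration); replicate wells at a step are
averaged before fitting. Points with negative activity — a strongly
absorbing sample background exceeding the corrected signal — are
excluded with a recorded reason.

Dose–response is sigmoidal, but short dilution series (dilution factor
1.25 over a narrow window) sample only part of the curve. The fitting
rule is therefore two-regime: if any usable point exceeds 80% activity
the series has left the locally linear region and activity is fitted
against ln(concentration); otherwise a straight line in concentration
is used. EC50 solves the fit at 50% activity, where the curve is
locally linear and the fit is most trustworthy. A fit is declared
unusable — reported as missing with a reason, never dropped silently —
when fewer than two usable points remain, the slope is not positive, or
the solved EC50 lies outside the observed concentration window by more
than a factor of 10 (all configurable renderings of "no satisfactory
curve fit"). Molar conversion is the exact unit identity
µg mL⁻¹ / kDa = µmol L⁻¹; void fractions propagate a reasoned missing
value. Positive controls (Trolox, EDTA) run through the same code path
for plate-level QC and are reported alongside, not used to normalize
sample EC50s.

## Screening

In-silico antioxidant prediction matches each protein's annotations
against 4 GO identifiers (cellular response to oxidative stress,
electron carrier activity, response to hydrogen peroxide, response to
oxidative stress) and 15 keywords. Keyword matching is case-insensitive
substring over GO term names, UniProt keywords and free-text function
terms — the keyword list mixes exact terms with stems such as "ferri"
and "ferre" that are clearly intended as prefixes, so substring
matching over all term text is the faithful reading. Annotations are an
offline input table; no live database access occurs in the tested path.

The three-step filter then applies per-protein predicates:
cross-reference against crude identifications (a protein is "identified"
in a fraction when observed in at least 2 of 3 replicates), a
confidence rule requiring at least 3 of 4 criteria — protein score
≥ 40; MS/MS count ≥ 1, coverage ≥ 5%, unique peptides ≥ 2, each in at
least 2 of 3 juice replicates — and the shortlist abundance rule.
"Identified by MS/MS" is rendered as an MS/MS count of at least 1 in a
replicate, i.e. not matching-only. Because every stage is a per-protein
predicate, the stages are idempotent, monotone, and order-insensitive
for the final set; the funnel counts, of course, depend on the stated
order, which the package follows. Literature categories (direct /
indirect / no explicit antioxidant function) are input metadata, not
computed.

## Crude-fraction statistics

Crude protein is nitrogen × 6.25. `mass_balance()` propagates fresh
masses and mean DM/CP percentages into per-fraction DM and CP masses,
distributions relative to the grass input, and closure losses; the
distributions are scale-invariant in mass units and the losses vanish
exactly under conservation.

For differential abundance, LFQ intensities are log2-transformed and
each sample's median is subtracted (per-sample median to zero), making
the result invariant to per-sample rescaling; the exact normalization
of external differential-analysis services is unstated, so the simplest
scale-invariant choice is used and recorded. Missing values are imputed
once, with a recorded seed, from a downshifted normal per sample:
mean µ~s~ − 1.8 σ~s~ and SD 0.3 σ~s~, where µ~s~, σ~s~ are the observed
log2 mean and SD. This "not missing at random" model reflects that
label-free missingness concentrates at low abundance. Observed cells
are never touched (bit-identical, asserted). Per-protein Welch t-tests
with Benjamini–Hochberg adjustment give differential calls at adjusted
p < 0.05 and |log2FC| > 1 (two-sided); zero-variance-in-both-groups
rows are flagged degenerate with a defined p rather than propagating
NaN. No claim is made to reproduce any external service's exact
p-values — only the stated parameter set.

Candidate-family abundance uses summed member riBAQ per replicate
(making results invariant to isoform splits that conserve the sum),
a Welch one-way omnibus test, and pairwise Welch contrasts with Holm
adjustment. Holm stands in for Dunnett T3: T3's
studentized-maximum-modulus critical values are not needed anywhere
else in the package, Holm is conservative, and the contrast engine is a
small, replaceable function. Heatmap reporting Z-scores rows (constant
rows become zeros with a warning) and cuts an average-linkage Euclidean
dendrogram at a fixed height (default 3).

## What the generators emulate — and what they do not

`generate_proteome()` draws uniform-random sequences of 80–1200
residues: sufficient for digest counting and MW, with no homology or
composition modeling. Isoform families share names across accessions;
fragments are truncated parent prefixes (30–70% of the parent) named
`"(Fragment)"`; contaminants and decoys carry `CON__`/`REV__`
prefixes. `generate_protein_groups()` makes intensities log-normal
around true abundance × theoretical-peptide count — so iBAQ recovers
molar abundance exactly in the noise-free limit — with the replicate
CV as the log-normal parameter, MNAR missingness as a logistic function
of log-intensity, and identification metrics (MS/MS counts, unique
peptides, coverage, score) as monotone functions of intensity. SEC
designs place each complex on a Gaussian elution profile (SD 1.5
fraction indices by default) centred at the position implied by its
assembled-complex MW; the overlap between neighbouring fractions is
intentional, since real fractionation is imperfect. Plates invert the
activity formula from a monotone curve whose 50% point is the true
EC50; calibration inputs come from a known K~d~–log MW line.

Passing tests on these fixtures show the estimators invert the
generating models and that the procedural rules (filters, funnels,
normalizations) are implemented exactly. They do not show robustness to
features the generators omit: peptide-level interference, co-eluting
isobaric species, retention-time drift, chromatographic peak shapes,
plate edge effects, or annotation errors. Real-data funnel counts
depend on deposited datasets and are outside desk scale; the suite
covers their logic with planted-structure fixtures instead.

## Numerical choices and problem sizes

Determinism: every generator and the imputation step take an integer
seed and restore the caller's RNG state. Ties and degenerate inputs are
defined states, not errors: double-flagged contaminant/reverse rows are
counted once as contaminant; all-missing riBAQ columns raise an error
naming the sample; unresolved fragments raise an error naming the
accession.

The simulation sizes used by the test suite and the acceptance script —
chosen as comfortable desk-scale studies — are: 200 noisy plates per
fit regime at absorbance noise SD 0.01; 100 null datasets of 200
proteins and 20 spike-in datasets of 200 proteins (30 spiked at log2FC
2, CV 15%) for the differential-abundance operating characteristics;
100 random sequences against the brute-force digest oracle; and
proteomes of 80–150 entries for the quantification fixtures. The
spike-in background size is not dictated by the procedure; 200 was
fixed to match the null study.

## Known limitations

- TriBAQ's divisor (number of fractions) is a convention; comparisons
  across runs with different fraction counts need the same convention.
- The EC50 two-regime rule is a deliberate simplification of 4PL
  fitting for short series; it is exact at 50% by construction but not
  a dose–response model.
- Holm-adjusted Welch contrasts are conservative relative to Dunnett
  T3; borderline pairwise significances may differ.
- The digest counter ignores modifications and non-standard residues
  (configurable averaging aside); counts are for the unmodified
  backbone.
- Extrapolated SEC MW values are numerically meaningful but physically
  unreliable; they are flagged, and molar EC50s built on them inherit
  that caveat.
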