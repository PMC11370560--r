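---
title: "Methods: from raw home-cage streams to the polysubstance analysis battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw home-cage streams to the polysubstance analysis battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sipflow)
```

`sipflow` analyzes group-housed home-cage drinking experiments in which an
RFID antenna at each drinking station detects which tagged animal is
present while a volumetric drinking monitor (VDM) measures consumption.
This vignette is the package's account of its methods: the integration
rules, the metrics, the models behind the statistics, what the synthetic
generator emulates, and the numerical decisions a maintainer would want
written down.

## Stream integration

Both streams carry timestamps in seconds on one experiment clock whose
zero is lights-on of day 1, so zeitgeber time is `t mod 24 h` and the
light phase is ZT 0–12. (The package assumes the devices share a clock;
drift correction is out of scope.)

**Visit bouts.** `collapse_visits()` merges maximal runs of reads of one
tag at one antenna with successive gaps at most `max_gap` (default 1.0 s).
Antenna detection is intermittent — a tag in range does not register on
every 10 ms sample — so the gap bridges dropout while still splitting
distinct visits, which are separated by locomotion on the scale of
seconds. Bout boundaries are the first and last observed reads, hence
containment below uses a closed interval: both endpoints are real
detections.

**Drink attribution.** `assign_drinks()` gives each VDM row at station
`s`, time `t` to the animal whose bout at `s` contains `t`. When no bout
contains `t` (a drink registered just after the tag left antenna range),
the bout whose nearest boundary lies within `tolerance` (default 2.0 s)
wins; ties and multiply-containing (overlapping) bouts resolve to the
earlier bout start, making attribution deterministic. Rows with no
candidate are kept as unassigned (`tag = NA`) and counted, never dropped,
so summed volume is conserved exactly — a invariant the tests enforce at
every aggregation granularity. The acquisition hardware does not document
an attribution rule for spout activity with no registered animal;
nearest-within-tolerance is this package's explicit choice.

## Intake, occupancy, preference

Normalized intake is reported in ml/kg: `volume(µl) / body weight(g)`,
with the single roster body weight (no weight time course is modeled).
Intake tables are dense — every animal × chamber × bin cell exists, zero
filled — so day-by-ZT matrices can be averaged into heat maps without
missing-cell bias; heat-map cells are group *means* of per-animal
normalized intake. Totals are sums over all observation days, not daily
averages. Occupancy sums bout durations, splitting a bout at every bin
boundary it spans so time is conserved at any granularity; a visit counts
in the bin containing its start.

Preference indices are classic two-bottle-choice ratios:
`V_drug/(V_drug + V_water)` (doses of the drug summed, both water
stations summed) and dose preference `V_high/(V_high + V_low)`. Body
weight cancels, so the ratio of raw volumes equals the ratio of
normalized intakes. A zero denominator leaves the index undefined; such
animals are excluded from group tests rather than imputed at 0.5, because
imputation would manufacture indifference from absence of drinking. In
day-scope repeated-measures analyses, animals with any undefined day are
excluded entirely to keep the design balanced.

## Polysubstance windows

`classify_windows()` partitions each day into fixed, non-overlapping
60-minute bins aligned to lights-on; a window's label is the set of
substance categories with positive consumed volume. Fixed windows (not
sliding) keep the tallies a partition — each event counts once — which is
what a distribution over windows requires; bins are half-open, so an
event exactly on a boundary belongs to the later window. Collapsed mode
uses the three substance types (7 possible non-empty combinations);
dose-resolved mode uses the five substance/dose chambers, for which the
package enumerates the full `2^5 − 1 = 31` subsets rather than a smaller
ad-hoc universe. Group distributions are compared with Pearson χ² on the
groups × categories table, either over set sizes ("outer ring" of the
nested-pie encoding) or over specific combinations ("inner ring").
Categories with zero total across all groups are dropped first (their
expected counts are undefined); no continuity correction and no
minimum-expected-count rule are applied, since sparse categories are part
of the phenomenon.

## Behavioral phenotyping

The 12 open-field and elevated-zero-maze parameters (distances, speeds,
center/open-arm times, entries, latencies) have incommensurate units, so
clustering operates on z-scores (population SD), equivalent to
correlation-matrix PCA. Components are sorted by explained variance with
a reproducible sign convention (largest-magnitude loading positive), and
the leading components whose cumulative ratio exceeds 0.75 are kept.
k-means uses multi-start (`n_init = 10` random initializations, best
inertia kept).

**Choosing k.** `stability_table()` fits, per candidate k (3–6), a
seeded reference model on the full data and `B = 100` replicate models on
bootstrap row-resamples with fresh random initializations; replicate
labels are compared with the reference on the rows each resample shares
with the full data, using five agreement scores computed from the label
contingency table: homogeneity, completeness, their harmonic mean
(V-measure), the adjusted Rand index (pair counting against the
permutation model), and adjusted mutual information (expected MI under
the hypergeometric model, arithmetic-mean normalizer — conventions for
the AMI normalizer differ across implementations, so ours is stated
here). The recommended k maximizes mean ARI, ties to the smaller k; the
full table is always returned so a human can fix k instead. The metrics
are implemented from first principles because no installed R package
provides AMI or V-measure; the ARI is cross-checked against an
independent implementation in the tests. Cluster labels are 0-based and
carry no semantic ordering.

## The statistical battery

Group comparisons use pooled-variance two-tailed t tests, one-way ANOVA,
or a mixed-design (two-way repeated-measures) ANOVA with one
between-subject factor (sex or cluster) and one within-subject factor
(substance chamber or day). The mixed ANOVA is the classical univariate
partition: between-subjects SS split into group and subjects-within-group,
within-subjects SS into the within factor, the interaction and the
residual, giving `F(group) = MS_group/MS_subj(group)` on `(g−1, N−g)` df
and `F(interaction) = MS_int/MS_resid` on `((a−1)(g−1), (a−1)(N−g))` df.
No sphericity correction is applied — reported df are the uncorrected
integers — and the partition is cross-checked in the tests against a
hand-computed cell-means decomposition. Designs must be balanced across
within levels (every subject at every level exactly once); group sizes
may differ.

Post hoc Bonferroni comparisons use `p_adj = min(1, m·p)` over the
declared family, with the residual mean square (and its df) for
within-factor contrasts and the subjects-within-group mean square for
between-group contrasts — the error-term assignment is stated here
because reporting conventions for it vary. Benjamini–Hochberg adjustment
is the standard step-up procedure. χ² tests use margin-based expected
counts without continuity correction. A completely constant response
yields `F = 0`, `p = 1` rather than a 0/0 error.

## The synthetic cohort generator

No per-animal dataset accompanies this class of experiment, so
`simulate_sip()` generates one with the statistical structure the
analyses assume. Defaults describe the study conditions: 32 males and 24
females in single-sex cages of 4, seven days, 12:12 light:dark with the
clock starting at lights-on, and the six-station map above.

- **Visit process**: homogeneous Poisson within each light/dark phase —
  `base_visit_rate` 0.5 visits/h in light, ×3 in dark — the simplest
  process with a day/night contrast. About 24 visits/animal/day.
- **Choice model**: each visit picks a chamber with probability
  proportional to a phenotype × sex × chamber weight table
  (`default_substance_weights()`): water carries the largest weight,
  females carry ×1.5 ethanol and ×2 fentanyl weights (the planted sex
  effect), phenotype 2 strongly prefers high-dose fentanyl, and fentanyl
  log-weights drift up by `escalation_slope = 0.15`/day (escalating
  fentanyl-directed visits across the week).
- **Bouts and volumes**: lognormal bout duration (median 10 s,
  `sdlog = 0.5`); 60% of visits drink a gamma-distributed volume (shape
  4, scale 75 µl, mean 300 µl), yielding ~4–5 ml/day total fluid per
  25 g mouse — physiological for mice.
- **Stream emission**: antenna samples at a nominal 100 Hz, but each
  within-bout sample registers with probability `rfid_detect_prob = 0.07`
  (entry and exit always register, so bout boundaries are observed).
  Real RFID detection is intermittent, and this duty cycle reproduces the
  magnitude of a real cohort-week — several hundred thousand reads and
  tens of thousands of 1 Hz VDM rows for 56 mice — rather than the tens
  of millions continuous 100 Hz sampling would imply. VDM rows are
  emitted at 1 Hz inside the bout with the bout's volume split evenly.
- **Behavior table**: each animal draws a latent phenotype
  (mix 0.2/0.1/0.7) and its 12 parameters from a multivariate normal
  around that phenotype's mean profile (high-anxiety, explorer,
  intermediate), diagonal covariance, nonnegative parameters clipped at
  zero. Neighboring profiles sit ≥3 within-phenotype SDs apart on the
  discriminating parameters, and the true labels are serialized so tests
  never re-derive them.

Everything is seeded: one `sip_config()` (including seed) produces
byte-identical fixture files.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: pharmacokinetics and dose-dependent
satiety, social dynamics between cagemates (visits are independent
Poisson streams), correlated behavior parameters within phenotype (the
covariance is diagonal; speed is drawn independently of distance), body
weight change, estrous effects, and hardware pathologies beyond uniform
detection dropout (no clock drift, no antenna cross-talk). The planted
effects are deliberately simple monotone weight multipliers.

## Calibration of the study conditions

Three properties tie the generator and pipeline together, and the test
suite and `scripts/acceptance.R` recompute them at these problem sizes:

- **Phenotype recovery**: at the default ≥3-SD separation with n = 200,
  the full phenotyping pipeline at the stability-recommended k recovers
  the true labels with median ARI ≥ 0.8 over 20 seeds (observed: 1.0,
  with k = 3 chosen in every replicate). With the three phenotype mean
  profiles made identical, recovery collapses to ARI ≈ 0.
- **Planted sex effect**: with the ×2 female fentanyl weight at the
  study size (n = 56, one week), the sex × substance mixed-ANOVA
  interaction rejects at α = 0.05 in ≥80% of 50 simulated cohorts
  (observed: 100%).
- **Null calibration**: with sex-equal weights the same test rejects at
  a rate within 3 binomial SE of 5% over 50 cohorts. Phenotype
  heterogeneity remains in the null — subject-level profile variation is
  part of the error, exercising the uncorrected RM ANOVA's robustness at
  a realistic heterogeneity level.

## Known limitations

Overlapping bouts of different animals at one station are resolved by
rule, not modeled; the uncorrected mixed ANOVA is anticonservative under
strong sphericity violation; dose-resolved χ² tables can be sparse (no
minimum-expected-count guard by design); and undefined preference
exclusion can shrink repeated-measures samples when an animal skips a
substance entirely for a day. The pie-chart and heat-map figures of a
typical report are emitted as data tables plus simple ggplot2 helpers;
styled graphics are out of scope.
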