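---
title: "Monitoring the blood-culture process: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring the blood-culture process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bckpi)
```

## The problem

The sensitivity and interpretability of blood cultures (BCs) are decided
mostly in the pre-analytical phase: blood volume per bottle, number of
bottles and venipunctures per febrile episode, pairing of catheter draws
with peripheral ones, and skin disinfection. `bckpi` turns a
de-identified bottle-level laboratory export into the standard KPIs of
that phase, stratified by center, hospitalization area and hospital
service, so that wards with critical practice can be identified and sent
a periodic report.

This vignette documents the underlying definitions, the parameters that
matter, the synthetic-data model used for validation, and the design
choices made where the problem statement is genuinely open.

## From bottles to sets and episodes

**BC set.** Bottles sharing one sampling procedure — identified by the
progressive `sample_id` — form a set: an aerobic + anaerobic pair, or a
single bottle. Sets are additionally keyed by specimen origin (a
venipuncture cannot be simultaneously peripheral and from a catheter), so
a `sample_id` that mixes origins yields one set per origin. In `strict`
mode (default) a `sample_id` carrying two bottles of the *same* type is
treated as a data-entry artifact and split into singleton sets, with a
count reported; `lenient` mode keeps such groups.

**Episode.** All bottles from one patient in one hospital area collected
within `window_hours` (default 24) of the first *index* sample. The
window is **anchored and closed**: the earliest unassigned bottle defines
hour 0, every bottle up to *and including* hour 24 joins it, and the next
unassigned bottle anchors a fresh window. There is no sliding and no
chaining — a bottle at hour 25 starts a new episode rather than extending
the old one, because the definition anchors hour 0 at the index sample.
"Within 24 h" is read inclusively; boundary bottles are rare and the
choice is visible in the closed upper bound.

Ties in collection time are broken by `bottle_id` (lexicographic), which
makes the partition invariant to input row order. Episode attribution
(center, area, hospital service, anchor time) comes from the index
bottle: deterministic, and consistent with the index bottle's anchor
role. The grouping key is configurable — `patient_area` (default),
`patient_service`, or `patient_only` — because patients transferred
between areas within 24 h are not covered by the definition; the center
is always part of the key, since patient identifiers are only guaranteed
unique within a center's export.

**Classification.** An episode is *CVC* iff at least one bottle comes
from an intravascular device (peripheral-vein samples in the same episode
belong to the CVC episode); *solitary* iff it contains exactly one set —
this covers both the single-set and the single-bottle readings; *positive*
iff any bottle flagged positive; *unpaired CVC* iff CVC with no
peripheral-vein bottle. `OTHER_DEVICE` origins (arterial lines, ports)
count as CVC-like by default (`device_as = "cvc"`), with options to count
them as peripheral or to ignore them in typing, since the field's
definition names the central venous catheter only as an example of an
intravascular device.

## The contamination rule engine

Only **non-solitary peripheral-vein episodes** are eligible: the
restrictive criteria are defined on them, and a one-bottle episode cannot
distinguish contamination from infection. CVC and solitary episodes are
marked `NOT_ELIGIBLE` — not `NO_PANEL_ORGANISM` — so every denominator
remains auditable.

The default contaminant panel is: coagulase-negative staphylococci
(CoNS) excluding *S. lugdunensis*; *Micrococcus* spp.; *Cutibacterium
acnes* (species-level — other *Cutibacterium* species are not
contaminants by default); *Corynebacterium* spp. excluding *C. jeikeium*
and *C. striatum*; *Bacillus*, *Lactobacillus* and *Aerococcus* spp.
Because "CoNS" names a group rather than species, membership is an
explicit, configurable species list (the common clinical CoNS plus the
literal label "coagulase-negative staphylococci"). Matching is
case-insensitive after whitespace normalization, and genus-level entries
("Bacillus sp.") match their genus rule. Unknown names are never
contaminants.

Categories over eligible episodes:

* `RESTRICTIVE_CONTAMINATION` — at least one panel organism among the
  positive bottles, and *every* panel organism occurs in exactly one
  bottle. Two different panel organisms in one bottle each still qualify:
  the criterion is stated per isolated organism, and each is applied
  independently. A true pathogen elsewhere in the episode does not change
  the category (the criterion concerns only the contaminant's occurrence
  pattern); the rationale field flags such mixed episodes for attention.
* `REVIEW_CANDIDATE` — some panel organism in more than one bottle. The
  candidate queue can be exported with per-bottle context and adjudicated
  by a reviewer.
* `CONFIRMED_AFTER_REVIEW` — a candidate confirmed either by the
  **automatic review rule** — the same contaminant positive in exactly
  two bottles belonging to the same BC set, and in no other bottle of the
  episode — or by a human adjudication. The rule needs set identity, i.e.
  a multi-sampling strategy; under single-sampling data
  (`set_structure = "sss"`) it is not evaluable and returns `NA`,
  leaving candidates open for manual review only.
* Human decisions always override the automatic rule, in both directions,
  and overrides are logged.

If an episode carries both a singleton panel organism and a multi-bottle
one, the review-candidate category takes priority, so the episode is
resolved by review rather than silently counted as restrictive.

## KPI definitions and conventions

| KPI | numerator | denominator |
|---|---|---|
| 1 (bottle) | Σ known volumes | bottles with known volume |
| 1 (episode) | Σ known volumes | episodes with ≥ 1 known volume |
| 2 | solitary episodes | **all** episodes (PV and CVC) |
| 3 | unpaired CVC episodes | CVC episodes |
| 4a | restrictive contaminations | non-solitary PV episodes |
| 4b | restrictive + confirmed after review | non-solitary PV episodes |

KPI 2's denominator is all episodes, not PV episodes only: the reference
totals (12,149 solitary of 55,819 episodes = 21.8%) force this reading.
KPI 1 is a bottle-count-weighted mean, so stratum cells aggregate exactly
to the overall cell; bottles without a volume reading are excluded from
numerator and denominator — never imputed as zero — and counted in a
first-class `n_missing` output, since volume instrumentation may be
absent for part of a fleet. A zero denominator leaves a cell undefined
(`NA`, non-displayable) rather than zero.

Every cell retains its raw numerator and denominator; display rounding
(rates to 1 decimal, means to 2) is applied only at presentation time.
Contaminant-ranking shares use **largest-remainder rounding** so they sum
to exactly 100 at the requested precision.

Service-level cells are grayed below representativeness thresholds:
strictly more than 500 episodes for KPIs 1–2 and strictly more than 75
CVC episodes for KPI 3 (both configurable). The heatmap's color scale is
linear between the stratum minimum and maximum per KPI — the field
publishes no absolute red thresholds — with low volume worse for KPI 1
and high rates worse for KPIs 2–4; benchmark reference values (≥ 8.0 mL
per bottle, ≤ 10% solitary) are shown as annotations, not cutoffs.

One reproduction note: reference tables occasionally disagree with their
own printed ratios at the last decimal (e.g. a printed 62.9% where the
printed counts give 2,142/3,401 = 63.0%). The engine always reports the
computed value and documents the divergence rather than matching printed
cells. Similarly, a published review yield of "177/32,592" sits alongside
a non-solitary PV count of 43,346 − 10,750 = 32,596; the engine uses the
single consistent denominator 32,596 everywhere.

## The synthetic-cohort model

`generate_cohort()` emulates the instrument/LIS export: per-patient
episode streams, aerobic/anaerobic set structure, PV/CVC origins,
truncated-normal fill volumes, true-pathogen positivity, and injected
panel contaminants. Its purpose is validation with known ground truth,
and three design choices follow from that:

* **Episode anchors are at least 25 h apart within a patient**, so the
  ground-truth episode membership is unambiguous and pipeline recovery
  must be *exact*. Boundary behavior (bottles at exactly +24 h) is
  exercised by dedicated fixtures, not by the main generator.
* **Counts per patient** follow a zero-truncated Poisson (every included
  patient has at least one episode by construction), with mean 2.1 by
  default in the multicenter preset.
* **Coupling of solitary and CVC structure.** A solitary CVC episode is
  necessarily unpaired, so the solitary fraction and the unpaired-CVC
  fraction cannot both hold if the number of sets is drawn independently
  of episode type. The generator draws set counts from the base
  distribution for PV and unpaired-CVC episodes and from the same
  distribution conditioned on ≥ 2 sets for paired-CVC episodes (which
  need at least one device set and one PV set);
  `multicenter_preset()` solves the base distribution so the marginal
  solitary fraction (21.8%), bottles/episode (4.21), CVC share (21.4%)
  and unpaired share (14.9%) are all exact ground truth under this
  conditioning.

The preset's other parameters: fill volume ~ Normal(6.45, 1.5²) mL
truncated to [0, 15] (the truncation's effect on the mean is below
10⁻⁴ mL at these parameters); contamination probability 4.7% for
non-solitary PV episodes, of which 5/47 are injected as same-set pairs
(so restrictive contaminations are 4.2% and the review yield 0.5%);
contaminant groups drawn as CoNS : *Corynebacterium* : *Micrococcus* :
*C. acnes* : others = 91 : 4 : 4 : 2 : 1 (normalized — the published
rounded shares sum to 102); pathogen positivity solved so that the
overall positive-episode rate (pathogens plus contaminated episodes)
equals 20.6%; patient-days per patient derived from the 132.3 BC sets
per 1,000 patient-days target and the preset's expected sets per
patient; center and area weights proportional to the reference episode
distribution. Pathogen species (E. coli, K. pneumoniae, S. aureus,
E. faecalis, C. albicans) are a documented invention — the reference
material names only contaminants.

What the generator does **not** model: seasonality, inter-center
correlation, patient transfers within an episode window, single-sampling
cohorts, organism-specific volume effects, or antimicrobial resistance.
Passing recovery tests therefore shows that the pipeline measures what
the generator encodes — it does not certify behavior on real exports
with, e.g., duplicated sample codes or ward renames, which is what the
validation layer and rejects report are for.

## Numerical and degenerate-input choices

* Timestamps are minute-precision ISO-8601; seconds are accepted and
  preserved. All times are interpreted in UTC (the export carries no
  zone).
* Validation is total: every input row is either accepted or appears in
  the rejects report with a row number, field and reason code. A
  duplicated `bottle_id` or a missing column is fatal — that is file
  corruption, not a bad row. A negative bottle carrying organism
  identifications is rejected (contamination logic keys on positive
  bottles only); a positive bottle without identification is accepted,
  since species identification can be pending or failed.
* The adult filter is inclusive at its boundary (age ≥ 18); records with
  missing age are routed to rejects by default, configurable to keep,
  because whether pediatric bottles are filtered here or absent upstream
  is site-dependent.
* Empty cohorts, empty strata and zero denominators yield zero-row or
  `NA` cells, never errors.
* Episode identifiers are the deterministic concatenation of center,
  patient, grouping key and anchor time, stable across runs and
  machines; machine reports contain no timestamps, so identical inputs
  and configuration produce byte-identical output.
* `EPISODES_PER_PATIENT` is the one indicator whose denominators are not
  additive across strata (a patient can appear in several areas); the
  additivity checks in the test suite cover every other KPI.

## Problem sizes used for validation

The test suite validates the episode builder against a brute-force
anchored-window oracle on cohorts of up to 50 bottles, and the
contamination engine against exhaustive enumeration of every episode
layout with up to six bottles, two organisms and all set structures
(62,944 layouts). Parameter recovery runs the full multicenter preset at
its natural scale — 26,559 patients, ≈ 235,000 bottles — and checks
KPIs 1–4 against the preset ground truth within three binomial/CLT
standard errors, plus twenty smaller seeded replicates (400 patients
each) for the same property. These sizes were chosen to make sampling
error bounds meaningful while keeping a full run in the order of a
minute.

## Known limitations

* No differential-time-to-positivity computation; unpaired-CVC episodes
  are counted, not interpreted.
* No statistical inference across strata (no confidence intervals or
  tests between centers); the report is descriptive.
* The manual-review workflow models decisions, not reviewers: no
  blinding, reconciliation or inter-rater machinery.
* Contamination eligibility follows the restrictive definition
  (non-solitary PV only); catheter-drawn contamination is out of scope.
* The package assumes de-identified input; it performs no anonymization.
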