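# bckpi — blood-culture process KPIs from bottle-level records

Blood cultures (BCs) are the cornerstone of bloodstream-infection
diagnosis, and their diagnostic yield is largely decided before the
bottle reaches the instrument: how much blood was drawn per bottle, how
many bottles and venipunctures were taken per febrile episode, whether a
catheter draw was paired with a peripheral one, and whether skin flora
contaminated the sample. Clinical microbiology laboratories are asked to
monitor these pre-analytical key performance indicators (KPIs), but the
bookkeeping — grouping hundreds of thousands of bottle records into
episodes and applying contamination rules consistently — is beyond what
most laboratories can do by hand.

`bckpi` is an R implementation of that bookkeeping for laboratory
informaticians and quality officers. From a de-identified bottle-level
export (one CSV/JSONL row per bottle with patient, ward, sample code,
specimen origin, timestamp, instrument flag, species identifications and
fill volume) it computes, stratified by center, hospitalization area and
hospital service:

* **KPI 1** — mean blood volume per bottle and per episode (mL),
  `sum(volume) / n` over volume-bearing bottles (a weighted mean, so
  strata aggregate exactly);
* **KPI 2** — solitary episodes / all episodes × 100, where an *episode*
  is all bottles from one patient in one area within 24 h of the first
  (index) sample, and *solitary* means a single sampling (one BC set or
  one bottle);
* **KPI 3** — unpaired CVC episodes / CVC episodes × 100: episodes drawn
  from an intravascular device with no concomitant peripheral-vein set,
  which blocks differential-time-to-positivity interpretation;
* **KPI 4a/4b** — contaminated episodes / non-solitary peripheral-vein
  episodes × 100, under *restrictive criteria* (a panel organism — CoNS
  excluding *S. lugdunensis*, *Micrococcus* spp., *Cutibacterium acnes*,
  *Corynebacterium* spp. excluding *C. jeikeium*/*C. striatum*,
  *Bacillus*, *Lactobacillus*, *Aerococcus* spp. — in exactly one bottle)
  alone (4a) or together with contaminations confirmed on manual review
  (4b), including an automatic review rule (same contaminant in both
  bottles of one set and nowhere else in the episode);
* auxiliary indicators: positivity, bottles/episode, episodes/patient,
  BC sets per 1,000 patient-days.

A seeded synthetic-cohort generator with known ground truth
(`generate_cohort()`, `multicenter_preset()`) makes every pipeline stage
testable without hospital data, and `run_compute()` / the `bckpi` script
drive the whole pipeline to a set of report files including a
service-level heatmap with representativeness thresholds (> 500 episodes
for KPIs 1–2, > 75 CVC episodes for KPI 3).

## Worked example

The package ships a 30-bottle fixture (6 patients, 11 episodes, 4
hospitalization areas):

```r
library(bckpi)
cohort   <- read_bottles(system.file("extdata", "bc_fixture_30.csv",
                                     package = "bckpi"))
episodes <- build_episodes(filter_adults(cohort))
assessed <- assess_episodes(episodes)
kpi_report(episodes, assessed, levels = c("OVERALL", "AREA"))
```

```
<bc_kpi_report> 45 cell(s)
Overall:
  KPI1_BOTTLE          8.14  (228 / 28)
  KPI1_EPISODE         22.80  (228 / 10)
  KPI2                 36.4%  (4 / 11)
  KPI3                 75.0%  (3 / 4)
  KPI4A                40.0%  (2 / 5)
  KPI4B                60.0%  (3 / 5)
  POSITIVITY           54.5%  (6 / 11)
  BOTTLES_PER_EPISODE  2.73  (30 / 11)
  EPISODES_PER_PATIENT 1.83  (11 / 6)
Also stratified by: AREA
```

Reading it: 28 of 30 bottles carried a volume (2 missing, never imputed)
averaging 8.14 mL; 4 of the 11 episodes were solitary (36.4%); 3 of the
4 CVC episodes had no peripheral-vein pair (75.0%); of the 5 non-solitary
PV episodes, 2 met the restrictive contamination criteria (40.0%) and one
more — the same *S. hominis* in both bottles of one set — was confirmed
by the automatic review rule, lifting KPI 4b to 60.0%. Every cell keeps
its raw numerator and denominator.

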