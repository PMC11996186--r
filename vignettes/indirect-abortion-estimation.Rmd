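---
title: "Indirect estimation of induced abortions from hospital admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect estimation of induced abortions from hospital admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aicm)
```

## The problem and the method

Where abortion is legally restricted, induced abortions cannot be counted
directly. The Abortion Incidence Complications Method (AICM) estimates them
indirectly from a quantity that *is* routinely recorded: hospitalizations
for abortion complications. The estimate is

$$
A \;=\; \sum_{s \in \{\text{public},\ \text{private}\}}
        H_s \cdot m_s \cdot f_s ,
$$

where for each funding sector $s$, $H_s$ is the number of hospitalizations
due to abortion, $m_s < 1$ removes the share attributable to spontaneous
abortion (miscarriage), and $f_s > 1$ scales the remaining hospitalized
complications up to all induced abortions, including the majority that
never reach a hospital. Dividing $A$ by the female population aged 10--49
(times 1,000) gives the abortion *rate*; dividing by live births (times
100) gives the abortion *ratio*. Uncertainty is expressed by moving each
$f_s$ down and up one unit, which propagates to bounds on every indicator.

This package implements the full pipeline for Brazilian-style
administrative data, with the 2015 national run packaged as fixtures:

1. **Public-sector case selection.** Hospital discharge records (SIH/SUS
   style) carry up to five ICD-10 diagnosis fields. A record is an abortion
   hospitalization if any field carries a category in O03--O08, the woman
   is 10--49, and the year matches. O00--O02 (ectopic and molar pregnancy,
   abnormal products of conception) are not induced-abortion outcomes and
   never qualify a record.
2. **Private-sector case selection.** Insurance claims come as
   consolidated events (up to four ICD-10 fields, which insurers may leave
   unreported) plus per-procedure detail rows, linked by a care-event
   identifier. Because roughly half the abortion events have no ICD-10, an
   event also qualifies if it carries a post-abortion procedure (manual
   vacuum aspiration 31309020/31303013 or curettage 31309062). Events
   carrying O00--O02 are excluded outright, and linkage guarantees a woman
   with both a diagnosis and a procedure is counted once.
3. **Coverage and the legacy estimator.** Before claims data existed,
   private hospitalizations were estimated as public counts times insurance
   coverage. `legacy_private_estimate()` reproduces that estimator from
   beneficiary/population panels; on the packaged margins it over-reports
   the observed private caseload 1.72-fold, which is why the pipeline uses
   the reported claims counts.
4. **Miscarriage correction.** $m$ follows the age gradient of clinically
   recognized miscarriage: 0.90 under 30, 0.85 at 30--39, 0.75 at 40--49,
   applied separately per sector because their age profiles differ.
5. **Factor calibration.** $f_s$ is calibrated against an external survey
   total of women reporting an abortion in the year (503,000 in 2015,
   ages 18--39), by comparing it with miscarriage-corrected
   hospitalizations in the same age range under five scenarios
   (`canonical_scenarios()`): pooled sectors; equal annual abortion
   frequency (1.35%) in both sectors; and private frequency at 50/75/90%
   of the public one, solved against the survey total.
6. **Estimation and indicators.** `estimate_result()` applies the equation
   with the chosen factors — 4 (range 3--5) public and 5 (range 4--6)
   private, the latter from the most conservative calibration scenario —
   and computes rates and ratios with bounds.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `year`, `age_range` | 2015, 10--49 | case-selection filter |
| include / exclude ICD categories | O03--O08 / O00--O02 | selection rule |
| procedure codes | 31309020, 31303013, 31309062 | private-sector detection |
| miscarriage factors | 0.90 / 0.85 / 0.75 | by age group <30, 30--39, 40--49 |
| `share_18_19` | 0.75 | share of private 15--19 admissions at ages 18--19 |
| non-hospitalization factors | 4 (3--5), 5 (4--6) | per sector, with bounds |
| `band_coverage` | 18 / 26 / 32 / 27% | denominator split by decade band |
| `rounding` | `"half_up"` | see below |

The 18--19 share matters because the private data only carry 5-year bands
while the calibration survey starts at 18: within 15--19 the annual
frequency of abortion rises steeply with age, so 18--19 year olds account
for well over their population share of admissions. Lowering the share
raises the calibrated factors.

## Numerical choices

* **Half-up rounding at each printed intermediate.** The published national
  tables this pipeline reproduces round half away from zero (6,628.5 →
  6,629; 1,657.5 → 1,658), where IEEE round-half-even would differ.
  `round_half_up()` implements this with a small relative epsilon guarding
  against binary representation error in products like $41{,}319 \times
  0.85$. `rounding = "none"` disables intermediate rounding for
  error-propagation studies.
* **Rounding granularity.** The miscarriage correction rounds once per
  *factor age group* (<30, 30--39, 40--49) — not per decade band — and the
  headline run corrects nationally summed counts
  (`aggregate_regions()`), because per-decade or per-region rounding gives
  totals that disagree with the published table by a handful of cases.
  Sector denominators round once at the coverage-weighted sum, and the
  public share is defined as total minus private so sectors always add to
  the national total exactly.
* **Calibration arithmetic.** In the constrained scenarios the public
  frequency solves the one-unknown linear equation
  $P_{\text{pub}} f + P_{\text{priv}} k f = A_{\text{survey}}$, and the
  private estimate is taken as the remainder of the survey total, so the
  sectors add up exactly. The sector populations (27,496,889 and
  9,540,963 women aged 18--39) are back-solved from the equal-frequency
  scenario at 1.35%; applying the quoted coverage shares to the packaged
  population panel instead implies a private population near 10.4M, an
  inconsistency inherent to the source aggregates that is surfaced here
  rather than hidden. With the back-solved values every scenario output
  reproduces exactly.
* **Ratios of counts.** National and per-band ratios always divide summed
  counts; cells with zero denominator are undefined (`NA`), which is data,
  not an error.
* **Degenerate inputs.** Empty selections give all-zero tables; a zero
  population or birth denominator is a hard error; detail rows whose event
  has no consolidated record have no stratum, are excluded from tables and
  reported in a diagnostic count.

## The synthetic-data generator

Real discharge and claims microdata cannot be redistributed, so
`generate_sus()`, `generate_ans()` and `generate_panels()` emit
record-level data whose aggregates match configured region-by-band margins
(`margin_spec()`, defaulting to the packaged 2015 national margins:
134,054 public admissions across 27 states, 20,756 private events of which
9,800 have an ICD-10). In exact mode the match is cell-for-cell —
integer allocation uses largest-remainder apportionment so global targets
are hit exactly; `"multinomial"` mode adds sampling noise around the same
expectations. Within-band allocations are calibrated to the published
survey-age totals: 16,625 of the 23,912 public 10--19 admissions are
placed at ages 18--19, and 641 of the 669 private 10--19 events in the
15--19 band. Generated decoys — O00--O02 events (some with abortion
procedures), non-obstetric admissions, out-of-range ages, wrong years,
duplicate detail rows — must never change any selection output, and the
tests enforce this.

What the generator does *not* emulate: municipality structure and
seasonality, realistic ICD subcode distributions, within-state coverage
heterogeneity, readmissions of the same woman, and the garbled regional
cells of the source aggregates (only nationally consistent margins are
packaged). Passing tests therefore demonstrate the *arithmetic* of the
pipeline on data with the published marginal structure, not robustness to
the recording errors of real administrative extracts.

The births-by-maternal-age panel is synthetic in a stronger sense: only
sector totals of live births are published, so a by-band panel was
back-solved to be consistent with them under the coverage split (the file
is named `births_by_age_2015_synthetic.csv` accordingly).

All randomness is confined to this module and seeded; the analysis
pipeline proper is deterministic, so two runs with the same configuration
and seed are byte-identical.

## Scope and problem sizes

The packaged run is national: regional estimates would require the
regional beneficiary panels, whose published cells are partly corrupt.
Tests run the full-scale 2015 dataset (about 155,000 generated records)
once and reuse it; property-style loops use two-region datasets of a few
hundred records. The pipeline is linear in record count and the full run
completes in seconds.

Known limitations, inherited from the method: the 30--34 group shares the
30--39 miscarriage factor (claims data carry no finer bands), likely
over-removing miscarriages there; the calibration survey covers literate
urban women aged 18--39 and counts women rather than abortions; and
out-of-pocket private care appears in neither source. The one-unit factor
bounds are a sensitivity convention, not a confidence interval.
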