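---
title: "Measuring the quality of outpatient CAP antibiotic prescribing from claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the quality of outpatient CAP antibiotic prescribing from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capquality)
```

## The measurement problem

For community-acquired pneumonia (CAP), delaying antibiotics worsens
outcomes, so stewardship cannot simply count prescriptions: it must judge
whether the *right* drug was given at the *right* dose for the *right*
length of time, and whether deviations were clinically defensible.
Administrative claims contain enough signal to make that judgement at
population scale — diagnosis-coded physician visits, dispensation records
with strength/quantity/days-supply, hospital admissions, and coded
comorbidity history — provided the analytic rules are explicit.
`capquality` encodes one such rule system end to end, and pairs it with a
synthetic claims generator with known ground truth so every rule is
testable.

The package assumes claims-like inputs: events are dated to the day,
diagnosis codes are tagged with their code system (ICD-9 / OHIP for visits,
ICD-10 for admissions), and dispensations carry ATC codes. All date
arithmetic is in whole days; same-day events have gap zero.

## Episodes of care

Visits with a configured CAP code are chained per patient into episodes: a
visit joins the current episode if it falls within `gap_days` (default 14)
of the **previous** visit. The rolling-gap reading was chosen over a fixed
window anchored at the first visit because it is the convention in Canadian
outpatient episode-of-infection work; the alternative is available as
`gap_semantics = "from_index"` for sensitivity analyses. The index date is
the first visit of the chain.

Two exclusions are applied as flags (never row deletions, so exclusion
counts remain reportable):

* **chronic span** — episodes whose total span exceeds `max_span_days`
  (default 30). "Exceeds" is read strictly: a 30-day span is kept, 31 days
  is excluded.
* **hospitalised** — an admission in the inclusive window
  `[index_date, end_date + followup_days]` (default 5 days). The window
  includes the episode itself, since an intra-episode admission equally
  implies inpatient treatment with hospital-dispensed antibiotics that
  outpatient claims cannot see. When both exclusions apply, the
  chronic-span reason (applied first) is retained.

## Linking the empiric prescription

Candidate dispensations for a kept episode are the patient's systemic
antibacterials (ATC prefix `J01`, configurable) dispensed in the inclusive
window from index to `followup_days` after the final visit. Only the
earliest is kept — the first dispensation is the best proxy for empiric
therapy — with same-day ties broken deterministically by smallest record
id (the tie rule is a package choice; claims data do not order same-day
fills). If one dispensation is reachable from two episodes of the same
patient (possible only with a stretched follow-up), it is assigned to the
episode with the later index date and a warning is emitted. The linkage
follow-up and the hospitalisation follow-up are deliberately independent
configuration values even though both default to 5 days.

Average daily dose is `strength_mg × quantity / days_supply` (mg/day).
`strength_mg` is the amoxicillin-component strength for combination
products, so doses compare directly with the guideline bounds. Duration of
therapy is the recorded days supply, taken verbatim: reconstructing
duration from quantity and strength would second-guess the dispensing
record without additional information.

## Guideline rules and concordance

The shipped rule set encodes the first-line oral regimens for non-severe
outpatient CAP in older adults and converts each to an average-daily-dose
band (mg/day):

| agent | bounds (mg/day) | rationale |
|---|---|---|
| amoxicillin | 2000–3000 | 1 g twice or three times daily |
| amoxicillin-clavulanate | 1750 | 875 mg (amoxicillin component) twice daily |
| doxycycline | 200 | 200 mg day 1 then 100 mg twice daily, collapsed to its 5-day mean |

The doxycycline loading schedule is collapsed to a regimen mean because
dispensation records carry no day-by-day schedule — only total quantity
over days supply, which for the recommended regimen equals 200 mg/day
exactly. The recommended duration is 5 days for all three agents;
amoxicillin-clavulanate keeps twice-daily dosing only (no three-times-daily
upper bound), the more conservative reading of the available
recommendations.

Two tolerances govern concordance. A relative `dose_tolerance` (default
±10%) widens both bounds before comparison, absorbing strength/quantity
granularity (e.g. a 9×250 mg/day fill should not fall out of a 2000 mg/day
bound). `duration_tolerance` defaults to 0 days — duration concordance is
exact equality to 5 days, because the source guidelines are unambiguous on
5-day therapy — but can be widened for sensitivity analyses. Widening
either tolerance can only move a verdict toward "within" (a tested
monotonicity property). Non-first-line agents skip the dose/duration
assessment entirely: their category is determined by justification alone,
at any dose or duration. Agents matching no rule (by ATC, then by
case-insensitive name) are flagged and, by default policy, treated as
non-first-line.

## The five-category decision table

Each linked prescription receives exactly one category, by the first
matching rule:

1. non-first-line agent, ≥ 1 justification → **clinically appropriate**;
2. non-first-line agent, no justification → **not recommended**;
3. first-line, dose and duration within → **guideline adherent**;
4. first-line, any axis below → **undertreatment**;
5. first-line, any axis above (none below) → **effective but unnecessary**;

then an undertreatment verdict with chronic kidney disease flagged is
reclassified to clinically appropriate, mirroring renal dose adjustment
when creatinine clearance is unobservable in claims.

Rule 4's "any below dominates" formulation does double duty: it implements
the opposing-deviations tie-break (subtherapeutic use is the clinically
riskier error, so dose-below with duration-above is undertreatment), and it
resolves the both-below case, which the category definitions leave
unaddressed, in the same conservative direction. The CKD reclassification
fires whichever axis was subtherapeutic, since the clinical rationale
(reduced clearance) is not axis-specific. The table is exhaustive and
exclusive by construction, and the test suite checks it cell-by-cell
against an independently coded predicate on the full 72-cell grid of
agent class × dose direction × duration direction × justification × CKD.

## Justifications and the Charlson index

A justification flag is raised when at least one qualifying record exists
in `[index − lookback_days, index]` (default 365 days, with per-condition
overrides for jurisdictions that use unlimited lookback for prevalent
conditions). Evidence is drawn from all three record types: diagnosis-coded
visits (prefix match per tagged system), ICD-10 admission diagnoses, and
ATC-prefixed dispensations for the two medication classes
(immunosuppressants: `L04A`, `H02AB`, `L01`; interacting drugs: vitamin K
antagonists `B01AA` by default). One configurable condition registry serves
both the comorbidity flags and the Charlson computation.

The Charlson score is the sum of classic weights over flagged conditions
(MI, CHF, chronic pulmonary disease, diabetes = 1; cancer, renal disease
= 2; CAD and hypertension are justification conditions but not Charlson
conditions, weight 0). "Moderate/severe" is score ≥ 3, aligning with the
conventional 3–4 stratum onset; the threshold is configuration. Validated
institutional Charlson implementations are proprietary; the weight table is
therefore swappable.

## Rates, trends and reporting

Rates are `1000 × count / population` per province-year-category, with
optional direct age standardisation `1000 × Σ w_b (count_b / pop_b)` over
configurable reference weights (the reference standard used by any given
published analysis is rarely stated, so standardised comparisons across
sources are approximate by nature). Temporal trends use Poisson regression
with year as a categorical predictor (first year as reference, so the
reported ratio compares the final against the first year) and
`log(population)` as offset, fitted by IRLS to relative tolerance 1e-8 via
`stats::glm`; confidence intervals are Wald on the log scale. Year can
instead enter linearly (`linear_year = TRUE`) for a trend test. A zero
count in the reference year would make the reference log-rate diverge, so
0.5 is added to all counts and the result is flagged
`continuity_corrected`. In the two-year case the model is saturated and the
estimate equals the closed-form rate ratio exactly — a tested invariant.

All reported tables pass through small-cell suppression: counts below
`min_cell` (default 6) become a marker string, and any derived proportion
or rate inherits the marker. Suppression affects reporting only; the
classifier's category counts always partition the linked prescriptions.

## The synthetic generator

The generator emulates the joint structure the pipeline assumes, with
defaults set once to the published cohort's conditions: age 77.98 ± 8.37
truncated at 65; 53.3% female; comorbidity prevalences from the published
cohort table (hypertension 71%, diabetes 38.7%, …); prescribing
probability 0.49 (between the two provinces' 46% and 52%); a visits-per-
episode distribution with mean ≈ 1.7; durations 7 > 10 > 5 days
(0.54/0.25/0.21) for non-first-line agents; a category mix of roughly 2%
adherent / 61% clinically appropriate / 20% effective-but-unnecessary /
11% undertreatment / 6% not recommended; and a 2% long-term-care fraction,
1% chronic-episode rate, 3% hospitalisation rate and 10% decoy-dispensation
rate to exercise every exclusion and the first-dispensation rule.

Categories cannot be drawn independently of comorbidities: a
not-recommended prescription requires a patient with *no* justification,
and a clinically-appropriate one requires at least one. The generator
therefore draws each prescribed episode's intended category from the
configured mix restricted to the feasible set for that patient's
justification state and renormalised; an undertreatment draw for a CKD
patient becomes an intended clinically-appropriate (reclassified) label.
Under independence of the configured prevalences only ~3% of patients have
no justification, so the realised not-recommended share is far below its
nominal weight — a structural consequence of emulating marginal prevalences
with independent draws, where the real cohort's comorbidity correlations
are unknown.

Three design choices make the noiseless round trip exact rather than
approximate:

* each patient's episodes are placed in equal blocks of the study window,
  at least 65 days apart, so linkage windows (≤ index + 35), decoy
  placements (≤ index + 57) and admission windows can never straddle two
  episodes;
* every true condition is re-evidenced per episode by an ICD-9-coded visit
  inside `[index − 300, index − 30]`, and medication classes by non-`J01`
  dispensations in the same band, so every episode's lookback sees the
  same flags the truth table records (hospital-ICD-10 evidence is
  exercised by handcrafted unit tests instead: a pre-index comorbidity
  admission could collide with a neighbouring episode's hospitalisation
  window);
* every generated regimen reproduces an exact daily dose whose concordance
  direction is unambiguous under the default tolerance (e.g. dose-below
  amoxicillin is 1500 mg/day against a widened bound of 1800).

Each table draws from its own pseudo-random stream derived from the master
seed, so regenerating with a larger cohort leaves earlier patients'
registry rows untouched. Dates are integer day offsets from a configurable
epoch, serialised ISO-8601. `edge_case_rate` (default 0) injects
deliberately unclassifiable prescriptions (an agent outside the rule set)
with no intended label; with it off, the pipeline recovers 100% of intended
categories, and the test suite asserts exactly that.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: correlated comorbidities, provincial coding
dialects beyond the configured lists, seasonality, refill chaining and
adherence, allergy-driven agent switching, creatinine-clearance-based
dosing, and concurrent non-CAP diagnoses competing for the same
dispensation. On real claims the pipeline's accuracy is bounded by the
accuracy of the code lists, which is why they are configuration rather
than constants.

## Problem sizes and runtime choices

The shipped checks use cohort sizes chosen to make sampling error
negligible relative to the tolerances while keeping the default test run
fast: 10,000 patients (≈ 21,000 episodes, ≈ 10,500 linked prescriptions)
for the round trip, 100,000 for demographic convergence checks, 1,000
replicates for Poisson CI coverage, and 1,000 random instances for the
brute-force equivalence of chaining, linkage and suppression.

## Known limitations

* Category definitions depend on dose *bands*; agents prescribed at
  unusual but defensible doses (renal adjustment without a CKD code) are
  classified undertreatment — the CKD proxy has limited sensitivity in
  claims.
* The Charlson implementation scores each configured condition
  independently; hierarchical variants (e.g. severe liver disease
  superseding mild) are not modelled because the shipped registry carries
  no such pairs.
* `from_index` gap semantics and non-default tolerances are provided for
  sensitivity analysis but the shipped defaults are the tested path.
* Poisson trends assume equidispersion; no negative-binomial fallback is
  provided.
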