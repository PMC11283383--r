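---
title: "Methods: claims-based treatment patterns and time-to-event analysis of ibrutinib in CLL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based treatment patterns and time-to-event analysis of ibrutinib in CLL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllclaims)
```

## The problem

National health-insurance claims databases record every reimbursed
dispensation, hospital stay and long-term-disease (LTD) status for tens of
millions of people, but they record *no clinical intent*: no indication on
a prescription, no progression assessment, no dosage, no cause of death.
Studying a targeted oral therapy such as ibrutinib — indicated in chronic
lymphocytic leukaemia (CLL), mantle cell lymphoma (MCL) and Waldenström's
macroglobulinemia (WM) — therefore requires a chain of reconstruction
algorithms: which disease was the drug prescribed for, when was the patient
actually exposed, what counts as a discontinuation when refill quantities
are all you see, which comorbidities were present at initiation, and what
is a defensible proxy for progression-free survival.

`cllclaims` implements that chain as a tested, reusable pipeline over four
delimited tables shaped like French national claims (SNDS) extracts:
`patients`, `dispensations`, `hospital_stays` and `ltd`. Because real
claims extracts are access-restricted, the package also contains a
synthetic claims generator with planted ground truth, so every stage is
verifiable end-to-end without any external data.

## The cohort and the phenotyping algorithm

The cohort is a *new-user* design: the index date is the first ibrutinib
dispensation, which must fall inside the inclusion window (1 August 2017,
when the drug reached community pharmacies, through 31 December 2020).
Patients not continuously covered by the general insurance scheme are
excluded (their history is incomplete), as are patients leaving no care
record after the index (they are unobservable). Follow-up runs to the
study end, death, or loss to follow-up — the last care record before a
period of more than `gap_days = 183` days without any reimbursed care.
Six months is read as 183 days; the figure is configuration, not a fixed
truth.

A boundary case deserves note: a *trailing* care-free period (between the
last care record and the study end) counts as a qualifying gap when it
exceeds 183 days. A consequence is that extending the study end can
*reclassify* a patient from administratively censored to lost to follow-up
once the silence becomes fully observable; follow-up is monotone in the
study end except for this disclosure effect, and the test suite pins down
exactly that behaviour. A death occurring within 183 days of the last care
record takes precedence over the gap.

The indication is recovered from diagnosis codes C91.1 (CLL), C83.1 (MCL)
and C88.0 (WM) in LTD statuses and all hospital diagnosis positions, by a
two-branch rule: the *latest* diagnosis strictly before index wins;
failing that, the *earliest* diagnosis up to 30 days after the last
ibrutinib dispensation wins; otherwise the patient is unclassified. Two
different disease codes on the same qualifying date yield `unclassified` —
the algorithm is deliberately restrictive, because misclassification
cannot be audited downstream. All code matching is prefix-based on
normalized codes (`C91.1` ≡ `C911`).

## Exposure: regimens from refill arithmetic

Claims carry quantities, not dosage. Coverage is therefore valued at the
lowest posology used in practice — one capsule per day — so a dose
reduction is never mistaken for a discontinuation; the price, which the
package inherits knowingly, is that short true pauses are invisible. A
dispensation of *q* capsules on day *d* covers the half-open interval
[*d*, *d* + *q*). Successive dispensations belong to the same regimen when
the next one falls no more than `grace_days = 30` after the coverage end;
30 days is chosen so that ordinary monthly-refill jitter can never split a
regimen, while observed inter-regimen breaks (about four months) always
do. A regimen whose coverage ends at least `discontinuation_days = 90`
before the end of follow-up is a *permanent discontinuation*; one still
covering at the end of follow-up is right-censored. Both thresholds are
configuration, not fixed truths, and the regimen builder is verified
against an independent day-by-day coverage oracle on a thousand random
refill histories.

Line of treatment is L2+ iff any CLL-specific drug (rituximab,
bendamustine, fludarabine, obinutuzumab, chlorambucil, venetoclax,
idelalisib, acalabrutinib, lenalidomide, doxorubicin, bortezomib) appears
strictly before index anywhere in the available history; cotherapy is any
such drug dispensed inside a regimen's coverage interval; the next
treatment is the earliest such drug after the last regimen's coverage end.
The treatment-free interval (TFI) is the gap from coverage end to next
treatment and is nonnegative by construction. Infusion drugs bundled into
hospital tariffs (intra-DRG) are representable only as an opaque `SESSION`
marker, mirroring what claims actually contain.

## Comorbidities and probabilistic markers

Baseline comorbidity uses a 12-month lookback over hospital diagnoses
(all positions by default; main/related only is a switch) plus LTD
statuses active at index — an LTD is a standing status, so its start date
may be arbitrarily old. Cardiovascular disease is additionally inferred
from *probabilistic markers*: a pacemaker device code on any pre-index
stay, or at least `marker_k = 3` dispensations of an antiplatelet (B01AC)
or anticoagulant (B01AA/AB/AE/AF) class in the lookback year. The
threshold of three keeps one-off perioperative prescriptions from flagging
chronic disease. The Charlson index uses the Quan ICD-10 coding with the
standard weights and hierarchy rules (metastatic disease supersedes
primary malignancy, complicated diabetes its uncomplicated form, severe
liver disease the mild form), plus age points (+1 per decade from 50–59,
capped at +4) — age adjustment is a switch because administrative-data
studies vary on it. Every code list ships as an editable YAML file
(`inst/extdata/comorbidity_codes.yaml`).

## Safety events and medication initiation

Hospitalizations for six cardiovascular/bleeding categories (atrial
fibrillation, hypertension, bleeding, cardiac arrest, paroxysmal
tachycardia, heart failure) are detected from *main and related* discharge
diagnoses only, with admission inside the exposure period (first regimen
start through last coverage end). Detecting over the exposure period —
whether or not treatment later resumed — reproduces the design it
emulates, including its acknowledged blind spot for events after the last
coverage day. Continuation after the first event is at least one ibrutinib
dispensation on or after that stay's discharge. Medication initiation in
the year after index uses a new-user rule (no dispensation of the class in
the lookback year) for anticoagulants and antiplatelets, and for
antihypertensives additionally an *add-on* rule: the count of distinct
ATC level-3 antihypertensive classes post-index exceeds the pre-index
count and reaches two or three. The pre-index class count uses the same
12-month lookback as the new-user rule; the add-on window is otherwise
unspecified in the design being emulated, and this is the package's
choice.

## Endpoints and estimation

TTNT — time from index to the first next-treatment dispensation or death,
whichever first — serves as the progression-free-survival proxy; TTD
replaces the next treatment with the permanent-discontinuation date.
Censoring is at the end of follow-up. Events on the index day get time
0.5 days so that entry strictly precedes exit. Reported "months" are
days / 30.4375 throughout.

The Kaplan–Meier estimator is the plain product-limit form with Greenwood
variance; the median is the smallest event time with S(t) ≤ 0.5 and is
reported as "not reached" when the curve never gets there. Without
censoring it reduces exactly to the empirical survivor function, which the
tests assert.

The Cox model is fitted by Newton–Raphson on the partial likelihood over
counting-process risk sets, from β = 0, with step-halving on any
likelihood decrease, convergence at a score sup-norm below 1e-9 (or a
numerically stationary likelihood — the score cannot be driven below
cancellation noise on large sums), and a hard stop with a named error when
a coefficient exceeds ±15, the signature of a monotone likelihood. Efron
tie handling is the default because day-granularity claims produce heavy
ties; Breslow is retained for cross-checks. The hospitalization covariate
is time-dependent: subjects are split at their first event
hospitalization, with left-continuous covariate paths, so a
hospitalization on the event day does not affect that day's risk set.
Standard errors come from the observed information; the score test at
β = 0 equals the log-rank statistic on tie-free data to 1e-8, which the
suite verifies against an independent implementation. Risk-set sums are
computed by a prefix-sum decomposition (risk set = {entry < t} minus
{exit < t}), making each derivative evaluation linear in records after
sorting.

The unadjusted column of the Cox table fits one covariate (or the age
dummy pair) at a time on the same counting-process data; the adjusted
column fits all jointly: sex, age class (<65 reference, 65–69, ≥70),
cardiovascular comorbidity, time-dependent hospitalization, line, and
medication initiation. Medication initiation is itself post-baseline and
its effect is an average over the study period, not a causal contrast —
the fit carries no proportional-hazards diagnostics beyond that caveat.

## The synthetic generator: what it emulates and what it does not

The generator's defaults *are* the study conditions: age N(73, 10), 61%
male, 46.6% cardiovascular comorbidity (about a third of it marker-only),
80% second-or-later line, disease mix 55/22/15/8 over CLL/MCL/WM/other,
28-capsule boxes refilled on a ~30-day cadence (jitter clipped to [21, 45]
days so refill noise never splits a regimen), a ~5% chance of one
deliberate regimen break of 95–160 days, and per-day baseline hazards for
next treatment, death and event hospitalization acted on by log-hazard
ratios for age ≥ 70, cardiovascular comorbidity, L2+ and a time-dependent
hospitalization switch (0.31, 0.40, 0.33, 1.11 — the natural logs of the
adjusted hazard ratios the design targets). Event-time competition is
resolved by simulating each cause and taking the minimum, ties broken
toward death. Every per-patient quantity is drawn from a substream keyed
by (seed, patient counter), so generation is order-independent and
byte-reproducible.

Ground truth records, per patient, the disease, line, regimen intervals,
comorbidity status, event times and causes, and whether the patient should
survive cohort selection; on noise-free data the pipeline recovers all of
it *exactly*, and with a planted fraction of missing diagnoses exactly the
noised patients come out unclassified. That is what passing tests show —
and also what they do not: the generator plants exactly one indication
code per patient, never a conflicting or miscoded one; refill cadence and
break lengths are stationary; hazards are exponential. Real claims violate
all of these, so recovery rates on real data would be lower, and the
package makes no claim otherwise. Reproducing any real cohort's counts or
hazard ratios is out of scope by design: the quantities the pipeline
reports on synthetic data are functions of the configured conditions.

A separate tie-free survival benchmark (`generate_survival_benchmark`)
simulates piecewise-exponential event times under exact proportional
hazards with one time-dependent covariate. Across 200 replicates at
n = 500, the fitter's absolute bias on each log-hazard ratio stays below
0.05 and empirical 95% CI coverage within [0.92, 0.98] — the standard
sanity band for a correctly calibrated estimator.

## Numerical and design choices

* Dates are whole calendar days; durations integer days; months =
  days / 30.4375; years = days / 365.25. Birth is known to the month, so
  age uses the mid-month day 15.
* Intervals are half-open. The regimen merge rule compares the next
  dispensation date to the *exclusive* coverage end plus the grace
  period: coverage running through day *d* and a refill on day *d* + 1 is
  contiguous treatment even at grace 0. This reading is forced by the
  regimen's definition as a maximal interval of continuous coverage and is
  pinned by the day-by-day oracle tests.
* The inter-regimen break is the count of *uncovered* days between two
  regimens.
* `unclassified` ties, the 183-day gap, the 90-day discontinuation
  threshold, the marker threshold, and ATC code lists are all
  configuration with the defaults above.
* Problem sizes used by the test suite — 1,000 random refill histories,
  200 benchmark replicates at n = 500, phenotyping cohorts of 2,000 —
  were chosen as the smallest sizes at which the checked properties are
  sharp (exact equality for phenotyping; Monte-Carlo bands for coverage).

## Known limitations

Everything the source data cannot express is out of scope: dosage (hence
short pauses), intra-DRG drug identity, progression (hence the TTNT
proxy), cause of death, outpatient specialist diagnoses, and any causal
attribution of events to treatment. The phenotyping algorithm is
restrictive by construction and will under-classify patients coded only
with unspecific haematologic codes; that is the intended trade-off.
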