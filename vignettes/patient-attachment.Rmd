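---
title: "Methods: hierarchical patient attachment from administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical patient attachment from administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcattach)
```

## The classification problem

Administrative health data record *transactions* — billed claims, formal
enrollment (roster) intervals, community health centre (CHC) encounters —
while "having a primary care provider" is a *relationship*. `pcattach`
operationalises that relationship as a hierarchy of progressively weaker
evidence, evaluated strictly in order for each person at an index date:

1. **PEM** — a roster interval covers the index date. Formal enrollment is
   the health system's own record of attachment, so it dominates.
2. **CHC** — at least one CHC visit in the lookback window. CHC physicians
   are salaried and do not bill claims, so their patients would otherwise
   be invisible to a claims-based rule.
3. **VIRTUAL** — plurality-of-visits attribution, gated by the attributed
   provider's continuity-of-care (CoC) index.

The first rule that fires decides; a person satisfying none is
*uncertainly attached*. The ordering is by strength of evidence and, in
the population the algorithm was designed for, by the number of people
each step resolves. Because earlier steps shadow later ones, adding claims
can never change the verdict of a rostered person, and removing a roster
record can only move a person *down* the hierarchy — properties the test
suite asserts directly.

### Virtual enrollment

Within each person's window, claims are reduced to *core visits*: service
code on the configured core list, office setting (ED and nursing-home
claims carry setting-specific codes and never attribute a patient to the
provider), at most one visit per patient-provider-day. The person is
attributed to the provider with the most such visits. Ties are broken by
the most recent visit date to each tied provider, then by smallest
provider identifier. The recency rule is a modelling choice — the most
recently active relationship is the most plausible current one — and the
identifier rule makes the result fully deterministic and independent of
input row order. A person with zero windowed core visits is attributed to
no one.

### The provider CoC index

Plurality alone would happily attribute an episodic walk-in user to
whichever walk-in clinic they visited twice. The gate is a per-provider
index computed over the **full population's** windowed visits, not only
the cohort being classified:

\[ \mathrm{CoC}_j \;=\; \frac{\#\{\text{patients virtually enrolled to } j\}}
        {\#\{\text{unique patients } j \text{ saw in the window}\}} . \]

A high-continuity practice sees mostly its own panel, so numerator and
denominator nearly coincide; a walk-in-style provider sees many unique
patients of whom few have their plurality there, so the index is small.
With the default cut-point of 0.10 and the default `strict_greater`
comparator, a provider at **exactly** 10% is low-continuity and its
virtually enrolled patients are deemed uncertainly attached. The source
descriptions of the rule disagree on whether the boundary itself is low
("≤ 10% is low" vs "≥ 10% attaches"); both comparators are implemented and
the difference is measure-zero except on exact ties, which the tests cover
explicitly. A *visit-based* variant of the index (visits by the provider's
virtually enrolled patients over all visits to the provider) is available
as `coc_mode = "visit"` for sensitivity analysis; the patient-count ratio
is the primary definition.

## Windows and index dates

The lookback window is `(index_date - lookback_days, index_date]` —
exclusive below, inclusive of the index date itself — with
`lookback_days = 730` standing in for "two years" (leap-day drift
accepted). Two anchoring policies exist:

* **survey** (validation runs): each respondent is anchored at their own
  survey date, so "the two years prior to completing the survey" is exact
  per person. The same per-person windows feed virtual enrollment and the
  population CoC computation; patients without a survey record are
  anchored at the latest survey date (or an explicit `index_date`).
* **fixed** (population application): everyone is anchored at one
  calendar date, e.g. December 31 of a reference year.

PEM membership is evaluated *at the index date* (interval covers it), not
"any time in the window": enrollment is the system's statement of the
person's current attachment, and a lapsed enrollment should not attach
anyone. A patient holding several intervals covering the date is an
upstream integrity error; classification resolves it deterministically in
favour of the latest `start_date`.

Persons absent from every event table are classifiable and come out
uncertainly attached — necessary for population application, where most
of the population never appears in the claims of a given window.

## Validation harness

The survey self-report ("do you have a PCP?") is the reference standard.
`confusion()` joins verdicts to responses (respondents without a verdict
are excluded and counted as linkage failures), and `diagnostic_metrics()`
computes sensitivity, specificity, PPV and NPV as percentages. Rounding is
**half-up to one decimal** — chosen to match how such metrics are printed
— applied once at the end; base `round()` rounds half-to-even and would
disagree on exact .x5 values, which the tests demonstrate. A metric whose
denominator is empty is reported as `NA`, never 0. `split_cohort()` cuts
the survey at a date into development (strictly before) and validation
(on/after) sets. `compare_thresholds()` reruns the engine at two CoC
cut-points and compares the true-negative proportion (among respondents
reporting no PCP) and true-positive proportion (among those reporting one)
with a two-sample proportion z-test (normal approximation, no continuity
correction, significance 0.001). Because the uncertain set at a higher
cut-point is a superset of the one at a lower cut-point, the true-negative
proportion can only rise with the cut-point; the tests pin this direction
on a hand-built instance with a walk-in provider at CoC exactly 0.15.

## What the synthetic generator emulates

`generate_scenario()` produces the six tables plus ground truth. Its
structure, and the reasoning behind the defaults:

* **Strata are drawn with fixed counts** (round(n · fraction)), not
  per-person coin flips: roster coverage 81.4% of the cohort and CHC use
  1.5% are the anchor marginals, and fixing the counts removes needless
  Monte-Carlo noise from calibration checks. Rostered patients are drawn
  from the truly attached; CHC users from the attached, non-rostered
  remainder (CHC physicians do not roster, and their patients' primary
  care leaves no claims).
* **Truly attached** patients (88% by default) hold a usual regular
  provider. Usual-provider visit counts are a shifted Poisson
  (`1 + Poisson(mean - 1)`, default mean 6 over two years): the minimum of
  one visit encodes the generator's definition of behavioural attachment —
  an attachment that produces no contact in two years is not recoverable
  from claims by construction, and modelling it would only blur ground
  truth. Stray visits (Poisson, default mean 2, 90% to walk-in providers)
  model care received away from the usual provider.
* **Truly unattached** patients draw episodic visits (Poisson, mean 2,
  95% to walk-ins). Nothing prevents an unattached person's visits from
  concentrating on a regular provider — such people are *correctly*
  attributed by the plurality rule and become the algorithm's false
  positives, which is the behaviour the validation study observed (modest
  specificity).
* **Walk-in CoC is low by construction**: walk-ins receive high unique-
  patient traffic (strays from the attached plus episodic visits) but few
  pluralities. At the preset's provider mix (13% walk-ins, ~87 patients
  per provider) the walk-in CoC indices sit near 0.07–0.09, safely below
  the 0.10 cut-point, while regular practices sit near 0.8–0.9. During
  preset design the stray mean was raised from 1.5 to 2.0 because the
  walk-in CoC upper tail touched the cut-point at the calibration scale,
  violating the construction. The margin shrinks at small n (fewer
  walk-in providers means fewer distinct-patient pairs per provider), so
  the preset's marginals are calibrated and guaranteed only at
  n = 10,000.
* **Survey misreporting**: self-report is the truth flipped with
  P(report yes | unattached) = 0.70 and P(report no | attached) = 0.02.
  The asymmetry mirrors the validation study's signature: self-reported
  attachment (~95%) exceeds algorithmic attachment (~89%), and most
  uncertainly attached respondents say they have a provider. Setting both
  rates to zero with full behavioural separation (no strays, no episodic
  visits, no walk-ins) makes all four metrics exactly 100.0 — the
  generator's identifiability check.
* **Hospital encounters** are a flat Poisson (rate 0.3 per person per
  window, 70% ED / 30% admission) so the uncertain-usage audit has
  signal; they play no role in classification.
* **Non-attributing claims** (non-core codes, ED settings) are generated
  at a low rate purely to exercise the core filter in pipelines.
* **Seeding**: one integer seed is expanded into a fixed vector of
  per-stage seeds drawn up front, so adding a later generation stage can
  never perturb earlier stages, and regeneration is byte-identical.

What the generator does **not** emulate: provider group practices (the
real system rosters to individuals who practice in groups), roster churn
around the index date, age- or geography-structured attachment, visit
seasonality, and any linkage error between tables. Passing tests
demonstrate the algorithm's internal correctness and its behaviour under
the generator's assumptions — not its accuracy on real administrative
data, where misclassification has sources (e.g. walk-in visits not
distinguishable from office visits in claims) that no synthetic bundle
certifies against.

## Numerical and degenerate-input choices

* Percentages: double arithmetic, half-up rounding to one decimal applied
  once at the end; zero denominators yield `NA`.
* Window boundary: exclusive lower / inclusive upper, so a 730-day window
  spans exactly 730 candidate dates.
* Ties: plurality — recency then smallest provider id; concurrent roster
  intervals — latest start date then smallest provider id.
* Empty inputs: an empty cohort returns empty results and an all-zero
  flow report; a patient with no visits gets a null enrollment; providers
  seen by nobody have no CoC row (never a 0/0).
* I/O: dates are ISO-8601, identifiers opaque strings, empty roster
  `end_date` means an open interval; reading is all-or-nothing with
  row-indexed diagnostics, so a file either parses completely or fails
  loudly.

## Problem sizes in the test suite

Unit and property tests run on instances of 2–20 patients (brute-force
oracle comparisons, ≥ 200 random cases) up to a few hundred. End-to-end
checks use 500-person scenarios against a straight-line re-implementation
of the three rules; calibration checks run the preset at n = 10,000; the
noise-degradation check averages 10 seeds per noise level at n = 1,500.
These sizes were chosen as the smallest at which the quantities being
checked are stable.

## Known limitations

* The pediatric access algorithm for under-19s is jurisdictional prior
  work; the package exposes only the hook.
* Nurse practitioners and other non-physician primary care leave no
  claims in the modelled tables, exactly as in the real data sources.
* The visit-count distribution is Poisson by choice, not by evidence; it
  is a named, swappable assumption of the generator, not of the
  algorithm.
* The two-sample proportion comparison uses the normal approximation;
  at the cohort sizes involved this is indistinguishable from the exact
  test, but very small scenarios should not rely on its p-values.
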