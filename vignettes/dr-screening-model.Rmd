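---
title: "A Markov cohort cost-utility model of diabetic retinopathy screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of diabetic retinopathy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drcea)
```

## The decision problem

Diabetic retinopathy progresses silently from no apparent disease through
non-proliferative (NPDR) and proliferative (PDR) stages, with diabetic
macular edema (DME) as a parallel vision-threatening complication; severe
visual impairment (SVI) is costly and largely irreversible, while
photocoagulation and anti-VEGF therapy substantially slow progression when
disease is caught early. The policy question this package quantifies is
whether organised screening of diabetic patients — by community fundus
photography or by telemedicine reading — is worth its cost in rural and
urban Chinese settings, and at what repeat interval.

## State space and transitions

The cohort model tracks ten states: the product of clinical state (no DR,
NPDR, PDR, DME, SVI, death) and management status (undiagnosed, NPDR under
annual follow-up, treated PDR, treated DME), with SVI split into a
first-year and a subsequent-year state purely so the higher first-year care
cost can be charged exactly once. The product space is needed because
treated and untreated disease progress at different rates and diagnosed
NPDR incurs an annual follow-up cost: a plain six-state model cannot carry
that information.

Each annual cycle applies, in order:

1. **Screening** (only at scheduled cycle starts): misclassification,
   referral, confirmation, treatment initiation — flags change, health
   states do not.
2. **Mortality**: background q(age) times 1.97 (diabetes) or 3.9 (SVI),
   capped at 1. Mortality is resolved first and disease transitions apply
   to survivors — the standard competing-risk convention in cohort models;
   the underlying studies do not fix an ordering.
3. **Disease transitions** among survivors at the annual probabilities
   (`param_registry()` lists them all); residual mass stays put. No
   recovery transitions exist, matching the source model and biasing the
   analysis, if anything, against screening (benefits of treatment-induced
   regression are not counted).

Two deliberately exposed structural choices:

* **SVI mortality multiplier.** The risk ratios 1.97 and 3.9 are published
  side by side with no statement on whether they compose for visually
  impaired diabetics. We default to *replacement* (SVI patients use 3.9
  alone) because the product (7.68) is nowhere stated;
  `mortality$svi_multiplier_mode: stack` selects the multiplicative
  alternative.
* **Treated PDR and DME.** Treated patients "remain or progress to SVI",
  so by default treated PDR has no DME pathway;
  `model_options$treated_pdr_to_dme: true` re-enables it (routing into
  treated DME, with the anti-VEGF cost charged on the transition).

## Screening cascade

A screening test is described by grade-calling errors (probability a normal
eye is called NPDR; a true NPDR eye is called normal; a PDR eye is called
NPDR or normal) plus a separate DME detection channel
(sensitivity/specificity). The two channels are assumed independent; a
person is referred if the grade call is NPDR/PDR *or* the DME flag fires.
Hospital confirmation is assumed perfect — the exam is priced ($100,
including transport) but no hospital error rates are published. Confirmed
NPDR enters annual follow-up ($122.32/yr, half-cycle corrected, until
progression or death); follow-up is assumed to detect progression with
certainty at the next cycle, initiating treatment directly (clinical
surveillance, not re-screening). False negatives stay undiagnosed until a
later screening round — there is no symptomatic-presentation pathway, which
understates late-stage detection under no screening and therefore slightly
favours screening.

Only undiagnosed, alive patients are invited: those already under
follow-up, treated, or visually impaired are in care and would not
re-enter a population screening programme. Attendance is independent
across rounds.

## Economics

Monetary values are 2020 USD (CNY inputs convert at 6.9762 CNY/USD).
Capital items are annualized by the annuity factor
\(((1+r)^n - 1)/(r(1+r)^n)\) at r = 0.035 over n = 5 years. The shipped
cost tables were produced with that factor *truncated* to two decimals
(4.51): the printed equipment lines reproduce to the cent only under the
truncated factor, so `rounding = "printed"` (the default for fixture work)
truncates, while `rounding = "exact"` uses full precision for new analyses.
Programme cost per screened person divides annualized capital plus annual
recurring cost by 20,000 people/year ($2.44 community, $1.84 telemedicine).

Costs and utilities are discounted at 3.5%/yr. Half-cycle correction is the
trapezoidal average of the state occupancy at the two cycle boundaries,
applied to utilities and recurring costs (follow-up, SVI care) at the
cycle-end factor \((1+d)^{-k}\). One-off event costs are undampened:
screening-round costs are charged at the cycle-start boundary factor
\((1+d)^{-b}\) (so the entry screen is undiscounted), treatment initiated
by within-cycle follow-up detection at the cycle-end factor. Only the
\(\sum_t (1+d)^{-t}\) shape of the accumulation is inherited from the
source; the boundary conventions are this package's own and are frozen in
the closed-form engine tests.

ICURs compare discounted per-person totals; a comparison with
|ΔQALY| ≤ 1e−9 is flagged undefined rather than divided (guarding ratio
blow-up), and dominance (cheaper *and* more effective) is labelled instead
of reported as a negative ratio. Interval recommendation walks from the
longest interval to the shortest, accepting each shortening whose pairwise
ICUR against the last accepted interval is below 3× per-capita GDP.

## What the synthetic-data module supplies

The published analysis leaves three ingredients unprinted, which this
package generates and labels as assumptions:

* **Background mortality**: a Gompertz schedule
  \(q(a) = \min(1, 0.004\,e^{0.085 (a-50)})\) over ages 50–100 — roughly
  0.4% annual mortality at 50 doubling every ~8 years, a plausible adult
  shape but *not* any national life table; ages beyond 100 reuse q(100).
  Any real schedule can be supplied via the config.
* **Compliance**: screening uptake 0.80 and referral acceptance 0.70, for
  both modalities and both settings. Equal compliance across modalities is
  the single assumption with the largest qualitative consequence: it makes
  community screening detect weakly more disease than telemedicine in
  every channel, so telemedicine ends up cheaper but very slightly less
  effective here, whereas modality-specific compliance could reverse that.
* **Perturbed parameter sets** (`perturb_parameters()`): lognormal noise
  followed by invariant repair, used for property-style testing.

Because mortality and compliance are synthetic, the absolute per-person
costs and QALYs differ from the published summary table (shipped verbatim
in `inst/extdata/published_summary.csv` for ratio checks); what the test
suite claims is therefore (i) exact reproduction of all *printed
arithmetic* (costing lines, annualization, ICURs from printed increments),
(ii) internal correctness of the engine against closed forms and an
independent microsimulation, and (iii) the qualitative decision structure
(screening gains QALYs and is cost-effective at 3× GDP; telemedicine is
preferred at the 1× GDP threshold in most probabilistic draws). Passing
tests do not certify the unprinted real-world inputs.

## Sensitivity analysis

One-way DSA moves each parameter to ±10% of its base (probabilities,
utilities, test accuracy, compliance), ±20% (programme costs) or ±50%
(treatment and SVI costs) — the cost split is an assumption, configurable
per group via `dsa_ranges` — clipping to valid supports and repairing
relational invariants rather than aborting, and reports the ICUR span per
parameter sorted as a tornado. Under these synthetic conditions the spans
are dominated by the SVI/treatment cost parameters (wide ranges on large
cost streams) and the DME pathway rather than by the treated-PDR
progression probability.

PSA fits beta distributions to probabilities and utilities and gamma to
costs by method of moments, with the mean at the base value and
SD = (hi − lo)/(2 × 1.959964) from the 95% interval; costs without printed
intervals use their DSA range as the interval. Complement entries (the
called-normal fractions) are recomputed from their drawn counterparts so
classification rows stay stochastic. Parameters are drawn independently
(no correlation structure is published); a draw violating any invariant is
rejected and redrawn, with the count reported — at the shipped fixtures
roughly a quarter of draws are redrawn, almost entirely where the utility
CIs of adjacent severity states overlap. ICUR CIs are percentile (2.5/97.5)
over draws with resolvable ΔQALY; acceptability curves report
P(NMB(λ) > 0) on a λ grid from 0 to 3× GDP. The default 1,000 iterations
(the source does not state its count) are seed-deterministic.

## Validation oracle

`microsimulate()` re-implements the identical decision process at the
individual level — same event ordering, valuation, discounting and
half-cycle convention, but independently written per-individual sampling
of death, progression and screening outcomes (it never calls the cohort
engine's transition-matrix code). Cohort totals are expectations of the
microsimulation, so agreement within Monte-Carlo error is a genuine check
of the transition algebra. The suite cross-validates five configurations
(both modalities, both settings, including a 2-yearly interval) at 100,000
individuals against a 3-standard-error band.

## Problem sizes and tolerances

Matrix row sums and occupancy mass are held to 1e−12; rate/probability
round trips to 1e−12; the ΔQALY guard is 1e−9. Moment checks of fitted
distributions use 100,000 draws against a 3-SE band. The test suite runs
PSA at 10–1,000 iterations and the microsimulation oracle at 20,000 (unit
level) and 100,000 (end-to-end) individuals — sizes chosen so the
Monte-Carlo bands are tight enough to catch a misplaced factor while the
whole suite stays interactive.

## Known limitations

DME treatment is idealised (no clinically-significant-edema subtypes, no
retreatment, no surgical costs); no recovery transitions; attendance is
uncorrelated across rounds; utilities do not distinguish treated from
untreated disease within a clinical state; the 1×/3× GDP thresholds are
taken as given constants ($7,000/$12,000 per setting) since the published
derivation from GDP, urbanization and income ratio does not reproduce under
any obvious decomposition; and the equal-compliance default means
cross-modality comparisons here describe test characteristics only, not
the access advantages that motivate telemedicine in practice.
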