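---
title: "Markov cohort cost-effectiveness modelling of colorectal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort cost-effectiveness modelling of colorectal cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The decision problem

`crcscreen` implements a deterministic annual-cycle Markov cohort model for
comparing population colorectal cancer (CRC) screening strategies in a
high-incidence, high-longevity Asian setting. A closed cohort of 100,000
average-risk 50-year-olds is offered one of four programmes until age 75 —
annual faecal immunochemical testing (FIT) with conventional colonoscopy
follow-up of positives (`fit_colo`), FIT with AI-assisted colonoscopy
follow-up (`fit_ai`), direct conventional colonoscopy every ten years
(`colo`), or direct AI-assisted colonoscopy (`ai_colo`) — and compared with
no screening. Effectiveness is measured as cancer-related life years saved;
the headline statistic is the incremental cost-effectiveness ratio (ICER),
the cost difference divided by the life-year difference between two
strategies, with dominance flagged when one strategy is simultaneously
cheaper and more effective.

AI-assisted colonoscopy is modelled the way the health-economics literature
treats it: identical unit cost to conventional colonoscopy (the one-time
software cost is negligible and excluded), but a larger CRC incidence
reduction (48.9% versus 44.2%) reflecting its higher adenoma detection.

## Model structure

Health states are: susceptible (never diagnosed, subdivided by screening
sub-state), diagnosed CRC by stage 1–4 in a five-year tunnel, cured, and
three absorbing death states (cancer, other cause, procedure-related
perforation). Each annual cycle applies events in a fixed order:

1. **Other-cause death** from the all-cause life table, at every age and in
   every living state.
2. **Screening events** (below the stop age): FITs, colonoscopies,
   polypectomies, and their complications.
3. **CRC incidence** among the susceptible, at the age-band hazard reduced
   by the strategy's effective incidence reduction, with the fixed stage
   distribution applied at diagnosis and the stage-care lump cost triggered.
4. **CRC death** among prevalent cases at stage-specific annual rates;
   patients who survive five consecutive annual draws exit to `cured`, after
   which cancer mortality and screening no longer apply (no recurrence
   surveillance is modelled).
5. **Accrual** of life-years-lost, procedure, complication and cost ledgers.

The within-cycle event order is a genuine modelling choice — it moves
results at the third significant figure — so it is fixed and documented
here rather than left implicit. Deaths are end-of-year events; no half-cycle
correction is applied, mirroring the simple spreadsheet cohort tradition
this class of model comes from. Mass is conserved to 1e-6 every cycle (a
tested invariant), and the model runs to the life-table horizon (age 100),
where closure (`qx = 1`) absorbs everyone.

### Screening pathway state machines

Susceptible persons occupy one sub-state of their arm's pathway:

* **FIT arms** — the due pool is offered a FIT (compliance 0.60). Positives
  (positivity = sensitivity x prevalence + (1 - specificity) x (1 -
  prevalence); undetected-disease prevalence is proxied by the current
  age-band hazard, so positivity is essentially the false-positive rate)
  attend colonoscopy with probability 1.0. A polypectomy (73% of
  colonoscopies) starts three-yearly surveillance; a clean colonoscopy
  starts a ten-year hiatus after which FIT resumes.
* **Direct arms** — the due pool attends colonoscopy (compliance 0.989),
  clean results repeat in ten years, polypectomies enter the same
  three-yearly surveillance loop.
* **Surveillance** repeats while polyps are found (probability 0.73 per
  visit, reusing the polypectomy rate; no separate recurrence probability is
  published) and reverts to the ten-year track otherwise. The expected
  number of surveillance colonoscopies per entrant is therefore the
  geometric sum 1/(1 - 0.73) = 3.70, which the state machine reproduces to
  1e-3 over a long horizon (a tested identity).

**FIT re-offer policy.** The package's default is `fit_reoffer =
"per_hiatus"`: a person who tests *negative* rests for the same ten-year
interval as a clean colonoscopy, while non-attenders are re-invited
annually. This choice is deliberate. Published outcome tables for this
programme design report roughly 2.4 FITs per person and 0.37 colonoscopies
per person over 25 years in the FIT arms — volumes that are irreconcilable
with literal annual re-offers to every negative (which produce ~15 FITs per
person and funnel most of the cohort through the colonoscopy surveillance
loop, several-fold higher screening costs, and an inverted cost-
effectiveness ordering between FIT-based and direct strategies). Under the
default policy the model reproduces both the published volume scale (2.55
FITs/person; direct-arm colonoscopies within 2% of the published count) and
the published ordering. The literal-annual policy remains available
(`options$fit_reoffer = "annual"`).

### Effective incidence reduction

Prevention enters the model only through incidence-reduction fractions —
there is no adenoma–carcinoma natural-history sub-model, and screening does
not shift the stage distribution at diagnosis (the published stage-cost
proportions are constant across strategies; a stage-shift hook exists but
ships disabled). The per-strategy effective reduction is:

| strategy | reduction | persistence |
|---|---|---|
| `fit_colo` | 0.21 x FIT compliance x follow-up compliance | screening window only |
| `fit_ai` | 0.21 x (0.489/0.442) x FIT compliance x follow-up compliance | screening window only |
| `colo` | 0.442 x primary compliance | lifelong |
| `ai_colo` | 0.489 x primary compliance | lifelong |

Three choices here are worth justifying. First, the FIT bundle for the AI
arm scales the 21% FIT-pathway effect by the AI/conventional efficacy ratio,
because the pathway's preventive effect is realized at the follow-up
colonoscopy; published prevented-case counts for the two FIT arms sit in
exactly this ratio. Second, the bundle is multiplied by *both* the FIT and
the follow-up-colonoscopy compliance (the latter is 1.0 in the base case, so
base results are unaffected): protection accrues only to people who test and
attend follow-up, and without this factor a joint compliance sweep shows the
ICER *rising* with compliance — the opposite of the established direction —
because procedure volume would scale quadratically while effect scaled
linearly. Third, colonoscopy-based protection persists beyond the screening
stop age (removing adenomas prevents cancers for decades), whereas
FIT-based protection applies only while the programme runs; published
prevented proportions (~42–46% for direct arms versus ~4% for FIT arms over
the whole horizon) are only consistent with this asymmetry. Persistence is
switchable (`options$colonoscopy_protection_persists`).

## The synthetic standard life table

The all-cause mortality input is a standard life table. No observed table is
bundled; instead `synth_life_table()` generates one from a Gompertz–Makeham
hazard, h(x) = c + a·e^{bx}, with q_x = 1 − exp(−h(x)) and closure q = 1 at
age 100. The defaults (a = 3e-5, b = 0.09 per year, c = 5e-4) target the
residual life expectancy at age 50 of a high-longevity East Asian
population: 33.3 years, within the plausible 30–37 band. The generator is
deterministic; it emulates the *level and shape* of adult mortality but not
cohort effects, sex differences, or old-age mortality deceleration, so all
absolute life-year magnitudes downstream are tolerance-level, not exact.
Users with an observed table can supply it via `read_life_table()` (two-
column CSV `age,qx`).

Residual life expectancy is the survival-product sum e_x = sum over t >= 1
of prod_{k<t}(1 − q_{x+k}). A cancer death at age A in cycle t forfeits
e_A undiscounted years; the discounted ledger discounts each forfeited year
by (1+r)^-(t+s), anchored at model start (the alternative anchor, the death
year, is switchable via `options$discount_lyl_from`).

## Costs and discounting

All costs are US dollars, discounted at 3%/year alongside life years;
reported *counts* are undiscounted. CRC care is charged as a single
stage-specific lump sum at the diagnosis cycle (the published stage totals
already bundle diagnosis, treatment and the nine-day admission; no spreading
rule is published). The consultation fee ($96) attaches once per colonoscopy
attendance and the histopathology fee ($142) once per therapeutic
colonoscopy — both attachments are documented toggles, since no attachment
rule is published. Complications are charged per colonoscopy (bleeding
0.98%, perforation 0.08%); perforation mortality (0.0029%) is interpreted
per perforation event, with per-colonoscopy and per-polypectomy bases
switchable. Perforation deaths are procedure-related, not cancer deaths:
their forfeited life years accrue to a separate ledger excluded from
"cancer-related life years".

Internally all money is double precision; reports serialize with fixed
digits (canonical JSON), which keeps re-runs byte-identical without a
bespoke integer-cent currency type.

## Parameters

The base case (`crc_basecase()`) carries: FIT sensitivity/specificity
0.73/0.919 at the 20 µg/g cutoff; compliance 0.60 (FIT), 0.989 (primary
colonoscopy), 1.00 (post-positive colonoscopy); polypectomy rate 0.73;
incidence reductions 0.21/0.442/0.489 (FIT/colonoscopy/AI); quinquennial
incidence 55.9, 89.8, 137, 200, 253.2, 330.5 per 100,000 for ages 50–54
through 75+ (half-open bands, the sixth band covering post-screening ages);
stage distribution at diagnosis 11.3/25.4/32.4/31.0% — which sums to 100.1%
as published and is renormalized by its sum — and stage-specific annual
mortality 1/4.5/8.7/43%; the cost table above; and 3% discounting for a
100,000-person cohort aged 50–75 (screening) and 50–100 (follow-up). An
alternative scenario (`crc_basecase("programme_efficacy")`) uses the 51.5%
colonoscopy efficacy reported for a territory-wide programme instead of the
trial-derived 44.2%. Configurations are YAML overrides onto the base case
(`load_config()`), validated against the invariants in `validate_config()`;
a JSON schema and a value manifest ship under `inst/extdata/`.

## Verification strategy

Beyond unit tests against closed forms (geometric survival sums, discount
factors, the surveillance identity, the no-screening pool recursion
S(t+1) = S(t)(1−h)), the cohort recursion is cross-checked by an
independent seeded microsimulation (`microsim_oracle()`, also reachable as
`simulate()` on a fitted model) that pushes individuals through the
identical event sequence: the deterministic engine computes that process's
expectation, so summaries must agree within Monte-Carlo error. The shipped
acceptance tests require agreement within three standard errors at
n = 200,000 for the no-screening and FIT+AI scenarios on cases, discounted
life years lost, FITs and colonoscopies.

A second, engine-independent fixture (`reference_totals()`) carries
published per-strategy totals (cases, life years lost, total costs) from the
literature for exactly this programme design; the comparison arithmetic is
required to reproduce the published derived rows exactly where the source
table is internally consistent, and within 0.5–1% where the source's own
rounding of life years intervenes (its ICERs were computed from unrounded
life years that are not published; two of its prevented-case entries are
also internally off by one from its own case counts).

What passing these tests shows — and does not show. The qualitative
structure (FIT+AI cheapest per life year and dominant over FIT+conventional;
AI dominant over conventional in the direct arms; direct arms preventing
several-fold more cancers at several-fold higher cost; the sensitivity-
analysis directions) is reproduced from mechanism, not fitted. Absolute
case counts and life-year totals are *not* reproducible from the published
inputs alone — the published no-screening case count cannot be derived from
the printed incidence schedule under any standard person-year convention we
examined — so this package keeps honest conventions (full other-cause
attrition, cases accrued to the life-table horizon) and reports absolute
magnitudes as its own, larger, internally consistent numbers (e.g. ~6,400
baseline cases per 100,000 rather than the published 3,233, which resembles
an in-window count).

## Sensitivity analysis

`one_way_sweep()` and `two_way_sweep()` re-run the full comparison over
deterministic grids (no probabilistic analysis, matching the source
tradition); `find_threshold()` locates criterion sign changes by linear
interpolation. The shipped default grids (`default_sweeps()`): joint
compliance 0.10–1.00 in steps of 0.10 — initial, repeated and follow-up
compliance move together — FIT specificity 0.20–0.919 in eight steps, FIT
sensitivity 0.40–0.73, colonoscopy cost 0.5x–2x, and stage-care costs
0.5x–2x. Published figures for these analyses give directions, not grids,
so the grids are this package's own and configurable. Tested directions:
every strategy's ICER falls as compliance rises; FIT-arm ICERs rise as FIT
specificity falls (more false positives, more colonoscopies, no added
benefit); FIT+AI stays below FIT+conventional across the whole FIT-
sensitivity grid; colonoscopy cost moves the direct arms' ICERs faster than
the FIT arms'.

## Problem sizes and runtime

The deterministic engine tracks ~20 occupancy masses over 51 annual cycles,
so a five-strategy comparison runs in well under a second; the default test
suite uses the full 100,000-person base case everywhere, microsimulation
cross-checks at n = 200,000, and the full sweep grids above.

## Known limitations

* No adenoma natural history, sojourn times, or stage shift under
  screening; prevention is an incidence-reduction fraction.
* The FIT-arm efficacy bundle is not decomposed per sub-state; everyone in
  the arm shares one reduction while the programme runs.
* Single-sex, single-period synthetic life table.
* Lump-sum care costing ignores the timing of treatment within the disease
  course; published bleeding complication counts are internally inconsistent
  with the published 0.98% rate under any per-procedure basis, so the stated
  rate is implemented and the discrepancy simply noted.
* No QALYs, willingness-to-pay thresholds, or acceptability curves.
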