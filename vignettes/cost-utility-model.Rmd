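---
title: "A cost-utility model of genetic screening for neovascular AMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cost-utility model of genetic screening for neovascular AMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdcua)
```

## The model

The package evaluates whether genotyping the annual US cohort of 944,400
Category 3 AMD patients (macular drusen ≥125 µm) at age 65 for progression
risk to neovascular AMD (NVAMD) is worth its cost. The causal premise is
behavioural, not pharmacological: a known high-risk profile is assumed to
make patients present promptly at symptom onset, so that ranibizumab therapy
starts in the early acuity stratum (20/40–20/80) rather than the late one
(≤20/160). All of the model's value comes from shifting patients between
these two strata; direct ophthalmic treatment costs cancel because both
strata receive the same therapy.

The model is deterministic arithmetic on a registry of published inputs —
there is no estimation step — evaluated over a 12-year horizon (mean NVAMD
life expectancy) with 3 %/yr end-of-year discounting of both utilities and
dollars, in 2012 US real dollars. `amd_cua()` runs every stage and returns a
classed object with `print`, `summary`, `coef`, `predict`, `plot` and
`simulate` methods.

### Fellow-eye conversion

Patients typically present with NVAMD in one eye (53.6 % unilateral at
baseline). The fellow eye converts over time; cumulative incremental
conversion of the baseline-unilateral pool is observed for years 1–2 (21.2 %,
38.0 %) and extended to years 3–12 by a last-observation-carried-forward
hazard: the mean of the two observed incremental conversions, h = (21.2 +
16.8)/2 = 19.0 %/yr, applied to the unconverted remainder,

$$A_t = A_{t-1} + h\,(100 - A_{t-1}).$$

Bilateral involvement is then \(B = 46.4 + 0.535\,A\) (46.4 % bilateral at
baseline), reaching 82 % at year 5 and 96 % at year 12. We read "average
incidence" as the arithmetic mean of the two incremental percentages applied
as a constant hazard; this is the only reading that reproduces both the
year-3 (49.8) and year-12 (92.5) trajectory values exactly, while
intermediate years drift by ≤0.2 points from the published cells (our tests
allow ±0.3 there; whether slightly year-varying hazards were used originally
is unknowable). The unilateral-share multiplier is 0.535 as in the formula;
the prose's 53.6 % is available as a documented override
(`parameter_alternates()`).

### Value engine

Each treatment arm carries a 12-year discounted QALY accrual from the
combined-eye model: sham 5.990, early 7.924, late 6.561. These accruals are
authoritative inputs — the monthly acuity trajectory behind them
(trial data for 24 months, LOCF thereafter, a meta-analytic natural-course
curve for untreated eyes) is not fully specified, so
`accrual_consistency()` only cross-checks that the early accrual is within
0.05 QALY of the 0.789-utility annuity plus the 0.121 bilateral-good-vision
bonus minus the 0.045 adverse-event disutility, and no test gates on a
trajectory recomputation.

Incremental gains are accrual differences (early − late = 1.363 QALY per
treated patient), scaled to the screened cohort by the three-way product of
first-eye late-presentation fraction (0.780), second-eye late fraction
(0.622) and test sensitivity (0.90): 0.4366, giving 0.595 QALY per
early-treatment case. Percent quality-of-life gains divide by the sham
accrual (5.990): 14.1 % early, 4.2 % late. That rule reproduces three of the
four published pairings exactly; the unadjusted early figure (32.8 %) is off
by 0.5 points under any fixed rule, and we test it at ±0.6. The four-way
product including the combined-eye multiplier (0.857) is 37.4 %; the 0.853
variant printed elsewhere does not reproduce it and is stored as an
alternate. The per-screened dilution 0.595/30.3 = 0.0196 matches neither
circulated per-screened figure (0.0185, 0.0177); since the unrounded
screened-per-early-case ratio is unstated, `per_screened_gain()` flags its
result as approximate and nothing downstream consumes it.

### Cost engine

The genetic test is a nine-line CPT build-up at 2012 National Limitation
Amounts. The exact sum is \$1,459.60; the published total (\$1,461, from
per-line rounding) is what the registry carries, because the downstream
chain compounds exactly that figure. Compounding from screening (65) to mean
treatment age (75) uses **9** annual periods: 1461 × 1.03⁹ = \$1,906, which
is the figure the per-capita cost is built from (10 periods would give
\$1,963); the period count is a parameter. Adding the \$299 closer-monitoring
add-on (one extra annual exam + OCT, with the 22.5 % high-risk weighting
folded into the lump) gives \$2,205 per screened patient, and \$66,873 per
early-treatment case at 30.3 screened per early case (that ratio is carried
as a primary input; 30.3 × 2,205 = \$66,812 shows it is itself rounded).

Negative costs — depression, injuries, nursing home, skilled nursing,
other medical (−\$93,699 unadjusted), caregiver (−\$394,929) and employment
(−\$32,288) — are stored signed. The registered adjusted components are the
published ones (−\$40,914, −\$172,443, −\$14,098; societal total −\$227,455);
`cost_ledger(..., from_unadjusted = TRUE)` rebuilds them by scaling the
unadjusted column with the 0.4366 factor and agrees within \$20 (per-row
rounding in the source). The third-party perspective keeps only the direct
non-ophthalmic bucket. Net per early case: societal −\$160,582, third-party
+\$25,959. Savings nominally accrue from month 7 after therapy initiation;
at the model's annual resolution this does not change 12-year totals and is
carried as metadata.

### Cost-utility ratios and break-even

For uptake p % of the 161,754 annual 65-plus NVAMD cases (unrounded count
1,617.54 per 1 %), total cost is the fixed national screening outlay
(944,400 × \$2,205 = \$2.082 billion) minus n × per-patient negative cost,
and CUR = total / (n × 0.595). The per-patient inputs enter at printed
precision; the original tables were evidently built from slightly different
unrounded intermediates (e.g. the societal 1 % negative-cost cell differs by
\$12k in \$368M), so table-cell tests use 0.1 % relative tolerance and
break-even values are reported to one decimal. Break-even uptake solves
n = S / (c⁻ + T·ΔQ) in closed form; tests also confirm it as the `uniroot`
inverse of the table. Negative CUR denotes dominance (total cost crosses
zero at ≈5.66 % societal uptake). The payer ROI table recomputes every ROI
from its dollar cells; the out-of-pocket patient row is known to circulate
with an ROI ((6,765−40)/40 = 16,813 %) that differs from its published
headline, and we always report the recomputed value.

### Sensitivity scenarios

Scenarios are override bundles run through the full pipeline and evaluated
at the base-case break-even points (4.1 % societal, 10.1 % third-party).
Replacement test prices enter **uncompounded** — (500 + 299) × 944,400 and
(1000 + 299) × 944,400 reproduce the published scenario cost totals exactly,
and removing the extra exam (per-capita \$1,906) does too. Earlier screening
ages are parameterised as extra compounding periods because the published
age-60/52/40 totals imply ≈10.3 extra periods for a 5-year shift and cannot
be reconciled with any stated convention; likewise the four-extra-exam total
implies 5 × \$299. Those mechanisms are therefore implemented and tested for
monotonicity (higher price ⇒ higher CUR; more periods ⇒ higher CUR) but not
against the irreconcilable cells. The doubled-injection scenario adds the
per-early-case drug differential divided by 30.3 to the per-capita cost; the
registered bundle uses 22 extra injections at an inferred \$853 each, which
approximately matches the circulated scenario total.

## The microsimulation generator

`simulate_cohort(n, seed)` draws individual screened patients: genetic class
(P(high) = 0.225), progression from the joint distribution uniquely implied
by the margins P(progress) = 0.20 and P(high | progress) = 0.90 — i.e.
P(progress | high) = 0.80 and P(progress | not high) ≈ 0.026 — detection
(high-risk progressors), independent per-eye presentation strata (0.780,
0.622; independence is an assumption, consistent with the published both-eyes
product 48.5 %), and a fellow-eye conversion year sampled from the trajectory
increments with residual mass "never within horizon". A progressor is
shifted to early treatment when detected and both eyes would have presented
late; the realized gain is then the full 1.363 QALY and the realized cost
nets the full unadjusted negative total against \$66,873. Means over
progressors therefore converge to 0.595 QALY and −\$160,582 exactly in
expectation — the generator is an oracle for the deterministic chain, not an
independent data source. One RNG stream is drawn in fixed patient order
(bit-reproducibility); the caller's RNG state is restored.

What it does **not** emulate: individual mortality, AREDS-supplement
effects, treatment switching, correlated eye presentation, secular drug-price
trends, or any uncertainty in the registry inputs themselves. Passing
convergence tests shows internal consistency of the arithmetic, not external
validity of the published inputs.

Problem sizes: convergence tests use n = 200,000 (per-early-case standard
errors ≈0.003 QALY and ≈\$1,300, comfortably resolving the targets);
seed-calibration uses 20 seeds at n = 20,000 and checks the between-seed
scatter against the reported standard error (ratio within \[0.5, 2\]).

## Numerical conventions and edge cases

- Patient counts stay real-valued internally (1,617.54 per 1 %); rounding to
  whole patients happens only at report time.
- Whole-dollar rounding at the two places the published chain rounds
  (CPT total, compounded cost); everything else full precision.
- CUR is undefined at zero uptake (domain error), and `breakeven_uptake()`
  reports thresholds unattainable below 100 % uptake as `NA` with an
  `unattainable` attribute rather than extrapolating.
- Zero discount rate is an explicit branch of the annuity factor (the
  closed form 0/0 limit); rates below ~1e-9 are cancellation-limited.
- Configs are flat YAML; unknown keys are rejected (both in configs and in
  scenario overrides) so typos cannot silently keep a default.
- `run_full_analysis()` writes CSVs that are byte-identical across runs with
  identical parameters; timestamps live only in the JSON metadata. Currency
  is serialized in whole dollars, QALYs at 4 decimals.

## Known limitations

The model inherits every limitation of its inputs: the behavioural link from
genetic knowledge to earlier presentation is assumed, not observed; the
12-year arm accruals and cost columns are taken at their published values
rather than re-derived; the screened-per-early-case ratio (30.3) and several
dual-printed constants (\$66,873 vs \$66,180; 85.7 % vs 85.3 %; 0.535 vs
0.536) are internal inconsistencies of the source material that we resolve
in favour of the arithmetically reproducible variant and document via
`parameter_alternates()`. No probabilistic sensitivity analysis is provided
(none exists for this model); the scenario engine varies one mechanism at a
time.
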