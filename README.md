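# dtxcea

Decision-analytic cost-effectiveness models for **digital therapeutics
(DTx)** added to treatment-as-usual (TAU) in **type 2 diabetes (T2DM)** and
**hypertension (HTN)**, from a US commercial-payer perspective over a
3-year horizon. The package is aimed at health-economics analysts who want
a fully scripted, testable version of this class of Excel decision-tree
model: cohort engine, costing, QALYs, deterministic sensitivity analysis
and break-even threshold curves, plus an individual-level microsimulation
that validates the cohort engine.

## Model in brief

Patients occupy one of four biomarker categories (HbA1c `<6.5`,
`6.5–7.49`, `7.5–9.0`, `>9.0` % for T2DM; SBP `<120`, `120–129`,
`130–139`, `>=140` mm Hg for HTN). Two cohorts — DTx+TAU and TAU alone —
evolve annually for 3 years. For a category distribution `p(y)` in year
`y`, per-enrollee annual cost is

    C(y) = sum_k p_k(y) * [ base_med * slope_med(k) * (1 - f_unmed * 1{k=2})
                            + sum_c prev_c * base_c * slope_c(k)
                            + r_cvd(k) * cost_cvd ]

with `r_cvd(k)` a hazard-ratio-scaled reference rate (T2DM) or an
annualized Framingham general-CVD risk (HTN). Utilities per category
accrue QALYs. TAU persistence is 80%/year; DTx transitions come from
tables synthesized to the published year-1 effectiveness (62%/87%
improving ≥1 category; −0.8 % HbA1c / −11 mm Hg mean change). Program
attrition (20% month 3, +20% year-end, 10%/year after; 36% gone by end of
year 1) returns year-1 withdrawers to enrollment values and later
withdrawers to average TAU outcomes. Clinical-inertia delays (6 months
for medication reductions, 3 for CVD-risk reductions) gate year-1
benefits. Costs and QALYs discount at 3%/year and feed

    PPPM(y)   = [C_TAU(y) - C_DTX(y)] / 12        (per enrollee per month)
    breakeven(lambda) = dSavings + lambda * dQALY (max 3-year program cost)

Unpublished closing quantities (reference CVD rate, Framingham scale,
year-2/3 improvement fractions) are calibrated so the base case
reproduces the published savings trajectory; `vignette("dtxcea-methods")`
documents the calibration and its caveats.

## Worked example

```r
library(dtxcea)
run_model(default_parameters("T2DM"))
#> <dtx_run> T2DM model
#>   PPPM savings (discounted): y1 $83, y2 $174, y3 $178 (avg $145)
#>   3-year HRU savings: $5220/enrollee; incremental QALYs: 0.0577
#>   break-even program cost: $8104 at $50k/QALY, $10987 at $100k/QALY
```

Year-1 savings are smallest because deprescribing starts only at month 6
and CVD-risk reduction at month 3; the 3-year average of $145 per
participant per month is dominated by medication reductions. At a
willingness-to-pay of $50,000/QALY the program pays for itself up to a
total 3-year cost of ~$8,104 per enrollee. Other entry points:

```r
one_way_sa(default_parameters("HTN"), "pppm_y1")       # tornado table
scenario_run(default_parameters("T2DM"), "severity_34_only")
microsimulate(default_parameters("HTN"), 1e5, seed = 1) # oracle check
run_base_case("T2DM", out_dir = "reports")              # CSV/JSON reports
```

A command-line wrapper lives at `inst/scripts/run_model.R`
(`Rscript run_model.R run --disease t2dm --out reports/`).

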