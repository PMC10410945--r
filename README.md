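# ceamarkov

Markov cohort cost-effectiveness analysis for disease-modifying
therapies, built around a shipped four-state Alzheimer's disease
scenario comparing annual Aducanumab treatment with standard of care
(SoC, symptomatic drugs plus supportive care).

## The problem and the model

Health-technology assessors need to decide whether a new, expensive
therapy is worth paying for. The standard tool is a discrete-time Markov
cohort model: a closed cohort of patients is distributed over a small set
of health states (here mild, moderate and severe Alzheimer's disease,
plus absorbing death) and redistributed once per annual cycle by a
row-stochastic transition matrix `P`, so the occupancy row vector evolves
as

```
n(t+1) = n(t) P,     n(0) = (N, 0, 0, 0)
```

Each state carries an annual cost `c_s` (USD) and a utility weight
`u_s ∈ [0, 1]`; cycle `t` contributes `Σ_s n_s(t) c_s` and
`Σ_s n_s(t) u_s` (quality-adjusted life years, QALYs), optionally
discounted at rate `r`. A disease-modifying therapy is modelled as a
relative risk `RR ∈ (0, 1]` applied to the outgoing transitions of the
mild state (three published readings of that adjustment are implemented —
see `?treatment_effect`). Two arms are compared through the incremental
cost-effectiveness ratio

```
ICER = ΔC / ΔE   (USD per QALY gained)
```

judged against a willingness-to-pay threshold λ (here 3 × GDP per capita
= $28,617/QALY), or equivalently through the net monetary benefit
`NMB = λ·ΔE − ΔC`. Uncertainty is handled by one-way deterministic
sensitivity analysis (tornado diagram) and probabilistic sensitivity
analysis (PSA): beta distributions for utilities and transition
parameters, gamma for costs, parameterised by method of moments, with
results summarised on the cost-effectiveness plane and as a
cost-effectiveness acceptability curve (CEAC).

## Worked example

```r
library(ceamarkov)

scn <- alzheimer_scenario()          # shipped published inputs
res <- evaluate_scenario(scn)
tidy(res)
#> # A tibble: 2 × 7
#>   strategy   total_cost total_qaly delta_cost delta_effect    icer cost_effective
#>   <chr>           <dbl>      <dbl>      <dbl>        <dbl>   <dbl> <lgl>
#> 1 SoC            21034.       2.95        NA        NA         NA  NA
#> 2 Aducanumab    102976.       3.42     81941.        0.467 175527. FALSE
```

Per person over five years, standard of care costs about $21,034 and
yields 2.95 QALYs; Aducanumab costs about $102,976 for 3.42 QALYs. The
extra 0.47 QALYs come at $175,527 each — far above the $28,617/QALY
threshold, so Aducanumab is not cost-effective at its current price.

```r
cloud <- run_psa(scn, n_iterations = 1000, seed = 1)
glance(cloud)$prob_cost_effective
#> [1] 0
autoplot(ceac(cloud, scn$ceac_grid))   # acceptability appears only above ~$100k/QALY

one_way_dsa(scn)                       # tornado: drug price & mild utility dominate
run_pipeline(scn, "results/", seed = 1)  # CSV tables + JSON manifest
```

The PSA confirms the deterministic verdict: at $28,617/QALY, 0% of the
1000 Monte-Carlo draws are cost-effective, and one-way variation of any
single parameter (costs, utilities, transition probabilities, discount
rate 3–9%) never brings the ICER below the threshold.

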