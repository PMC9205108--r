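# fact8d

Utilities from cancer-specific quality-of-life data: an R implementation of
the FACT-8D valuation and scoring workflow.

## The problem

Cost-utility analysis needs health-state *utilities* (1 = full health,
0 = dead, negative = worse than dead), but the FACT-G — the most widely
used cancer quality-of-life questionnaire — only yields descriptive scores.
The FACT-8D closes that gap: it classifies health on eight dimensions
(pain, fatigue, nausea, sleep, work, support, sadness, worry), five
severity levels each, mapped from nine FACT-G items, and attaches a
*value set* of utility decrements `w_dl` elicited from the general
population, so that

```
U = 1 − Σ_d w_{d,l(d)}
```

converts any completed FACT-G into a QALY-scale utility. Value sets are
estimated from a discrete choice experiment (DCE): respondents repeatedly
choose between two health profiles, each paired with a survival duration
`t ∈ {1, 2, 5, 10}` years, and the choices are fitted with a conditional
logit whose systematic utility

```
V = α·t + Σ_{d,l} β_dl · x_dl · t
```

is parameterised so a zero-duration state has zero utility. Decrements are
marginal rates of substitution with duration, `w_dl = −β_dl / α`, and
monotonicity (worse levels never get smaller decrements) is imposed by
collapsing offending levels and refitting.

This package is for health-economics and outcomes researchers on either
side of that workflow:

* **scoring** FACT-G responses with the packaged Canadian value set (or any
  value set file), and
* **running the valuation pipeline** — design generation, cohort and choice
  simulation, representativeness checks, raked (IPF) survey weights,
  weighted conditional logit with cluster-robust errors, monotonicity
  constraining, MRS anchoring — end to end or stage by stage.

## Worked example: scoring

```r
library(fact8d)

cvs <- canadian_value_set()
resp <- c(GP1 = 1, GP2 = 0, GP4 = 2, GF1 = 3, GF5 = 4,
          GS2 = 4, GS3 = 2, GE1 = 1, GE6 = 1)
map_factg_to_state(resp)
#> FACT-8D health state (1 = best, 5 = worst)
#>    pain fatigue  nausea   sleep    work support sadness   worry
#>       3       2       1       1       2       1       2       2
score_factg(resp, cvs)
#> [1] 0.715
```

The respondent reports somewhat pain (GP4 = 2 → level 3, decrement 0.077),
a little fatigue (0.054), a little trouble working (GF1 = 3 reverse-scores
to level 2, 0.057), full support (GS2 = 4 is the better item → level 1),
a little sadness (0.000 — the Canadian set only charges sadness from level
3) and a little worry (0.097): `1 − 0.285 = 0.715`. Anchors: all-best
responses score exactly 1; the all-worst (PITS) state scores
`1 − 1.652 = −0.652`, i.e. worse than dead. `score_factg_file()` scores a
CSV of responses and reports unscorable rows.

```r
print(cvs)
#> FACT-8D value set: Canadian FACT-8D value set (Canada)
#>         L1     L2     L3     L4     L5
#> pain     0  0.000 -0.077 -0.187 -0.384
#> ...
#> monotone; PITS utility = -0.652
```

## Worked example: valuation pipeline

```r
cfg <- pipeline_config(seed = 1, out_dir = "run1")
b <- run_pipeline(cfg)   # ~4 s: 1,582 respondents x 16 sets, 3 models
b$representativeness     # language/education/health flagged at the 2-pt rule
b$constrained$fit$k      # parameters after monotonicity constraining
pits(b$value_set)        # PITS utility of the derived set
```

Every stage is also exported on its own (`generate_design()`,
`simulate_respondents()`, `simulate_choices()`, `rake()`, `fit_clogit()`,
`constrain()`, `derive_value_set()`), takes an explicit seed, and reads and
writes plain CSV/JSON, so externally collected choice data can be ingested
in place of the simulator (`pipeline_config(choices_file = ...,
profiles_file = ...)`).

See `vignette("fact8d-methods")` for the model, the simulator's assumptions,
and the numerical choices.

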