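# emibandit

Behavioral treatment for obesity works, but it is slow and
therapist-intensive. A mobile ecological momentary intervention (EMI) can
move the set-a-behavior / review-it cycle into daily life: each evening the
participant picks a few weight-loss behaviors for tomorrow (reduce snacking,
walk 30 minutes, ...), and the next evening records which were actually done.
`emibandit` implements the decision engine and analysis stack for such a
study: a per-user **Thompson-sampling multi-armed bandit** that orders the
behavior list so that easily achievable, low-effort items appear first, the
event-log data model for the daily cycle, a synthetic cohort simulator, and
the longitudinal statistics used to evaluate feasibility and the predictors
of daily behavior.

It is aimed at researchers building or evaluating just-in-time adaptive
interventions who want a testable, reproducible reference implementation of
the recommender and of the analysis pipeline — no app required.

## The model

Each behavior is an independent bandit arm. For an arm selected (and
subsequently reviewed) *N* times and executed *a* times, the completion
probability θ has the posterior density

p(θ | a, N) = θ^a (1 − θ)^(N − a) / ∫₀¹ θ^a (1 − θ)^(N − a) dθ,

i.e. Beta(a + 1, N − a + 1) under a uniform prior. Every evening the engine
draws one score θ̂ per arm from its posterior and sorts the catalog by score:
arms with little data keep wide posteriors and keep getting explored, while
arms with high observed completion rates rise to the top (exploitation).
Each participant has an independent model trained only on their own data.

Daily behavior counts are analyzed with a two-level linear mixed-effects
model: for participant *i* at time *j*,

- Level 1: Y*ij* = Π₀*i* + Π₁*i* · Depression*ij* + ε*ij*
- Level 2: Π₀*i* = γ₀₀ + ζ₀*i*,  Π₁*i* = γ₁₀ + γ₁₁ · Psychiatry*i* + ζ₁*i*

with depression scored on [0, 1] from a nine-item 0–100 visual-analog mood
scale, fit by maximum likelihood (`lme4`), with fixed effects and random
effects chosen by AIC. Pre/post clinical measures are compared with exact
Wilcoxon signed-rank tests.

## Worked example

```r
library(emibandit)

# simulate a 20-participant, 28-day cohort and check feasibility
log <- simulate_cohort(sim_params(seed = 1))
summarize_feasibility(log)
#> Feasibility over 20 users
#>   use rate: median 94.7% (range 89.3-100.0), mean 94.8% (SD 3.9)
#>   distinct behaviors performed: median 13 (range 10-19)
```

With the default ~5% skipped review days, simulated adherence lands in the
mid-90s — the feasibility range this class of intervention reports. The
event log flows into the analysis-ready table and the two-level model:

```r
tab <- build_analysis_table(log)   # 531 paired records
fit <- fit_lmm(tab, lmm_spec())
fit
#>                          term estimate    se ci_lower ci_upper  p_value
#>                   (Intercept)    1.878 0.138    1.607    2.149 4.45e-42
#>                    depression   -0.870 0.460   -1.772    0.032 5.87e-02
#>  depression:psych_comorbidity    0.005 0.316   -0.614    0.625 9.87e-01
#>   AIC 1615.1 | n_obs 531, n_groups 20
```

The negative depression coefficient recovers the direction of the
mechanism built into the simulator: days with worse depressive mood
produce fewer completed behaviors (with only ~3 selections per evening the
count-scale effect is modest, so a single simulated cohort sits near the
significance boundary). The bandit itself converges within a few weeks of reviews:

```r
ep <- run_bandit_episode(c(walk = 0.9, veg = 0.5, gym = 0.1),
                         n_rounds = 21, seed = 8)
ep$final_state
#> <bandit_state> user sim - 3 arms, draw 21
#>   walk                 N= 17 a= 17  E[theta]=0.947
#>   veg                  N=  3 a=  1  E[theta]=0.400
#>   gym                  N=  1 a=  0  E[theta]=0.333
```

After 21 evenings the achievable behavior dominates the top of the screen,
while the rarely-tried arms keep wide posteriors (note `gym` still sampling
a score of 0.82 on one draw — that is the exploration half of Thompson
sampling at work). Pre/post comparisons use the exact signed-rank test:

```r
wilcoxon_signed_rank(pre = c(34.9, 30.1, 41.2, 28.0, 52.9, 27.4),
                     post = c(34.1, 29.5, 40.0, 28.4, 51.0, 26.7))
#> Wilcoxon signed rank (exact)
#>   W+ = 1  n_effective = 6  p = 0.0625
```

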