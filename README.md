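# pemem

Model-based analysis of how **prediction error (PE) at encoding relates to
episodic recognition memory**, for researchers in computational cognitive
(neuro)science who work with probabilistic contingency-learning tasks.

In the task family this package implements, participants first learn that
scene contexts predict object categories with graded reliabilities
(e.g. 0.80–0.10–0.10, or uniform).  During a subsequent encoding phase
they keep predicting the category of trial-unique objects; a surprise
recognition test then probes memory for exactly those objects.  The
package covers the full analysis chain:

- **Task simulation** — counterbalanced learning/encoding schedules for
  both experiment designs (three categories with 0.80/0.33 contingencies;
  two categories with 0.90/0.70/0.50), filler-object rules that realize
  the contingencies, softmax reinforcement-learning agents, and a
  generative logistic memory model, all reproducible from one master seed.
- **Learning models** — four delta-rule models of the context→category
  expected values $Q^{j,c}$ (initialized at $1/J$), sharing the update
  $Q_{t+1} = Q_t + \lambda_t (r_t - Q_t)$ with one-hot feedback $r_t$ and
  differing in the effective learning rate and feedback type:
  `dLRI` ($\lambda = 1/t$, instructive), `dfLRI` ($\alpha/t$), `fLRI`
  ($\alpha$), and `fLRE` ($\alpha$, evaluative: only the chosen category
  updates, towards its correctness).  Action selection is softmax,
  $P^j \propto e^{\beta Q^j}$.
- **Fitting & comparison** — per-subject maximum likelihood (bounded,
  5 random restarts; $\alpha \in [0,1]$, $\beta \in [0,10]$), BIC
  ($-2\widehat{LL} + k \ln T$) with evidence bands on the best-vs-second
  margin (weak < 2 ≤ positive < 6 ≤ strong < 10 ≤ very strong), plus
  parameter-recovery and model-recovery (confusion matrix) diagnostics.
- **Memory analysis** — unsigned PE $= 1 - Q[\text{presented}]$ per
  encoding item, d′ scoring with permutation-based exclusion of at-chance
  responders, and mixed-effects logistic models
  $p(\mathrm{hit}) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 \mathrm{PE} +
  \beta_2 \mathrm{PO} + \beta_3\, \mathrm{PE}{\cdot}\mathrm{PO})$ with
  by-subject random intercepts and slopes (unstructured covariance),
  simple slopes by prediction outcome, binned-PE and signed-PE
  follow-ups.

See `vignettes/prediction-error-memory.Rmd` for the models, assumptions,
and every numerical choice.

## Worked example

Simulate a small two-category study, fit all four learning models, compare
them, derive trial-level PE at the best-fitting parameters, and test the
PE × prediction-outcome memory effect:

```r
library(pemem)

design <- build_design("EXP2")
study  <- make_synthetic_study(8, design, seed = 42)
study
#> <synthetic_study> EXP2 - 8 subjects, 4560 trials, 1440 recognition records

fits       <- fit_study(study$trials, seed = 1)
compare_models(fits)
#> <model_comparison> over 8 subjects
#> # A tibble: 4 x 5
#>   model mean_bic se_bic n_best n_very_strong
#>   <chr>    <dbl>  <dbl>  <int>         <int>
#> 1 dLRI      699.   39.6      3             0
#> 2 dfLRI     705.   39.6      0             0
#> 3 fLRI      581.  102.       4             3
#> 4 fLRE      638.   71.2      1             0

trajectories <- derive_pe(study$trials, fits, model = "fLRI")
tab <- build_analysis_table(trajectories, study$recognition, fits)
fit <- fit_mixed_logistic(tab, "basic")
fit$fixed[, c("term", "estimate", "se", "z", "p", "odds_ratio")]
#>   term        estimate    se      z      p odds_ratio
#> 1 (Intercept)   0.138  0.165  0.833 0.405       1.15
#> 2 pe           -0.0570 0.243 -0.234 0.815       0.945
#> 3 po            0.653  0.375  1.74  0.0816      1.92
#> 4 pe:po         1.30   0.555  2.34  0.0191      3.68

ss <- simple_slopes(tab)
cat(sprintf("correct-prediction PE slope:   beta = %.2f, OR = %.2f\n",
            ss$correct$fixed$estimate[2], ss$correct$fixed$odds_ratio[2]),
    sprintf("incorrect-prediction PE slope: beta = %.2f, OR = %.2f\n",
            ss$incorrect$fixed$estimate[2], ss$incorrect$fixed$odds_ratio[2]))
#> correct-prediction PE slope:   beta = 0.56, OR = 1.75
#> incorrect-prediction PE slope: beta = -0.75, OR = 0.47
```

Reading the output: the fLRI model (free constant learning rate,
instructive feedback) fits most simulated subjects best; in the memory
model the PE main effect is null but the PE × prediction-outcome
interaction is positive and significant — higher PE predicts *better*
recognition after correct predictions (OR > 1) and *worse* recognition
after incorrect ones (OR < 1), which is exactly the effect structure the
synthetic study generates.

For a file-based workflow, `run_pipeline(study_config(...))` executes
simulate → fit → compare → derive-PE → analyze and writes every table as
CSV plus a JSON manifest whose digests make the run reproducible;
`read_trial_table()` adapts externally collected data to the canonical
schema via a column mapping.

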