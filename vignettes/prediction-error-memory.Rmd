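---
title: "Model-based analysis of prediction error and episodic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based analysis of prediction error and episodic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemem)
```

## The problem

In probabilistic contingency-learning tasks, people learn that a context
(say, a beach scene) predicts an object category (say, musical instruments)
with some reliability.  Once expectations are established, every new object
presentation generates a *prediction error* (PE): large when the presented
category was unexpected, small when it was anticipated.  `pemem` implements
a complete model-based pipeline for asking how that trial-level PE at
encoding relates to later episodic recognition of the very objects that
triggered it — and in particular whether the relation depends on the
*outcome* of the prediction (was the participant's category guess correct
or not?).

The pipeline has four stages, each usable on its own:

1. **Task simulation** — counterbalanced trial schedules for two
   experiment designs, softmax reinforcement-learning agents, and a
   generative logistic memory model, so that every downstream stage can be
   validated end-to-end on synthetic data with known ground truth.
2. **Learning models** — four delta-rule value-learning models with
   softmax action selection, producing per-trial expected values, choice
   probabilities, and unsigned/signed PE.
3. **Model fitting** — per-subject maximum-likelihood estimation, BIC
   model comparison with evidence grading, and parameter/model-recovery
   diagnostics.
4. **Memory analysis** — d'-based recognition scoring with
   permutation-based at-chance exclusion, and mixed-effects logistic
   models linking item-level PE and prediction outcome to recognition
   success.

## The task designs

Both designs use six scene contexts.  Experiment 1 (three object
categories) pairs three contexts with 0.80–0.10–0.10 contingencies and
three with uniform 0.33 contingencies.  Experiment 2 (two categories) uses
0.90–0.10, 0.70–0.30 and 0.50–0.50 contingencies, two contexts each.
Which category is dominant in which context rotates deterministically
across participants (a Latin-square rotation), so that over a full cycle
every category is dominant equally often in every condition.

During the encoding phase each context shows a fixed set of unique,
never-repeated objects — the items later probed in the recognition test —
plus *filler* objects repeated several times so that the category
proportions realize the nominal contingency without inflating the number
of unique items.  In the 0.80-contexts of Experiment 1, for instance, 24
unique objects (8 per category) are mixed with 8 dominant-category fillers
shown 7 times each: 64 of 80 presentations (80%) are dominant.  This
yields 312 encoding trials (144 unique objects) in Experiment 1 and 330
(100 unique objects) in Experiment 2.  The recognition test probes every
unique object plus 144 (Experiment 1) or 80 (Experiment 2) new
distractors; in Experiment 1 a random half (72) of the old items carries
the immediate-test flag and enters the analysis.

Two integer-allocation details are worth noting.  Category counts per
context are apportioned by largest remainder, so a 10-trial 0.80-context
realizes 8/1/1 exactly.  The 0.70–0.30 condition cannot be realized
exactly in 35 trials (0.7 × 35 = 24.5); the schedule allocates 25/10
(71.4%/28.6%) and records the realized proportions in the schedule's
`realized_contingency` attribute.

The learning phase length is configurable and defaults to 40 trials per
context — a value chosen once as a realistic pre-training length for this
kind of design; the package does not treat it as empirically fixed.
Trial order is an unconstrained uniform permutation over all contexts
pooled (no run-length constraints), and the per-context trial counter `t`
that drives decreasing learning rates continues across the
learning/encoding boundary, because the models treat both phases as one
continuing experience.

## The learning models

All four models maintain a categories-by-contexts matrix of expected
values $Q^{j,c}$, initialized at $1/J$ (exactly $1/3$ with three
categories, $0.5$ with two), and share the delta-rule update

$$Q_{t+1}^{j,c} = Q_t^{j,c} + \lambda_t\,\delta_t^{j,c}, \qquad
  \delta_t^{j,c} = r_t^j - Q_t^{j,c},$$

where $r^j_t$ is the one-hot feedback vector of the presented category.
They differ in the effective rate $\lambda_t$ and in what feedback they
use:

| model | $\lambda_t$ | feedback | free parameters |
|-------|-------------|----------|-----------------|
| dLRI  | $1/t$       | instructive | $\beta$ |
| dfLRI | $\alpha/t$  | instructive | $\alpha, \beta$ |
| fLRI  | $\alpha$    | instructive | $\alpha, \beta$ |
| fLRE  | $\alpha$    | evaluative  | $\alpha, \beta$ |

Instructive models update *all* categories of the current context from the
presented category, regardless of the choice; the evaluative model updates
only the chosen category, towards 1 after a correct and towards 0 after an
incorrect prediction.  The evaluative update rule as usually written
conditions on the choice matching the presented category, which is
internally inconsistent with values decreasing after errors; this package
resolves it as "the chosen entry moves towards the correctness outcome",
the only reading under which incorrect predictions lower the chosen
value.

The dLRI's $1/t$ rate makes its values exactly the running empirical
presentation frequencies per context — the delta-rule form of the optimal
running-mean (Bayesian) learner.  This equivalence is enforced as an exact
oracle test, as is the reduction dfLRI $\to$ dLRI at $\alpha = 1$.

Choices follow a softmax over the current context's values,
$P^j \propto \exp(\beta Q^j)$, computed with a max-shift so it is
overflow-safe and invariant to adding a constant to all values;
$\beta = 0$ is handled as exactly uniform.

Two PE variants are emitted per trial, both evaluated on the *pre-update*
values: unsigned PE $= 1 - Q[\text{presented}]$ (how unexpected the
presented category was) and signed PE $= r - Q[\text{chosen}]$ with
$r \in \{0, 1\}$ the correctness of the choice (positive after correct,
negative after incorrect predictions).

## Fitting and model comparison

Per subject, parameters maximize the likelihood of the observed choices
over learning and encoding pooled — filler trials included, since they are
modelled trials like any other.  The objective is minimized with bounded
L-BFGS-B from 5 random starts drawn from the same priors used for
simulation ($\alpha \sim U(0,1)$, $\beta \sim \mathrm{Exp}(1)$ truncated
to the fitting bound of 10 by resampling); the best restart wins.  Choice
probabilities are floored at $10^{-12}$ inside the log so the objective
stays finite at extreme parameters.  The likelihood core is compiled
(Rcpp) and cross-checked in the test suite against a plain-R replay and an
independent hand recursion on small instances.

Model comparison uses $\mathrm{BIC} = -2\widehat{LL} + k\ln T$ (natural
log; $T$ = number of modelled trials) and grades the margin between the
best and second-best model per subject: weak $< 2$, positive $[2, 6)$,
strong $[6, 10)$, very strong $\geq 10$ (boundaries assigned to the
higher band).  Exact BIC ties are broken in favour of fewer parameters,
then canonical model order.

Recovery diagnostics simulate agents with known parameters on the
*learnable* (non-uniform) conditions only — uniform contexts carry no
information about learning — then refit.  Parameter recovery reports
true/fitted correlations; model recovery tabulates a 4×4 confusion matrix
of generating versus BIC-best model.  A caveat worth knowing: under the
$\mathrm{Exp}(1)$ prior roughly half of the simulated agents have
$\beta < 0.7$ and choose near-randomly, so every model fits their data
about equally and the 1-parameter dLRI wins on the BIC penalty.  The
same agents blur parameter recovery: the learning rate of a near-random
chooser is unidentifiable, so the pooled true/fitted $\alpha$
correlation depends on how many such agents a seed draws, while among
informative agents ($\beta > 1$) it sits around 0.9 or higher.
Identifiability of the 2-parameter models therefore concentrates in the
informative-$\beta$ regime, and the dfLRI is intrinsically hard to
separate from dLRI at these trial counts (its $\alpha/t$ rate differs
from $1/t$ only early in learning, a likelihood difference usually
smaller than the BIC penalty $\tfrac{1}{2}\ln T \approx 2.9$ nats).  The
package reports the matrix as measured rather than conditioning the prior
to make the diagonal dominate.

## The subsequent-memory model

Recognition is scored per subject as hits, misses, false alarms and
correct rejections; $d' = z(\mathrm{HR}) - z(\mathrm{FAR})$ with the
log-linear correction (0.5 added to every cell) so extreme rates stay
finite.  At-chance responders are excluded by a per-subject permutation
test: the response vector is permuted against the old/new labels (5000
permutations by default) and the subject is kept only if the observed
$d'$ reaches the null distribution's 95th percentile.  The comparison is
implemented through the *mid-p* permutation p-value (half weight on null
values tied with the observed one): for a continuous null this is the
plain percentile rule, but the permutation null of binary responses is
discrete, and the plain rule is conservative (measured ≈2.4% inclusion of
true at-chance responders instead of the nominal 5%), while mid-p stays
at the nominal level and still excludes degenerate responders who give
the same answer to every item (their null collapses onto their observed
$d'$, so mid-p is 0.5).

The item-level analysis table joins each unique encoding object's
unsigned PE (from replaying the best-fitting fLRI model over the
subject's choices) and prediction outcome (PO, contrast-coded +0.5
correct / −0.5 incorrect) to its later hit/miss.  Fillers never enter;
Experiment-1 rows are restricted to the immediate-test subsample; the
subject's fitted learning rate enters as a (deliberately uncentered)
between-subject covariate, and experiment is coded +0.5/−0.5.

The memory model is a mixed-effects logistic regression,

$$p(\mathrm{hit})_{i,j} = \mathrm{logit}^{-1}\!\big(\beta_{0,j}
  + \beta_{1,j}\,\mathrm{PE} + \beta_{2,j}\,\mathrm{PO}
  + \beta_{3,j}\,\mathrm{PE}\!\cdot\!\mathrm{PO}\big),$$

with by-subject random intercepts and random slopes for PE, PO and their
interaction under an unstructured covariance — the maximal structure the
design justifies; between-subject covariates (learning rate, experiment)
enter as fixed effects only, and supplying them as random slopes is
rejected with an error.  The `"full"` preset crosses PE × PO with
learning rate and experiment up to the four-way interaction.  Estimation
is Laplace-approximated maximum likelihood via `lme4::glmer`; the
`nloptwrap` optimizer without the post-fit derivative check is used for
speed after verifying it reproduces default estimates to four decimals.
Each coefficient is reported with a Wald $z$ (and $\chi^2 = z^2$, 1 df),
a 95% Wald CI, and an odds ratio $e^\beta$.

Follow-ups: *simple slopes* refit the PE effect separately in the
correct- and incorrect-prediction subsets (random intercept + PE slope);
the *binned* analysis aggregates hit rate within subject × PE-quartile ×
outcome, fits a linear mixed model, and Bonferroni-corrects all pairwise
bin contrasts ($p \cdot k$, capped at 1); the *signed-PE* variant swaps
the predictor for the signed PE.

## What the synthetic data do and do not show

The generator's memory stage draws hits from the logistic model above
with generative coefficients defaulting to a strong positive PE × PO
interaction (1.87) and weak main effects, subject-level random effects
with SDs (0.55, 0.17, 0.03, 0.18) drawn independently, and a constant
0.3 false-alarm rate for distractors (which puts synthetic $d'$ near
0.9).  Agents' parameters are drawn from the fitting priors.  Every
stream derives from one master seed with fixed per-subject offsets, so
adding subjects never perturbs existing ones.

Synthetic data are the package's ground-truth testbed: passing tests show
that the pipeline recovers what the generative model put in — schedules
realize their contingencies exactly, fitted parameters and the generating
model are identifiable in the informative regime, and the mixed model
recovers its coefficients with near-nominal CI coverage.  They do *not*
show that real participants obey these models: real data bring
serial dependencies, attention lapses, response-time structure and
item-memorability differences that the generator deliberately omits.
Conclusions about real data rest on fitting it, not on these simulations.

Problem sizes used in the shipped checks were chosen as the smallest that
exercise each property cleanly: recovery with 50 agents and 25
repetitions per generating model, memory-model recovery with 60 subjects
× 150 items over 50 replicates, exclusion calibration with 500 null
responders at 1000 permutations, and a full two-experiment pipeline at
the study's own sample sizes (32 + 40 subjects).

## Numerical choices, in one place

- Softmax: max-shifted; $\beta = 0$ exactly uniform.
- Initialization: exact $1/J$, never a rounded literal.
- Probability floor inside log-likelihoods: $10^{-12}$, constant.
- Integer apportionment: largest remainder; ties by first index.
- BIC: natural log; $T$ counts all modelled trials (fillers included).
- Evidence-band boundaries to the higher band; BIC ties to fewer
  parameters, then canonical order.
- d' correction: log-linear (+0.5 per cell).
- Exclusion: per-subject null, mid-p comparison at the 95th percentile.
- Wald inference throughout the logistic models; no df corrections.
- Seeds: one master seed, per-subject/stage streams by a fixed integer
  recurrence kept below $2^{31}$.

## Known limitations

The package does not model response times, the delayed recognition
session, recollection/familiarity decomposition, or changing
contingencies; the evaluative model's update rule is an interpretation
(see above); and mixed-model p-values are asymptotic Wald, which can be
anticonservative for very small subject counts.
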