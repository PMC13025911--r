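---
title: "Predicting post-ICU deterioration from irregular clinical time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting post-ICU deterioration from irregular clinical time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posticu)
library(dplyr)
```

## The problem

Discharging a patient from the ICU to a general ward is a bet that the
patient will keep improving without intensive monitoring. When the bet is
lost — an unplanned return to the ICU or death within seven days of the
transfer — the outcome is substantially worse than for comparable patients
who stayed. `posticu` implements a discharge-time risk model for this
composite endpoint ("discharge failure") from routinely charted clinical
data, together with the clinical comparator score used in practice (SWIFT)
and the full evaluation protocol: cohort selection, endpoint labeling,
stratified cross-validation, paired AUROC comparison, cross-site
fine-tuning curves and Shapley attribution.

The defining obstacle is missing data. Ward-style daily charting leaves
30-60% of lab values unmeasured on any given day, not at random: sicker
patients are measured more. Classical pipelines forward-fill and mean-fill
before modeling; the models implemented here instead treat the observation
pattern itself as input.

## The model

Each stay is a daily grid of `D` channels: values `X` (T x D), an
observation mask `M` (1 = measured that day), and a staleness matrix
`Delta` whose entry is the number of days since the channel was last
observed (`Delta[1, ] = 0`; thereafter 1 if observed yesterday, else the
previous entry plus one). The recurrent cell is a GRU with two learned
exponential-decay gates driven by staleness:

* an **input decay** `gamma_x = exp(-max(0, w_x * delta + b_x))`, per
  channel (diagonal), which imputes a missing value as
  `gamma_x * x_last + (1 - gamma_x) * xbar`: a freshly stale value stays
  near its last observation, an old one relaxes to the channel's global
  mean `xbar` (0 after standardization);
* a **hidden decay** `gamma_h = exp(-max(0, W_h' delta + b_h))`, full-rank
  to the hidden size, which shrinks the hidden state before each step.

The mask vector enters all three gates as an extra input, so the *fact* of
measurement is informative independently of the value. With everything
observed and both decays at 1 the cell is exactly a plain GRU — a reduction
the tests pin to 1e-10.

Three variants are exposed:

| variant | missing values | no-history channels |
|---|---|---|
| `gru` | consumes forward/mean-filled values only | n/a |
| `grud` | decay imputation | fall back to the global mean |
| `grudpp` | decay imputation | trainable per-channel default `x0` |

`grudpp` addresses the classical decay cell's assumption that every channel
is observed at the first time step. In real ICU data several labs are
structurally unavailable on day one (results return the next morning).
Where no prior observation exists, the trainable default `x0[d]` stands in
for the last observation and is blended by the same decay gate, with
staleness counted from the start of the stay; `x0` is learned end-to-end
with everything else. The exact functional form of this extension was an
open design point; it sits behind the `variant` interface so an alternative
rule can be swapped in without touching the training loop.

The readout maps the final hidden state, concatenated with the static
covariates (standardized age, sex), to a logit. Applying the same readout
to every prefix hidden state yields per-day risk trajectories: the day-`t`
prediction provably uses only bins up to `t` (tested bitwise), so the model
can be queried at any point of the stay.

## Training

Binary cross-entropy on the discharge-day logit, Adam (learning rate 1e-3,
minibatch 64), at most 500 epochs, early stopping when the validation loss
has not set a new minimum for 20 consecutive epochs, with 10% of the
training stays (stratified) reserved for model selection; the returned
parameters are those of the best-validation epoch, and the warm-start state
itself is a selection candidate so fine-tuning can never return something
worse than its starting point by its own selection criterion. Forward and
backward passes are compiled (RcppArmadillo) with hand-derived
backpropagation through the decay gates; the analytic gradients are checked
against central finite differences at relative 1e-4 in the test suite.

Three further training choices matter at cohort sizes of a few thousand
stays and are this package's own: (i) L2 weight decay 0.03 on the dense
gate and readout weights — without it the 32-unit cell overfits in a
handful of epochs and validation-loss selection picks nearly untrained
models. Biases, the decay-gate parameters and `x0` are exempt: penalizing
the decay weights toward zero pins both gates open and silently erases the
imputation mechanism (we observed exactly this: under uniform L2 the decay
variants became indistinguishable from the fill-based GRU). (ii) The output
bias starts at the log-odds of the training prevalence, so early epochs
learn ranking rather than recalibrating a 7%-positive base rate. (iii) The
step size halves when the validation loss plateaus. Input-decay weights
initialize in U(0.5, 1): a day-old missing value starts about halfway
relaxed to the channel mean, so staleness is informative from the first
gradient step.

## The synthetic cohort generator

No shareable ICU dataset exists at this package's scale (the real cohorts
behind this class of model are credentialed or private), so the generator
is a first-class module, and its defaults define the study conditions used
throughout the tests:

* **Latent severity** follows a per-day AR(1), `s_t = 0.7 s_{t-1} + e_t`,
  with unit stationary variance — the simplest process with the
  longitudinal autocorrelation the recurrent model is meant to exploit.
* **Channels**: 24 monitored channels (6 binary treatments such as
  ventilation and vasopressors, 6 physiologic parameters including urine
  output, 9 labs, consciousness (GCS) and sedation (SAS) scores, plus
  lactate), each a linear readout of severity with channel-specific
  loading and noise on scales taken from published ICU baseline tables.
  With age, sex and length of stay this gives the canonical 26-feature
  set after variable selection. Treatments are threshold exceedances of
  severity and are never missing, mirroring how order records behave.
* **Missingness**: per-channel daily missing rates span 0-0.6 (~40%
  averaged over the monitored numeric channels; vitals low, labs high).
  Two labs (WBC, BUN) and lactate are missing-not-at-random: the
  observation probability rises with the standardized value, with the
  intercept solved from the logistic-normal integral so the marginal rate
  still matches the configured one. Three labs are structurally
  unobserved on day one, exercising the no-history path; lactate is
  configured at 60% missingness so the <50% variable filter always drops
  exactly one planted channel.
* **Outcome**: discharge failure is Bernoulli with logit
  `-3.4248 + 1.5 * s_T` at the discharge day; the intercept solves the
  logistic-normal integral for 7% prevalence. The implied latent-truth
  AUROC ("oracle") is about 0.83.
* **Planted special cases** (exact counts, assigned not sampled): age
  under 18 (1%), stays under 24 h (2.5%), in-ICU death (3%), transfer to
  a specialized unit or operating room (2%), and planned surgical
  readmissions (4%) emitted as a flagged second interval that the merge
  rule must absorb into one continuous stay.
* **Site shift** (for transfer experiments): channel means move, missing
  rates rise, and — the part renormalization cannot undo — the severity
  loadings are re-weighted so that strong channels weaken and weak ones
  strengthen. Warm-started fine-tuning must absorb this concept drift;
  its learning curve rises monotonically with the training fraction.

What the generator does *not* emulate: real pharmacology and physiology,
unit mixtures across hospitals, sub-daily dynamics, artifact outliers, or
documentation idiosyncrasies. Passing tests therefore demonstrate that the
machinery recovers planted structure under honest missingness — not
clinical validity on real cohorts, which requires credentialed data.

A deliberate consequence of the chosen channel noise levels: the exact
Bayes posterior computed with the true generator parameters scores about
0.03 below the latent-truth oracle, so a trained model closing to within
0.05 of the oracle is operating near the information ceiling of the data,
not merely near other models.

## Cohort rules and preprocessing

Selection keeps adult stays (>= 18 years) of at least 24 h that ended
alive with discharge to a general ward; removals are audited by first
matching reason and the audit partitions exactly. Planned readmissions are
merged before selection so the length-of-stay filter sees the continuous
stay. The endpoint window is closed on the right at exactly 7 x 24 h.

Day bins are 24 h windows anchored at ICU admission (the number of bins is
then deterministic from the length of stay); numeric channels average
their in-bin measurements, treatment channels are any-event indicators. A
bin is missing only when it contains no measurement — the alternative
reading (a day with *any* missing measurement counts as missing) would
discard the partial information daily averaging is meant to retain, and is
not used. Normalization is z-scoring with the population (divide-by-n)
variance convention — either convention is statistically equivalent here,
but one must be fixed for bit-exact tests — fitted on training folds only;
a `normalized` flag makes re-application an error, and fold statistics are
provably invariant to the content of the held-out fold. Consciousness and
sedation scores are treated as numeric channels like the published
baseline tables do. Age and sex enter as static covariates at the readout
rather than per time step; length of stay enters the snapshot features
and the SWIFT inputs as cumulative days.

## SWIFT

The comparator score sums five components at discharge: admission source,
ICU length of stay, last GCS, most recent PaO2/FiO2 and PaCO2. The point
table ships as versioned JSON transcribed from the original 2008
derivation (maximum 64 points); this study class names the components but
prints no cut-points, so the table is configuration, not code. Missing
components score the lowest-risk bin rather than excluding the stay. When
no arterial gas exists, the SpO2/FiO2 ratio substitutes untransformed,
with its own bin set at cut-points mapped from the PaO2/FiO2 cuts by the
standard linear pulse-oximetry conversion; with no inspired-oxygen record,
room air (0.21) is assumed. Every substitution is recorded in a
provenance flag.

## Evaluation choices

* AUROC is the tie-aware pairwise probability (midranks); AUPR is
  step-wise average precision over unique thresholds. Both are pinned to
  brute-force O(n^2) oracles in the tests.
* Cross-validation is stay-level and stratified (at 7% prevalence,
  unstratified 10-fold splits risk positive-free test folds); each fold
  refits the variable filter and normalization.
* The DeLong comparison uses midrank placement components; its variance
  components match the direct-definition quadratic-time computation to
  1e-10, and its type-I error is verified within [0.035, 0.065] at
  alpha = 0.05 under a correlated null.
* The operating threshold maximizes Youden's J over midpoints between
  adjacent distinct scores, ties broken toward higher specificity.
* Two external-cohort modes are supported and named in every report:
  `zero-shot` (a frozen model scored on the new site) and `internal-cv`
  (site-internal cross-validation), since the two answer different
  questions.

## Shapley attribution

Channel-level attributions of the discharge logit, matching the
26-feature displays this model family reports: masking a player replaces
its whole series (or static value) with the reference stay's, and values
are estimated by antithetic permutation sampling — which makes the
efficiency identity exact by telescoping, not just in expectation. The
default reference is the all-global-mean stay with statics at cohort
means; an `all-missing` reference probes the model's own imputation path
instead. The estimator is the package's normative definition (the model
family's papers rarely state which approximation they used); an exact
2^D enumeration oracle validates it at small dimension, along with the
null-player and symmetry axioms. Day-resolved attribution is out of
scope.

## Problem sizes used in the checks

The bundled tests run the full pipeline at n = 2000 generated stays
(~1830 after exclusions, ~7% positive), 10 training seeds for the
multi-seed comparisons, 5 fine-tuning fractions on a site of n = 1500,
and 2000 replicates for the DeLong null; metric oracles run on hundreds
of random fixtures. These sizes make the whole suite complete in well
under half an hour on one core while keeping Monte-Carlo error far
below every asserted tolerance.

## Known limitations

* The generator's linear-Gaussian readouts make forward filling a strong
  imputation baseline; the decay models' margin over it is accordingly
  small here (fractions of a point of AUROC), unlike on real EHR data
  where the reported gaps are larger.
* Channel-level (not day-level) attribution; no calibration layer; no
  hyperparameter search beyond the fixed configuration; no GPU path.
* The CLI covers the simulate / swift / train / predict / evaluate
  chain; programmatic use is the primary interface.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cohort <- generate_cohort(sim_config(n_stays = 2000, seed = 1))
sel <- select_cohort(merge_planned_readmissions(cohort))
tens <- daily_aggregate(sel$cohort)

report <- kfold_cv(tens, model_grud("grudpp"), k = 10, seed = 1)
glance(report)

swift <- swift_auroc(sel$cohort)
paired <- dplyr::inner_join(attr(report, "scores"), attr(swift, "scores"),
                            by = "stay_id", suffix = c("_m", "_s"))
delong_test(paired$score_m, paired$score_s, paired$label_m)
```
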