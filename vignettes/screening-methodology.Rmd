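---
title: "Screening indoor air quality with surrogate pollutants: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening indoor air quality with surrogate pollutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaqscreen)
```

## The screening problem

A full indoor air quality (IAQ) assessment of an air-conditioned office
measures nine pollutants over 8 hours — CO2, CO, respirable suspended
particulates (RSP), NO2, O3, formaldehyde, total volatile organic compounds
(TVOC), radon and airborne bacteria — and declares the office
*satisfactory* only if every level is at or below its exposure limit. That
is expensive. Screening replaces it with three cheap, continuously
monitorable surrogates — CO2 (occupant load and ventilation), RSP
(filtration performance) and TVOC (building and activity emissions) — and a
single statistic, the IAQ index

$$\theta = \frac{1}{3}\sum_{j=1}^{3} \Phi_j^{*}, \qquad
  \Phi_j^{*} = \frac{\Phi_j}{\Phi_{j,e}},$$

the mean *fractional dose*: each surrogate's level over its reference
exposure limit. The reference limits are fixed at the older Hong Kong
objective ("Scheme 1": CO2 1000 ppm, RSP 180 µg/m³, TVOC 600 µg/m³) for
*both* schemes' analyses, so index values stay comparable when the
assessment standard changes; `iaq_index()` exposes this as a default that
can be overridden but rarely should be.

Because an office can fail on a pollutant the surrogates do not see, a
surrogate screen is inherently imperfect; the point of the methodology is
to quantify that imperfection as per-bin *likelihood ratios* (LR): the
probability of observing an index bin among unsatisfactory offices over
that among satisfactory ones. With a pre-test probability (e.g. a regional
failure rate), `post_test_probability()` converts an observed bin into a
post-test probability of unsatisfactory IAQ by plain odds multiplication.

## Assessment conventions

* **Boundary:** a level exactly at the limit is satisfactory. Survey
  reports are equivocal on ties; we fix the ≤ convention because it is
  deterministic and consistent with satisfactory-group maxima that sit
  exactly at limits. It is flagged here because it is a choice, not a fact.
* **Units** are fixed to the scheme's unit system (ppm, µg/m³, Bq/m³,
  CFU/m³); no conversion layer.
* **Scheme nesting:** every Scheme-2 limit (the 2019 Hong Kong update,
  tightening CO, RSP and radon) is at most its Scheme-1 counterpart, so
  Scheme-2 satisfaction implies Scheme-1 satisfaction — a property the test
  suite checks on 10^5 random records.

## The synthetic survey generator

The 525-office survey behind the published group statistics is not
deposited, so `generate_offices()` is a first-class module, not a test
fixture. It emulates the survey's *group-wise* statistical structure:

* a Bernoulli satisfactory/unsatisfactory split with
  `p_satisfactory = 358/525`;
* per group, the three surrogates follow **truncated log-normal**
  marginals. Pollutant concentrations are non-negative and strongly
  right-skewed (the unsatisfactory TVOC maximum, 3144 µg/m³, is five times
  its mean), which rules out normal marginals; truncation to the observed
  min–max keeps draws inside the surveyed range. We solve the
  (meanlog, sdlog) pair so that the *truncated* distribution matches the
  target mean and standard deviation (closed-form truncated log-normal
  moments plus a Nelder–Mead solve), rather than moment-matching the
  untruncated distribution and accepting truncation bias — for heavily
  truncated marginals such as satisfactory TVOC (cut at 597 µg/m³) the bias
  would otherwise reach several percent of the mean;
* dependence between surrogates is a **Gaussian copula** with a single
  exchangeable correlation, default 0.3. The survey describes the
  surrogates as distinct yet correlated indicators without printing a
  coefficient, so the correlation is a configuration knob, not a constant;
* the six non-surrogate pollutants matter downstream only through their
  pass/fail status, and are drawn as scaled fractions of their limits
  (pass) or, for hidden failures, one randomly chosen exceedance between
  1.05× and 1.6× the limit.

**Hidden failures.** An unsatisfactory office whose three surrogates all
pass is invisible to any surrogate screen. By default the generator lets
the calibrated marginals decide which offices these are: surrogate triples
for the unsatisfactory group are drawn unconditioned, and a draw that
passes all three surrogate limits becomes a hidden failure (it is assigned
one non-surrogate exceedance). This choice preserves the configured group
moments exactly and, under the default calibration, makes roughly half of
unsatisfactory offices hidden — which caps the achievable screening
accuracy around 0.8 on the default data, the regime the methodology is
designed for. The alternative — forcing a prescribed hidden fraction by
conditioned resampling — is available via `hidden_failure_fraction`, but it
necessarily distorts the realised surrogate moments: exceedances flow
almost entirely through TVOC (RSP can never exceed Scheme 1's 180 µg/m³
within its observed range, CO2 rarely exceeds 1000 ppm), so conditioning
80% of unsatisfactory offices to fail a surrogate pushes the TVOC mean far
above its target. The documentation of `generator_config()` spells this
out; choose forced mode only when the hidden fraction itself is the
quantity under study.

Labels are verified: generation ends by re-assessing every record and
refusing to return if any intended label disagrees with `assess_iaq()`.
Rejection sampling is capped (default 1000 rounds) and an impossible
configuration — e.g. a satisfactory-group mean above a limit — raises a
calibration error instead of looping.

**What the generator does not emulate:** sampling density and floor areas,
measurement error, seasonal structure, and any real correlation between
surrogates and specific non-surrogate pollutants (a hidden failure's
failing pollutant is chosen uniformly). Tests passing on synthetic data
therefore validate the *pipeline* — labelling, training, tuning, screening
arithmetic — not the field performance of any classifier on real offices.

## The model-comparison harness

The harness reproduces a factorial evaluation design: testing fraction
r_d ∈ {0.2, 0.3, 0.4, 0.5} × cross-validation folds K ∈ {5, 10} × scheme ∈
{1, 2} — 16 conditions, each evaluated at a "trained" stage (shipped
default hyperparameters) and a "retrained" stage (grid-search winner), so a
full run produces 32 result sets per algorithm. We read r_d as the testing
*fraction of the total* (training fraction 1 − r_d); the alternative
reading of a test/training *ratio* is inconsistent with the design's
wording and was rejected. r_d is a design factor, never searched over.

Other conventions, fixed where the methodology leaves them open:

* **Normalisation** is min-max to [0, 1], fitted on the training split only
  and applied unchanged to the test split (values may leave [0, 1]; they
  are not clipped). Fitting on all data would leak test information.
* **Untuned defaults** for the trained stage are shipped in the grid
  config; they follow the single illustrative values quoted alongside the
  published test ranges and are defaults, not tuned winners.
* **Tie-breaking** is deterministic everywhere: grids enumerate in a fixed
  order (first listed dimension fastest) and a cross-validation tie goes to
  the earliest grid point; a test-accuracy tie in the best-model tally
  credits all tied algorithms.
* **Seeds** all derive from one master seed through a fixed counter scheme
  (`condition`, `condition × 1000 + algorithm`, fold number), so any run is
  reproducible end to end and no package function perturbs the caller's
  RNG state.
* A model whose test accuracy falls below the majority-class baseline
  (`baseline_accuracy()`, the mode count over n) is flagged unsatisfactory.

### Classifier backends

SVMs (linear, polynomial, RBF, sigmoid) are fitted by `e1071::svm`; the
decision tree by `rpart` (Gini or information impurity, depth/minsplit/
minbucket mapped directly, complexity pruning disabled so the depth grid is
in control); the random forest by `ranger` (trees, max depth, leaf size;
note `ranger` offers no independent min-samples-to-split knob and only Gini
impurity for classification, so those two dimensions are not part of the
forest grid); logistic regression by `glmnet` ridge with λ = 1/(nC). The
regularization factor C follows the inverse-regularization convention
throughout — larger C, weaker penalty — matching the behaviour of the
software ecosystem this design comes from.

Two components are implemented in-package because no installed backend
provides them:

* **distance-weighted kNN** (weights 1 or 1/d, with exact-match short
  circuit) — a brute-force vectorised implementation is entirely adequate
  at survey scale, and prediction ties go to "unsatisfactory", the
  conservative screening outcome;
* a **multilayer perceptron** with arbitrary hidden-layer stacks. The
  design space spans 1–6 hidden layers with neuron totals of 100 or 200
  allocated by ratios such as 1:8:1 (`allocate_neurons()`: proportional
  floor allocation, remainder to the first layer), four activations
  (identity, logistic, tanh, relu) and three iteration schemes. Training
  minimises cross-entropy with an L2 penalty α‖W‖²/(2n): "lbfgs" runs
  limited-memory BFGS via `stats::optim`, "sgd" and "adam" are full-batch
  loops with constant, inverse-scaling or adaptive (divide by 5 on stall)
  learning rates. Weights initialise Glorot-style from a per-spec seed;
  iteration budgets default to 200, past the accuracy plateau at survey
  scale. The 60-configuration MLP design enumerated by
  `mlp_configurations()` is this package's own deterministic
  reconstruction of that design space, truncated in grid order.

### Problem sizes

Routine runs and the test suite use a 2000-office synthetic survey with
the reduced grid set — large enough that baselines, group moments and the
accuracy ordering stabilise, small enough that the complete 16-condition ×
9-algorithm design with grid search finishes in minutes on one core. The
full published test ranges remain available (`grid_set = "full"`) for
users who want the complete sweep.

## Updating the screening table for a new standard

When the exposure standard tightens (Scheme 1 → Scheme 2), the established
likelihood-ratio table must be updated without waiting years for newly
labelled survey data. The procedure implemented in `update_screening()`:

1. **Monte-Carlo sample** surrogate space uniformly — CO2 400–1400 ppm,
   RSP 1–120 µg/m³, TVOC 0–1500 µg/m³, covering the observable office
   range — and compute each triple's index θ (default n = 100,000,
   seeded).
2. **Predict satisfaction** for every triple with an ensemble of the best
   fitted classifiers per scheme (default: the top four algorithms by test
   accuracy, via `select_top_models()`; size configurable). The ensemble
   vote fraction is averaged; a tied vote counts as unsatisfactory.
3. **Fit normal distributions** to θ within the predicted satisfactory and
   unsatisfactory groups (`fit_index_distributions()`). Normality of the
   index is a modelling assumption inherited from the screening
   methodology; the studentized-range statistic u = (range)/s is computed
   per group as the quick check, and a value outside the configured band
   warns rather than errors, because the procedure proceeds under
   normality regardless.
4. **Likelihood ratios** per index bin from the two normal masses
   (`likelihood_ratio()`), for each scheme's ensemble; their per-bin ratio
   is the **relative impact** r of the new scheme on the old.
5. **Update**: LR(new) = r × LR(old) applied to the established Scheme-1
   table (`default_lr1()`: 0.1, 0.4, 0.8, 1.7, 25 across the five bins).

Numerical conventions: the published bin labels (<0.32, 0.32–0.42,
0.43–0.53, 0.54–0.64, ≥0.65) contain gaps because they are 2-decimal
roundings of θ; internally the bins are contiguous half-open intervals
with edges 0.315/0.425/0.535/0.645, which reproduce the labels exactly
under display rounding. Updated LRs are stored unrounded next to a display
value (one decimal below 10, integers at ≥10, round-half-up). A
satisfactory-group bin mass below 10⁻¹² flags the LR as infinite rather
than erroring; relative impacts over zero or infinite LRs are reported as
missing with a warning.

Two readings of "whose θ distribution enters the likelihood ratio" are
defensible: fitting the group normals to the model-predicted labels on the
Monte-Carlo sample (no reference to any office population), or fitting
them to a labelled office dataset. The package's primary mode is the
former — it is the one that needs no survey data, which is the method's
selling point — while `fit_index_distributions()` accepts any θ/label
pairing, so the survey mode is a two-line variant. The two bracket the
plausible interpretations; neither is claimed to be the original
computation.

A structural self-check ships in the tests: running the update with the
*same* ensemble for both schemes and one seed yields r = 1 in every bin
exactly, and the empirical (count-based) LR agrees with the normal-CDF LR
within 10% on genuinely normal simulated indices.

## Known limitations

* Published per-condition accuracies cannot be reproduced: they depend on
  the undeposited survey. The harness reproduces the design's *structure*
  and the synthetic data reproduce the survey's group statistics; accuracy
  values on synthetic data are properties of the generator.
* The MLP backend is a minimal full-batch implementation adequate at
  survey scale (hundreds to thousands of records, three features); it is
  not a general-purpose neural-network library, and with threaded BLAS its
  training is deterministic only up to floating-point reduction order.
* The normality assumption for θ within predicted groups is inherited, not
  tested away: strongly non-normal predicted groups will distort bin LRs,
  and only the u statistic warns about it.
* Relative impacts depend on the ensemble's decision boundaries; with very
  small ensembles the vote fraction is coarse (steps of 1/4 by default).
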