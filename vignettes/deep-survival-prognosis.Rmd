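---
title: "Deep survival prognosis from hysteroscopic images: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep survival prognosis from hysteroscopic images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

After hysteroscopic adhesiolysis for intrauterine adhesions (Asherman's
syndrome), the central management question is prognosis: how likely is this
patient to conceive naturally, and how soon, and would she benefit from
early referral to assisted reproductive technology (ART)? Clinical scoring
systems (AFS, CSGE) grade adhesion severity but are subjective and only
moderately predictive. Post-operative second-look hysteroscopy produces
images that carry the relevant information — cavity morphology, residual
adhesion bands, the state of the tubal ostia — and `hysterosurv` implements
a pipeline that turns those images into a continuous conception-hazard
score, time-resolved conception probabilities, and an ART-benefit
stratification.

## The model

### Cox partial likelihood with a network predictor

The Cox proportional-hazards (CPH) model writes patient $i$'s conception
hazard as $\lambda_0(t)\,e^{h(x_i)}$. With a linear predictor
$h_\beta(x)=\beta^\top x$, $\beta$ is found by maximizing the partial
likelihood

$$L = \prod_{i:\,E_i=1} \frac{e^{h(x_i)}}{\sum_{j \in R(T_i)} e^{h(x_j)}},$$

where $R(T_i)$ is the set of patients still at risk (not yet conceived,
not censored) just before $T_i$, and $E_i$ indicates an observed event
(ongoing pregnancy, i.e. fetal heartbeat beyond 12 weeks of gestation).
DeepSurv replaces $\beta^\top x$ with the scalar output $h_\theta(x)$ of a
neural network and trains $\theta$ on the loss

$$\ell(\theta) = -\frac{1}{N_{E=1}} \sum_{i:\,E_i=1}
  \left[ h_\theta(x_i) - \log\!\!\sum_{j \in R(T_i)} e^{h_\theta(x_j)} \right]
  + \lambda \lVert\theta\rVert_2^2,$$

the event-averaged negative log partial likelihood plus an L2 penalty.
Tied event times use the Breslow approximation throughout (the partial
likelihood above *is* the Breslow form; Efron's correction is a non-goal).
Everything downstream — Breslow baseline hazard, survival conversion,
hazard ratios — is ordinary Cox machinery applied to the network's score.

Key consequences the test suite leans on:

* the loss is invariant to adding a constant to all scores, so only score
  *differences* are identified;
* a network with no hidden layers is exactly a linear Cox model, so the
  package's Newton–Raphson solver (`fit_linear_cox()`) is an analytic
  oracle for the trained head (`test-imaging.R` asserts the equivalence);
* with all scores zero the Breslow estimator reduces to Nelson–Aalen and
  must agree with Kaplan–Meier up to $O(1/n)$.

### Architecture

The image model is backbone → global average pooling → dropout 0.2 →
survival head. The head is two hidden layers of 8 SELU units with batch
normalization and dropout 0.5, then one linear output node; the training
defaults are `learning_rate = 0.154`, `weight_decay = 0.00567` (the
$\lambda$ above), `momentum = 0.887`, Nadam, batch size 16. Those tuned
values are kept as the package defaults and are freely overridable; the
0.154 learning rate is unusually large for Nadam, and the desk-scale
recipes below use smaller rates. Where the tuning description mentions
both Nadam and SGD with Nesterov momentum, Nadam is the default and
`optimizer = "sgd_nesterov"` is provided.

Four ImageNet backbones are supported as *architecture shape
specifications*: InceptionV3, InceptionResNetV2, ResNet50, VGG19. A shape
spec propagates the input size through every convolution, pooling and
batch-norm stage, which is sufficient for exact parameter counting
(`count_parameters()`) and FLOPs accounting (`count_flops()`), without
allocating tens of millions of weights or downloading anything. Parameter
counts include non-trainable batch-norm moving statistics; the Inception
family uses un-scaled batch norm (3 parameters per channel), ResNet full
batch norm (4 per channel). FLOPs are reported under an explicit recorded
convention — 2 FLOPs per multiply-accumulate, convolution and dense layers
only — because published FLOP figures vary by convention; the convention
string travels with every `complexity_report()`.

The fifth backbone, `tiny_test`, is a small fully trainable CNN (3×3
convolutions, ReLU, 2×2 max-pooling, configurable widths, default 8→16).
The entire network stack — convolution via im2col, batch norm, SELU,
dropout, Nadam/SGD-Nesterov, reverse-mode gradients — is implemented in
the package and verified against finite differences in `test-nn.R`.
Training the 20M+ parameter ImageNet backbones is out of scope: without
their pretrained weights they are useful only for complexity accounting,
and `build_model()` says so explicitly.

### Minibatch risk sets

Training forms the Cox risk set *within each minibatch*: a batch is
scored, the within-batch partial likelihood and its gradient are computed,
and one optimizer step follows. A batch at least as large as the data set
reproduces the full-cohort loss exactly (asserted in `test-nn.R`), which
is also how the full-batch head fine-tuning mode is expressed. Batches
that contain no event carry no information and are skipped (counted in the
training history). Images inherit their patient's outcome; patient-level
scores are the mean (configurable: max) of per-image log-hazards.
Per-patient aggregation is a package decision — a multi-view study design
leaves it open — and the mean is the variance-reducing choice.

### From scores to probabilities

Scores become probabilities through the Breslow cumulative baseline hazard
$\hat H_0$ fitted on the training cohort:
$P(\text{conception by } t \mid x) = 1 - \exp(-\hat H_0(t)\,e^{h(x)})$.
$\hat H_0$ is a right-continuous step function, zero before the first
event time. Checkpoints store the curve in their JSON sidecar, so a saved
model is a self-contained predictor of 12- and 24-month conception
probabilities.

## Evaluation methodology

* **Harrell's c-index** with the usable-pair convention: a pair is usable
  iff the smaller follow-up time is an event time; score ties credit 1/2;
  confidence intervals by patient-level percentile bootstrap (B = 1000 by
  default, seeded). `test-evaluation.R` checks exact agreement with a
  literal $O(n^2)$ pair enumeration.
* **IPCW time-dependent AUC**, cumulative-case / dynamic-control with
  Kaplan–Meier censoring weights (the Uno estimator). Cases at horizon
  $t$ are weighted $1/\hat G(T_i^-)$; patients censored before the horizon
  receive zero weight (standard IPCW, no imputation). With no censoring
  before the horizon the statistic collapses to the exact Mann–Whitney
  AUC, and on a frozen seeded fixture it reproduces an independent
  reference implementation of the estimator to $10^{-6}$.
* **Calibration** by quantile binning (5 bins by default) of predicted
  probabilities against the Kaplan–Meier observed event frequency at the
  horizon, with Greenwood intervals. A bin whose follow-up cannot reach
  the horizon is flagged unavailable rather than imputed.
* **Model comparison** by paired patient-level bootstrap of the c-index or
  AUC difference with a two-sided normal-approximation p-value. Identical
  scores give p = 1 by convention; the test is symmetric in its arguments.
  DeLong-style tests are a non-goal because they do not accommodate
  censoring.

## ART-benefit stratification

Patients are split at a predicted 1-year conception probability of 0.5
(boundary values go to the low group), plus the clinical comparator strata
AFS ≥ 5, CSGE ≥ 18, endometrial thickness ≥ 7 mm. Within each stratum the
ART effect is the hazard ratio from a Cox fit with the binary ART
covariate; Wald 95% CIs and p-values are reported.

Two ART conventions are implemented because the immortal-time question is
genuinely open in this design. Under the **baseline-covariate** reading
(the default, matching the simplest reading of a stratified HR table), ART
is a time-fixed covariate from surgery. But ART typically starts only
after a year of attempted natural conception, so ART users are guaranteed
event-free for their first 12 months — immortal time that biases the naive
HR downward; on synthetic cohorts with a true post-initiation HR of 3 the
naive estimate can fall below 1, and the test suite asserts that bias
direction. Under the **time-dependent** convention
(`time_dependent = TRUE`) an ART patient contributes an untreated interval
$[0, t_{\text{ART}})$ and a treated interval $[t_{\text{ART}}, T]$, via
the solver's delayed-entry support; this recovers the generating effect
direction and significance. A second caveat the vignette states because
the tests rely on it: with heterogeneous baseline hazards the *marginal*
stratum HR is frailty-attenuated relative to the conditional effect (≈ 2.1
versus a conditional 3 at a severity spread of $e^{\pm 1}$), so stratum
tests assert direction, significance and null-coverage, while CI coverage
of the true value is tested on homogeneous two-arm simulations.

A parallel convention switch exists on cohort ingestion: for the
natural-conception prediction model, `read_cohort()` by default censors
ART users at ART initiation (their natural-conception follow-up ends
there), with `keep_at_risk` available; whether ART-assisted conceptions
should count as events in such a model is not decidable from the study
design alone, so both behaviors are provided and the default documented
rather than attributed.

## The synthetic cohort generator

No clinical images ship with the package (the source cohort is a
non-public clinical database), so every pipeline stage is exercised on a
generator whose truth is known:

* severity $s_i \sim U(0,1)$; conception hazard
  $h_i = \lambda_0 e^{\beta_s (s_i - 0.5)}$, Weibull event times with
  cumulative hazard $h_i t^k$ ($k=1$, exponential, by default; the shape
  is exposed for robustness tests);
* defaults $\lambda_0 = 0.012$/month and $\beta_s = -1.2$ give a ~40%
  event fraction by the 48-month administrative censoring bound — the
  cohort-scale event rate of the study population this emulates — with an
  exponential loss-to-follow-up of 0.003/month (~13% dropout) on top;
* ART: patients still at risk at month 12 start ART with probability 0.5,
  after which their hazard is multiplied by the stratum-appropriate HR
  (defaults 3.13 / 0.52, the benefit pattern the stratification module
  must recover); the truth table stores counterfactual no-ART times;
* images: a pale elliptical cavity on a dark background; dark occluding
  bands whose number and thickness grow monotonically with severity
  (cavity view) or a proportionally occluded ostium disc (cornua views);
  illumination gradient and Gaussian noise on top; a ground-truth mask
  marks adhesion pixels. Rendering is deterministic per (severity, view,
  seed).

What the generator does *not* emulate — specular reflections, instrument
shadow, fluid turbidity, anatomical variation, view mislabeling — bounds
what green tests mean: they demonstrate that the pipeline recovers a
known monotone image-to-hazard relationship end to end, not that any
particular clinical accuracy would be attained on real hysteroscopy data.

Two named study conditions are fixed once and used by the tests:

* **strong-signal** (`beta_severity = -8`, everything else default): the
  condition under which end-to-end learning is judged. It was chosen so
  that the *generating law itself* discriminates 12-month conception at
  IPCW AUC ≈ 0.95 (oracle = true severity; $\beta_s$ of −4, −6, −8 give
  oracle AUC 0.81, 0.90, 0.945) — a trained model is asked to find 0.8 of
  discrimination that is actually present in the data.
* **stratification stress** (`baseline_rate = 0.06`,
  `beta_severity = -2`): rates under which true 1-year conception
  probabilities straddle the 0.5 threshold so both risk strata are
  populated; under the cohort-emulating defaults every patient sits below
  0.5 and the high stratum would be empty.

## Interpretation (Grad-CAM)

For a scalar survival output, Grad-CAM weights a convolutional layer's
channels by the spatially averaged gradient of the output, sums, rectifies,
max-normalizes to $[0,1]$ and bilinearly upsamples. The default target is
the last convolutional layer; the default sign negates the output so that
hot regions are subfertility drivers (`sign = "hazard"` gives the raw
direction). The map is invariant to constant shifts of the output, and a
constant-output model yields an all-zero map with a warning.

One empirical subtlety, documented because the tests depend on it: the two
rectified maps (hazard direction and its negation) roughly partition the
image — one concentrates on the adhesion bands, the other on the
complementary open cavity — but *which* map captures the bands depends on
the learned channel signs and therefore on the training seed: channel-mean
gradient weighting mixes signs through global average pooling, and a
channel can encode band presence with either activation polarity. The
band-localization checks therefore evaluate both maps and require that the
better-localizing one concentrates on the ground-truth band mask: on ≥ 20
held-out strong-signal images its mean intensity inside the mask exceeds
the outside mean (asserted as a tendency, not per image). For clinical
display, both signed maps should be inspected; the default display keeps
the subfertility direction.

## Numerical choices

* Newton–Raphson: max 50 iterations, convergence at
  $|\Delta \log L| < 10^{-9}$, step-halving on likelihood decrease;
  standard errors from the inverse observed information; coefficients
  exceeding 20 in absolute value abort with a monotone-likelihood
  (separation) diagnosis. Delayed entry supports the time-dependent ART
  convention.
* Partial likelihood and gradients are computed on max-shifted scores
  (log-sum-exp), so the loss is stable for scores of any magnitude.
* Baseline hazard and Kaplan–Meier curves are right-continuous; censoring
  weights use the left limit $\hat G(T^-)$.
* Risk-group boundary: probability exactly at the threshold goes to the
  low group.
* Gradient clipping by global norm (default 5) and seeded minibatch
  shuffling; two runs with the same config and seed are bit-identical,
  and `with_local_seed()` keeps the generator from clobbering the
  session RNG.
* Quantile calibration breaks deduplicate; degenerate constant
  predictions collapse to a single bin rather than erroring.

## Desk-scale problem sizes

The test suite and acceptance script run at sizes chosen for a laptop
core: 200-patient cohorts at 40×40 px and 3 views (600 training images,
25 epochs, ~1.5 min per training run), n = 500–2000 outcome-only cohorts
for estimator checks, 200 replicates for CI coverage, B = 50–200
bootstrap draws in tests (B = 1000 remains the analysis default). These
are the package's own choices of demonstration scale; all sizes are
ordinary function arguments.

## Known limitations

* Trainable networks are limited to the tiny backbone; the ImageNet
  architectures participate as complexity specs and (by design) no
  pretrained weights are bundled or downloaded.
* Proportional hazards is assumed throughout; time-varying covariates,
  competing risks, frailty terms and Efron/exact tie handling are
  non-goals.
* The marginal/conditional HR gap and the immortal-time sensitivity
  discussed above are properties of the estimand, not bugs; users
  comparing conventions should expect materially different stratum HRs.
* Bootstrap p-values use a normal approximation of the resampled
  difference; very small p-values are approximations, not exact tail
  probabilities.
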