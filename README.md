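# hysterosurv

Image-based fertility prognosis after hysteroscopic adhesiolysis.

Intrauterine adhesions (Asherman's syndrome) are treated by hysteroscopic
adhesiolysis, after which the clinical question is prognostic: how likely is
natural conception, how soon, and who should be referred early to assisted
reproductive technology (ART)? Second-look hysteroscopy images carry that
information — residual adhesion bands, cavity morphology, tubal ostia — but
clinical severity scores (AFS, CSGE) summarize them subjectively.
`hysterosurv` implements the full deep-survival pipeline for this problem,
for researchers in reproductive medicine and for methodologists working on
image-based time-to-event models.

## What it does

At its core is a Cox proportional-hazards neural network (DeepSurv): a
convolutional feature extractor followed by a small survival head whose single
output `h_θ(x)` replaces the linear predictor `βᵀx` in the Cox partial
likelihood. Training minimizes

```
ℓ(θ) = −(1/N_{E=1}) Σ_{i: E_i=1} [ h_θ(x_i) − log Σ_{j ∈ R(T_i)} exp h_θ(x_j) ] + λ‖θ‖²
```

with Breslow handling of ties and risk sets `R(T_i)` formed within each
minibatch. Around that core:

* **survival mathematics** — partial likelihood, Newton–Raphson linear Cox
  solver (with delayed entry), Breslow baseline hazard, Kaplan–Meier, and the
  conversion `P(conception by t | x) = 1 − exp(−H₀(t)·exp h(x))`;
* **evaluation** — Harrell's c-index (exact against brute-force pair
  enumeration), IPCW time-dependent AUC (Uno estimator; collapses exactly to
  Mann–Whitney without censoring), quantile-bin calibration against
  Kaplan–Meier, paired-bootstrap model comparisons;
* **interpretation** — Grad-CAM heatmaps for the scalar survival output, with
  both sign conventions (subfertility drivers vs raw hazard) and overlay
  rendering;
* **stratification** — risk groups at a predicted 1-year conception
  probability of 0.5 and ART-benefit hazard ratios per stratum, with both the
  baseline-covariate and the time-dependent (immortal-time-safe) ART
  conventions, plus the AFS ≥ 5, CSGE ≥ 18 and endometrial-thickness ≥ 7 mm
  clinical comparators;
* **complexity accounting** — exact parameter counts and convention-annotated
  FLOPs for InceptionV3, InceptionResNetV2, ResNet50 and VGG19 from
  architecture shape specs (no weight downloads);
* **synthetic cohorts** — a deterministic generator of hysteroscopy-like
  images (adhesion bands occluding a cavity silhouette) whose severity drives
  event times under a known proportional-hazards law with censoring and an
  ART effect, so the whole pipeline is testable without clinical data.

The neural-network engine (convolution, batch norm, SELU, dropout,
Nadam/SGD-Nesterov, reverse-mode gradients) is implemented in the package and
verified against finite differences; the `tiny_test` backbone is fully
trainable at desk scale.

## Worked example

Simulate a 200-patient cohort whose image-visible adhesion severity drives
conception hazard, train the tiny CNN survival model, and evaluate on the
held-out quarter of patients:

```r
library(hysterosurv)

count_parameters("inception_v3")
#> [1] 21802784

cfg    <- generator_config(n_patients = 200, image_size = 40,
                           beta_severity = -8, seed = 1)
cohort <- generate_cohort(cfg)
splits <- make_splits(cohort, seed = 1)          # 60/15/25% by patient
spec   <- backbone_spec("tiny_test", input_size = 40)
imgs   <- lapply(cohort$images, function(im)
            lapply(im, preprocess_image, backbone = spec))

rec <- cohort$records
tr  <- which(rec$patient_id %in% c(splits$train, splits$validation))
model <- build_model(spec, seed = 1)
model <- train_deepsurv(model, unlist(imgs[tr], recursive = FALSE),
                        rep(rec$time_months[tr], each = 3),
                        rep(rec$event[tr], each = 3),
                        train_config(learning_rate = 0.02, weight_decay = 1e-4,
                                     epochs = 25, seed = 1))

te <- which(rec$patient_id %in% splits$test)
scores <- vapply(te, function(i) predict_patient(model, imgs[[i]])$log_hazard,
                 numeric(1))
ipcw_time_auc(scores, rec$time_months[te], rec$event[te], horizon = 12,
              B = 200, seed = 1)[c("auc", "ci_low", "ci_high")]
#> $auc      [1] 0.8768909
#> $ci_low   [1] 0.7706145
#> $ci_high  [1] 0.9704855
harrell_cindex(scores, rec$time_months[te], rec$event[te],
               B = 200, seed = 1)[c("c_index", "ci_low", "ci_high")]
#> $c_index  [1] 0.7311828
#> $ci_low   [1] 0.6580698
#> $ci_high  [1] 0.8241143
```

The trained model discriminates 12-month conception on held-out patients at
IPCW AUC 0.88: the network has recovered the severity signal painted into the
images. Attaching the Breslow baseline hazard turns scores into per-patient
conception probabilities:

```r
model$baseline <- breslow_cumulative_hazard(
  vapply(tr, function(i) predict_patient(model, imgs[[i]])$log_hazard, numeric(1)),
  rec$time_months[tr], rec$event[tr])
round(predicted_event_probability(scores[1:3], model$baseline, 12), 3)
#> [1] 0.270 0.256 0.318
round(predicted_event_probability(scores[1:3], model$baseline, 24), 3)
#> [1] 0.377 0.359 0.438
round(cohort$truth$severity[te][1:3], 2)
#> [1] 0.57 0.91 0.20
```

The mildest-adhesion patient (severity 0.20) gets the highest predicted
conception probability; probabilities rise with the horizon, as they must.
`grad_cam()` then localizes the image regions driving a prediction, and
`stratification_table()` reports the ART-benefit hazard ratio per risk group.

A command-line wrapper covering the same pipeline
(`simulate`, `train`, `predict`, `evaluate`, `gradcam`, `stratify`,
`complexity`) is installed at `inst/cli/hysterosurv`.

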