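---
title: "Shortcut learning from site prevalence: the radshift simulation and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortcut learning from site prevalence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Image classifiers trained on radiographs pooled from several hospital
systems can look excellent on held-out data from those same systems and
then disappoint at a new site. One mechanism is *confound exploitation*:
every archived radiograph carries site-identifying acquisition artifacts —
corner metal laterality tokens, burned-in text, department-specific
inverted color schemes, detector noise signatures — and when sites differ
in disease prevalence, recognizing the site is itself predictive of
disease. The model then calibrates to per-site base rates instead of (or
in addition to) reading pathology, which inflates internal pooled-test
performance without improving, and sometimes while degrading, external
performance.

`radshift` reproduces this mechanism end to end on fully synthetic data:
no patient images are used anywhere. The package is organised as an
analysis workflow — the numbered drivers under `analysis/` narrate the
study, and every computational step they use lives in the package proper
where it is unit-tested.

## The synthetic study population

`generate_study_set()` draws patients, studies and images for a set of
[site_profile()] objects. The default three-site world
(`default_site_profiles()`) emulates the shape of the public multi-site
chest-radiograph landscape:

* `site_a` — an urban tertiary hospital: pneumonia prevalence 34.2%,
  inpatient-heavy department mix with a portable emergency-department
  scanner that archives in an inverted color scheme, a near-white text
  banner, a bottom-right corner token, mean patient age 63.2 (SD 16.5),
  44.8% female.
* `site_b` — a large research archive: prevalence 1.2%, top-left token,
  low detector noise, age 46.9 (16.6), 43.5% female.
* `site_c` — a small external outpatient network: prevalence 1.0%,
  top-right token, high detector noise, age 49.6 (17.0), 57.3% female.

Prevalences, demographics and the 3.5 mean studies per patient follow the
published baseline characteristics of the three hospital systems this
world emulates; the artifact geometry (6 px tokens at intensity 0.8–1.0,
3-row banners, per-site noise SD 0.06–0.11) is the package's own choice of
a *detectable but not overwhelming* acquisition signature. Site evidence
is deliberately both local (tokens, banner) and global (noise level,
background offset), matching the observation that real site classifiers
can call the site from almost any subregion of the image.

Key generator decisions:

* **Exact-count labels.** Each site receives exactly
  `round(prevalence * n_studies)` pneumonia-positive studies (not
  Bernoulli draws), split across sex strata proportionally so each sex's
  prevalence matches the site's. This makes cohort arithmetic
  deterministic and testable. Under this proportional allocation a
  feasible request can always be satisfied; the defensive stratum check
  matters for the cohort sampler, where equal-per-sex counts are enforced.
* **Episode clustering.** Positives are assigned patient-by-patient
  (a randomly ordered queue of patients contributes all of their studies
  until the exact count is reached), because pneumonia persists across the
  serial radiographs of one admission. This keeps patient-level and
  study-level prevalence coherent, which the engineered-prevalence
  sampler — which operates on patients — relies on.
* **Disease signal.** A pneumonia-positive frontal study receives one
  additive soft-elliptical opacity (amplitude `effect_size`, default 0.15
  intensity units) at a randomized lung-field location. The location is
  drawn for every frontal render and added with weight equal to the
  label, so positive and negative renders of the same metadata consume
  identical randomness and are pixel-identical at `effect_size = 0` — the
  null-signal oracle the tests rely on. At the default amplitude a small
  CNN reaches a within-site AUC around 0.7, deliberately imperfect so
  there is headroom for shortcut inflation. Only pneumonia has an image
  correlate; the other eight findings are report-only labels that give the
  multi-label models and the NLP labeler realistic structure.
* **Views.** Laterals use a distinct projection: narrower torso, single
  lung field, a bright spine column, and a globally brighter exposure.
  These are the cues the frontal-view filter stage learns from.
* **Order of composition.** Silhouette + disease + noise are clipped to
  `[0, 1]`, *then* inversion is applied (`1 - pixel`), and the token and
  banner are overdrawn last — metal and burned-in text stay bright in
  either color scheme, so an inverted render equals one minus its
  non-inverted counterpart everywhere except the overdrawn artifacts.

What the generator does **not** emulate: anatomy beyond blurry ellipses,
exposure/processing pipelines, image correlates for the eight secondary
findings, scanner-model textures beyond Gaussian noise, or longitudinal
disease progression. Passing tests therefore demonstrate the *mechanism*
of prevalence-confound shortcut learning under controlled conditions, not
performance on real radiographs, and the real-data AUC tables of the
emulated setting are expressly not reproduction targets.

## Cohorts

`split_by_patient()` assigns whole patients (or accession groups, for
data without patient identifiers) to fixed 70/10/20 train/tune/test
splits by the largest-remainder rule, so no patient straddles splits.

`engineer_prevalence_cohort()` subsamples a two-site cohort whose
patient-level pneumonia prevalence per site is set by design while the
overall prevalence stays constant. `standard_specs()` returns the five
standard designs (site-A share of a constant 5% overall prevalence:
9.9%, 9%, 5%, 1%, 0.1%). Sampling is exact within the four site-by-sex
strata — positives and totals split evenly between the sexes, so male and
female prevalence agree to one patient — and errors name the deficient
stratum when a pool cannot support a design. Existing split membership is
preserved rather than resampled; because sampling is not additionally
stratified by split, per-split prevalence matches the design in
expectation only (the alternative — stratifying by split too — was
rejected as stronger than what the emulated protocol states). Whether to
balance sex within site or only overall is genuinely open; the sampler
balances within site and exposes `balance_sex` to turn the constraint
off.

## Report labeling

`generate_report()` writes templated English sentences: every positive
finding is asserted with one of several lexical variants, a random subset
of negative findings is explicitly negated (lexicon: "no", "without",
"resolved"), and hernia-positive studies always contain the word
"hernia". A report never asserts a finding whose label is 0 without a
negation cue, so labels remain recoverable from text.

`fit_label_model()` is the recovering instrument: 1-/2-gram bag-of-words
*count* features (counts, not binary presence, which is the stronger
default for short reports) with Lasso logistic regression, the penalty
chosen by cross-validated deviance. Negation is not modeled explicitly —
bigrams such as "no pneumonia" carry it, which is exactly what the
end-to-end recoverability test checks (held-out AUC > 0.9 on a 283/122
split). The hernia keyword rule matches the whole token,
case-insensitively, so "herniation" does not fire it. Models serialize to
JSON (vocabulary, coefficients, intercept, threshold).

## The classifier and its training schedule

No deep-learning framework is assumed: the CNN is implemented in
vectorized base R (im2col gathers feeding BLAS matrix products, with
backpropagation verified against numerical gradients in the test suite).
The architecture is deliberately small — blocks of 3×3 same-padding
convolution, ReLU and 2×2 max pooling reduce the input to a `g × g × K`
feature map (defaults: 32 px input, channels 4 and 8, so `g = 8`,
`K = 8`), then global average pooling and a linear head; multi-label
models insert a *linear* bottleneck (width 15) before the head. The
claims under study concern data and confounds, not architecture, so a
desk-scale network replaces the seven-million-parameter model of the
emulated setting. Two consequences of the design:

* Because bottleneck and head are both linear, they compose into a single
  per-class weight vector over the K pooled channels, and the subregion
  score map (below) averages *exactly* to the model's logit.
* Inputs are normalized to roughly zero mean and unit scale
  (`(x - 0.5) / 0.25`) before the first convolution; without
  normalization the fixed learning rate makes small-feature tasks stall.

Training follows a fixed recipe: cross-entropy (summed over the binary
findings for multi-label models, so every head trains at full gradient
scale), SGD with momentum 0.9, initial learning rate 0.01, weight decay
1e-4, minibatch 8. After every epoch whose tune loss fails to improve
strictly on the best so far, the learning rate is divided by 10; three
consecutive non-improving epochs end training; the best-tune-loss
parameters are retained. `plateau_schedule()` is the pure reference
implementation of this rule and the trainer's log is tested against it.
A hard cap of 25 epochs bounds runtime; the plateau rule almost always
fires first. One stage deviates from the shared rate: the frontal-view
filter trains at 0.003 because its broad, high-contrast silhouette
features destabilize 0.01 at this input scale (the rate was chosen from
the task's optimization behaviour, and the deviation is confined to that
stage).

Two scaled-down caveats are worth stating. First, with tune sets of a few
hundred images the tune-loss estimate is noisy relative to early-epoch
improvements, so training occasionally plateaus out near initialization;
the experiment scales below were chosen so this is rare. Second, epochs
here are passes over a few thousand images, not hundreds of thousands, so
absolute AUCs are lower than a full-scale system would reach.

## Subregion activation maps

For one image, `extract_final_features()` returns the final-layer
activations `X[k, i, j]` and the effective head `(B, B0)`.
`subregion_scores()` applies the head at every grid cell,
`Y[c, i, j] = sum_k B[c, k] X[k, i, j] + B0[c]`;
`subregion_probability()` softmaxes over classes at each cell;
`count_decisive()` counts cells whose target-class probability meets the
threshold (inclusive at exactly `tau = 0.95`, reading "at least 95%
certain" inclusively); `influence_heatmap()` shows
`Y[target] - sum(others)` minus its grid mean (zero-sum by construction),
which isolates the strongest evidence when many cells vote the same way.
For more than three classes the target-minus-sum-of-others form is the
natural generalization of the three-class difference. Per-image maps are
computed first and aggregated afterwards; averaging maps before
thresholding is the other defensible reading and would give smoother,
smaller counts. The grid follows the architecture (`g = 8` at the
defaults rather than 7); all statistics report `g^2` alongside counts.

## Evaluation statistics

All implemented from their definitions and cross-checked in the tests
against independent routes (`pROC`, `binom.test`, brute-force pair
enumeration, leave-one-out jackknife):

* `auc_estimate()` — Mann–Whitney AUC with ties counted one half; DeLong
  structural-component variance `var(V10)/m + var(V01)/n`;
  normal-approximation CI clipped to `[0, 1]` (the CI convention of the
  standard ROC packages).
* `delong_paired()` / `delong_unpaired()` — z from the paired
  component covariance, or from the sum of the two single-set variances;
  identical rankings give the degenerate `p = 1` convention with a
  warning. The orchestrator uses the paired test only when two score
  vectors share an identical case set.
* `clopper_pearson()` — exact beta-quantile interval, boundary-exact at
  0 and n successes.
* `chi_square_proportions()` — Pearson chi-square without continuity
  correction (the large-sample convention; a flag restores Yates).
* `operating_point_at_sensitivity()` — the screening threshold admits the
  fewest positives that reach the target (`ceiling(target * n_pos)`-th
  largest positive score, ties classified positive, so achieved
  sensitivity is always ≥ target), and reports all binary metrics with
  Clopper–Pearson intervals.
* `trivial_prevalence_ranker()` — every case scored by its site's
  training prevalence; its AUC on a pooled test set measures how far
  site identity alone ranks disease.
* `calibration_summary()` — the calibration slope is the coefficient of a
  logistic recalibration of outcomes on the logit of the predicted
  probability (a slope definition has to be chosen; this is the standard
  Cox recalibration), plus equal-width bins for plotting; constant
  probability vectors are flagged degenerate rather than fit.

## The three studies

`run_site_generalization()` trains one nine-finding model per train-site
combination and evaluates pneumonia screening on the joint internal test
set, each single-site subset, and the external site (all of whose studies
are reserved for testing). `run_site_detection()` trains site and
department classifiers and audits them with the activation-map machinery.
`run_engineered_prevalence()` runs the five-design relative-risk
experiment. Comparison rows are labelled by site-set algebra
(`internal`, `subset`, `superset`, `external`), every statistic in a
results table is recomputable from the saved per-case score frames, and
everything is deterministic given the run seed. Phenomenon-level claims
are always evaluated across replicate seeds (five in the tests), because
single-run CNN AUCs at this scale are noisy.

Problem sizes used by the tests and the acceptance script (the package's
own choice of desk scale): 32 px images; 200–1,600 patients per site for
the generalization study (the low-prevalence site is largest so its
subset test set retains enough positive studies); pools of 800 patients
per site at 15% prevalence feeding engineered cohorts of 300 patients per
site; an external site of 400 patients; 5 replicate seeds for the
directional claims. Site-detection audits use the wider channel pair
(8, 16): per-cell *certainty* — unlike accuracy — is capacity-limited,
and the narrow default saturates below the majority-decisive regime.
The package defaults keep the reference conditions (64 px, 10,000
patients per site in `standard_specs()`).

## Known limitations

* The generator's site signature is low-dimensional; real inter-site
  variation is richer and partly unknown, which is the point of the
  original observation but beyond the simulation.
* Only pneumonia is rendered; the eight secondary findings regularize
  training but cannot be learned from pixels.
* The tiny CNN under a strict plateau rule occasionally stops before
  learning anything on marginal tasks; replicate seeds and the chosen
  scales keep this from driving conclusions.
* External AUC at the external site rests on a handful of positive
  patients at desk scale, so single-seed external estimates are wide; only
  cross-seed patterns are interpreted.
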