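# fatlat — latent-space assessment of exercise-induced fatigue

`fatlat` is an R package for quantifying neuromuscular fatigue from
multimodal wearable-sensor recordings of repeated exercise. It targets the
setting where participants perform sets of 10 repetitions of lower-body
exercises (squat, left/right lunge, plank jump-in) to exhaustion while
instrumented with a balance board (four vertical corner forces, 30 Hz) and
three inertial measurement units (hip and both forearms, 3-axis
accelerometer + gyroscope, 60 Hz). It is aimed at movement scientists and
sports-science researchers who want a tested, end-to-end reference
implementation of this analysis — including a synthetic cohort generator,
since datasets of this kind are rarely public.

## The method

Each repetition is preprocessed into a standardized matrix
**X** ∈ ℝ^(192×n) (192 frames by cubic-spline resampling; n channels
depending on the sensor subset DB0–DB4), with inertial-to-segment
calibration from a static T-pose, gravity removal and height normalization
of the accelerations, mass-normalized ground reaction force and
initial-subtracted centre of pressure from the board, a zero-phase 4th-order
15 Hz Butterworth low-pass, and per-type z-scoring
(z = (x − μ_t)/σ_t for t ∈ {GRF, CoP, acc, gyro}) with statistics from the
training split only.

A semi-supervised adversarial autoencoder embeds each matrix into
**z** ∈ ℝ². The encoder (three residual 5×1 convolution blocks of 16/32/64
channels with 2×1 max-pooling, a 128-unit dense layer, a linear 2-unit
latent layer) and its mirrored decoder minimize reconstruction error, while
a discriminator (two 512-unit sigmoid layers on (z, one-hot label)) is
trained to tell encoder outputs from samples of a mixture-of-Gaussians
prior with one mode per activity, drawn at each item's *own* label's mode —
so fooling the discriminator pulls every activity toward its own cluster.
A conditional variant (Cond-SSAAE) additionally feeds a learned label
embedding to encoder and decoder. Model selection restores the epoch with
the lowest mean validation KL divergence between per-activity Gaussian fits
and their prior modes; the model is then fine-tuned on the fatigue group
for 10 epochs at one tenth of the learning rate.

Each set of 10 repetitions forms a 10-point latent cluster. Four indices
track drift relative to the session's first set: the two-cluster
silhouette, the two-cluster Davies–Bouldin ratio (S_i + S_0)/d(c_i, c_0),
the 95 % confidence-ellipse area π·χ²₂(0.95)·√det(Σ̂), and the centroid
distance. Indices are standardized per participant, set position becomes a
completion percentage (100·i/(S−1)), and one pooled OLS regression per
(exercise, index) cell tests for a fatigue trend at α = 0.05. With K folds
this yields K×4×4 fold-level regressions and 4×4 ensemble regressions on
fold-averaged indices; the counts of significant slopes summarize each
sensor combination and model variant.

## Worked example

A small end-to-end experiment on a synthetic cohort (hip-IMU-only variant
DB3, one model variant, two folds, deliberately tiny training budget so it
runs in about a minute):

```r
library(fatlat)
cfg <- experimentConfig(
  databases = "DB3", variants = "Res-SSAAE", K = 2,
  cohort = cohortConfig(nGroupA = 4, nGroupB = 2, setsRange = c(3, 4)),
  maxEpochs = 4, batchSize = 16, lr = 2e-3, fineTuneEpochs = 2)
res <- runExperiment(cfg, outDir = "fatlat-demo", seed = 3, verbose = FALSE)
res$assessment
#>   database   variant p_value_counter counter_total p_value_ensemble ensemble_total
#> 1      DB3 Res-SSAAE              21            32               12             16
```

Reading the table: over the 2 folds × 4 exercises × 4 indices = 32
fold-level regressions of standardized cluster index on completion
percentage, 21 had p < 0.05; of the 16 regressions on fold-averaged
indices, 12 were significant. (At this toy budget the embedding is barely
trained, so the counts mostly reflect the injected fatigue drift that
survives any reasonable projection; the package's tests run larger budgets
where the latent space is properly shaped and directions of all four
indices are checked.) The run also writes per-fold latent coordinates,
index tables, trend tables and an `assessment.json` under `fatlat-demo/`,
and re-running the same call is a cached no-op.

At the test-suite scale (10 training subjects, 32 epochs), the validation
latent accuracy — the fraction of validation repetitions whose nearest
prior mode matches their activity — reaches 1.00 on the synthetic cohorts,
and on fatigue cohorts the ellipse area and centroid distance slopes are
positive, the silhouette slope positive and the Davies–Bouldin slope
negative, as expected when the latent clusters drift and widen with
fatigue.

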