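# semgcobb

Predicting Cobb angle outcomes in adolescent idiopathic scoliosis (AIS)
from surface electromyography (sEMG).

AIS severity is tracked by the Cobb angle read from full-spine radiographs —
slow, operator-dependent, and a radiation dose. Scoliotic curves activate
the paraspinal muscles asymmetrically, and that asymmetry is measurable
non-invasively with sEMG. `semgcobb` is for researchers in rehabilitation
and biomedical signal processing who want a complete, reproducible pipeline
from raw multichannel sEMG to clinical outcome predictions for patients in
a 24-week Schroth exercise programme: signal conditioning, feature
extraction, a dual-branch TCN-LSTM regression model with TCN / LSTM / SVR
baselines, patient-grouped evaluation, and a calibrated synthetic-cohort
generator so everything runs end to end without access to clinical data.

## The method in brief

Each recording is 8 channels (bilateral erector spinae, multifidus, rectus
abdominis, external oblique) at 1000 Hz during a 20-s isometric exercise
hold, taken at weeks 0, 8, 16, 24. Conditioning is a 4th-order Butterworth
band-pass (20–400 Hz, zero-phase). Per channel the amplitude feature is

    RMS = sqrt( (1/N) * sum( x_i^2 ) )

and per muscle pair the paraspinal muscle symmetry index

    PMSI = RMS_convex / RMS_concave

with the convex side taken from the patient's curve. PMSI ≈ 1 means
symmetric activation; PMSI > 1 means the convex side dominates.

The primary model is a dual-branch network: a temporal convolutional stack
(dilated causal convolutions, dilations 2–32, kernel 3, conv → ReLU →
batch-norm → dropout) feeding a 2-layer LSTM whose final hidden state is
concatenated with a fully connected embedding of the static features (sex,
BMI, multi-week PMSI history), then passed through 128/64/32 dense layers
to a linear output. Training is Adam (batch 16, MSE) with early stopping
(patience 10, ≤ 100 epochs), 7:3 patient-grouped splits and 3-fold
patient-grouped cross-validation; metrics are RMSE and R². The neural
engine — forward and hand-derived backward passes — is implemented in this
package and verified against finite differences in the test suite.

Because the clinical recordings are not public, the package includes a
synthetic-cohort generator calibrated to the published cohort statistics
(143 patients; age 14.6 ± 2.7; baseline thoracic/lumbar Cobb 19.12 ± 5.95 /
15.28 ± 6.71°; erector spinae RMS 38.57 µV convex vs 25.56 µV concave, mean
PMSI 1.37), with convex/concave asymmetry coupled to the regional Cobb
angle so the learnable signal exists by construction. See the methods
vignette (`vignettes/semgcobb-methods.Rmd`) for the model, the calibration
mathematics and the design decisions.

## Worked example

```r
library(semgcobb)

# a small synthetic cohort: 8 patients, 4 exercises x 4 weeks each
sim <- simulate_cohort(sim_params(n_patients = 8, seed = 1))
sim$cohort
#> <semg_cohort> 8 patients, 32 outcome rows, 128 recordings

# features of one recording
rec <- sim$cohort$recordings[[1]]
st  <- sim$cohort$statics[sim$cohort$statics$patient_id == rec$patient_id, ]
f   <- extract_features(rec, st)
round(f$rms, 1)
#>   erector_spinae_L   erector_spinae_R       multifidus_L       multifidus_R
#>               18.9               17.3               14.5               16.2
#> rectus_abdominis_L rectus_abdominis_R external_oblique_L external_oblique_R
#>                8.7                7.9               10.8                9.3
round(f$pmsi, 2)
#>   erector_spinae       multifidus rectus_abdominis external_oblique
#>             1.09             1.12             1.10             1.16
```

This patient has a left thoracic curve, so the convex side of the erector
spinae pair is the left channel and the convex side of the (mirror-image)
lumbar curve is the right multifidus channel; every PMSI is above 1. The
asymmetry magnitude varies strongly across patients — this is a mild case —
and its coupling to the regional Cobb angle is the signal the models
regress on.

```r
# assemble the thoracic-Cobb dataset and train the hybrid
# (use >= 40 patients for a meaningful fit; 8 is only a smoke size)
ds    <- make_supervised_samples(sim$cohort, "cobb_T")
ds
#> <semg_dataset:cobb_T> 64 samples, 8 patients, weeks {0, 24}
spec  <- train_spec(max_epochs = 20, seed = 1)
parts <- split_dataset(ds, spec)
cfg   <- model_config("tcn_lstm", n_filters = 8, lstm_units = 16)
fit   <- train_model(build_tcn_lstm(cfg, dim(ds$X)[2:3], ncol(ds$S)),
                     parts$train, parts$val, spec)
pred  <- predict_dataset(fit, parts$test)
rmse(parts$test$y[, 1], pred[, 1])   # degrees of Cobb angle
r2(parts$test$y[, 1], pred[, 1])
```

On a 60-patient cohort the same configuration (run by
`scripts/acceptance.R`, seed 1) reaches a test-set R² of 0.78 for the
thoracic Cobb angle, and 0.04 on a control cohort generated with the
asymmetry coupling switched off — the model finds the signal where the
generator put one, and nothing where it did not.
`benchmark_models()` runs the full model × target × fold grid
and `format_eval_report()` prints it as the comparison table; a CLI wrapper
for the whole flow lives in `inst/scripts/semgcobb`.

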