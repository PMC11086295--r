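# echoscope

Classification of bat species from ultrasonic echolocation recordings
with a compact convolutional network, in plain R.

Bats emit ultrasonic navigation pulses (roughly 9–200 kHz) whose sweep
shape, frequency band and repetition rate differ between species, so a
spectrogram of a short recording carries a species signature. Passive
acoustic monitoring stations record this audio at 384 kHz and need an
on-device classifier small enough for a battery-powered field unit.
`echoscope` implements that pipeline end to end for researchers in
bioacoustic monitoring:

* **Synthetic call generation** — parametric frequency-modulated (FM),
  constant-frequency (CF) and FM–CF pulse trains in calibrated Gaussian
  noise, standing in for restricted field data
  (`call_template()`, `generate_dataset()`, WAV export).
* **Feature pipeline** — sample-rate relabelling (time expansion),
  3-s segmentation, Hann STFT (25 ms window / 10 ms hop), 128 mel-scaled
  filter banks (MSFB), 20 MFCCs, and rendering to the `112 × 170 × 3`
  model input image.
* **Compact CNN** — a declarative 204,256-parameter architecture
  (203,648 trainable) with closed-form parameter counting, minibatch
  Adam training (batch 8, learning rate 0.003), early stopping, and
  8-bit quantised export. The convolution/pooling kernels are compiled
  RcppArmadillo; no external deep-learning framework is used.
* **Dataset preparation** — stratified train/validation/test splitting
  and SMOTE oversampling to equalised class counts.
* **Semi-supervised GAN** — a dual-head discriminator sharing the
  classifier backbone (`C_out` softmax head, `D_out` real/fake score
  `Z/(Z+1)` over the class logits) and the reference 15.7M-parameter
  generator, with a labelled-fraction sweep experiment.
* **Evaluation** — per-class precision/recall/F1
  (`F1 = 2PR/(P+R)`), confusion matrices, macro F1, and one-vs-one
  pairwise ROC AUC by the Mann–Whitney rank statistic.
* **Edge utilities** — a streaming detection loop, the
  `"code,lat,lon"` serial payload codec with ISO 8601 timestamps, and
  battery-budget arithmetic.

## Worked example

Generate a four-species synthetic dataset, train the compact classifier
and evaluate it:

```r
library(echoscope)

templates <- bat_call_templates()[c("T_perforatus", "R_nasutus",
                                    "P_kuhli", "M_emarginatus")]
dataset <- generate_dataset(templates, rep(60L, 4), seed = 1L, snr_db = 20)
imd     <- dataset_to_images(dataset)
split   <- stratified_split(imd$labels, test_frac = 0.10,
                            val_frac_of_remainder = 0.20, seed = 2L)

fit <- train_classifier(build_classifier_spec(n_classes = 4L),
                        imd$images, imd$labels,
                        train_config(max_epochs = 30L, early_stop_patience = 5L,
                                     min_delta = 1e-3, seed = 3L),
                        split = split)
report <- evaluate_model(fit$model,
                         imd$images[, , , split$test_idx, drop = FALSE],
                         imd$labels[split$test_idx])
report
#> <eval_report> accuracy 1.000, macro F1 1.000
#>          class precision recall f1
#>   T_perforatus         1      1  1
#>      R_nasutus         1      1  1
#>        P_kuhli         1      1  1
#>  M_emarginatus         1      1  1
```

Accuracy 1.000 means every held-out test segment was assigned its true
species; the per-class rows confirm no class is traded off against
another, and with four well-separated synthetic sweep bands at 20 dB SNR
this is the expected outcome. Architecture arithmetic is available
without training:

```r
count_parameters(build_classifier_spec())$total
#> [1] 204256
battery_life_hours(power_budget(528, 5, 50, 0.5))
#> $full_hours
#> [1] 94
#> $derated_hours
#> [1] 47
```

(A 528 mA draw at 5 V against a 50 Ah bank is 250 Wh / 2.64 W ≈ 94 h of
runtime, halved by the conservative derating.)

## Command line

A thin CLI over the same functions ships in `inst/cli/echoscope.R`:

```sh
Rscript inst/cli/echoscope.R simulate --out sim/ --seed 1 --per-class 5
Rscript inst/cli/echoscope.R battery --ma 528 --v 5 --ah 50
```
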