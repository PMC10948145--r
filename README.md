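# apodetect

Spatiotemporal detection of apoptotic cell death in label-free time-lapse
microscopy. The pipeline is: quantile normalization → per-frame region
proposal → temporal-clip classification with a Conv-Transformer →
probability thresholding → per-frame non-maximum suppression → centroid
tracking → event extraction → evaluation metrics and dose–response
analysis. Everything — including the classifier's forward/backward passes
and a ground-truthed synthetic movie generator — is implemented in this
package (R with Rcpp/Armadillo kernels), so the whole system trains, runs
and scores itself with no external data or deep-learning framework.

See `vignettes/apodetect-methods.Rmd` for the methods and numerical
conventions.

## Worked example

Train a compact classifier on a synthetic clip library, then detect
apoptoses in a held-out synthetic movie with ground truth (all numbers
below are the actual output of these commands on one CPU):

```r
library(apodetect)

# 1. clip library: 500 apoptotic + 500 negative 5x59x59 clips
#    (a quarter of the negatives are time-reversed apoptotic clips)
lib <- generate_clip_library(
  synth_config(H = 160L, W = 160L, T = 60L, n_cells = 40L,
               n_apoptoses = 12L, seed = 301L),
  n_per_class = 500L)
split <- assemble_training_set(
  apodetect:::clip_set_subset(lib, which(lib$label == 1L)),
  apodetect:::clip_set_subset(lib, which(lib$label == 0L)),
  seed = 303L)

# 2. train (~9.5 min)
model <- build_model(model_config_compact(), seed = 305L)
model <- train_model(model, split$train, split$val,
                     train_config(lr = 1e-3, epochs = 20L, seed = 307L))
max(model$history$val_acc)
#> [1] 0.9916667

# 3. detect on a held-out movie (256x256, 100 frames, 100 cells,
#    30 planted apoptoses; ~5.6 min)
sm  <- generate_movie(synth_config(seed = 401L))
det <- detect_events(sm$movie, model, pipeline_config())
trk <- track_detections(det)
ev  <- tracks_to_events(trk)
evaluate_events(ev, sm$truth, sm$movie)
#> evaluation: TPR 1.000, FPR 0.062 (32 pred / 30 truth)
#>   spatial error 1.22 px, temporal offset 1.80 frames (|.|=1.87)
#>   cumulative-curve Pearson r 0.9952, TRA NA
```

Dose–response on cumulative event counts:

```r
doses  <- c(0, 0.5, 1, 2, 4, 8, 16, 32)
counts <- c(2, 11.1, 18.0, 29.3, 42.0, 55.3, 66.0, 73.1)
fit <- fit_4pl(doses, counts)
project_response(fit, c(0, 4, 64))
```

## Command line

`inst/cli/apodetect` wraps the exported functions:

```sh
apodetect synth --seed 5 --T 100 --out movie.tif --truth truth.csv
apodetect train --lib libdir --out model.rds --epochs 20 --lr 1e-3
apodetect detect --in movie.tif --model model.rds --out det.csv
apodetect track --in det.csv --out tracks.csv
apodetect evaluate --tracks tracks.csv --truth truth.csv --T 100 \
    --H 256 --W 256 --out report.json
apodetect end2end --seed 1 --out report.json
```

Exit codes: 0 success, 2 usage error, 1 runtime failure. Flat
`key = value` config files are accepted via `--config`; flags override
the file, which overrides defaults.

## Reproduction

All results above, and the package's own correctness claims, reproduce
from a clean checkout (single CPU, times observed on one core):

```sh
# install (compiles the Rcpp kernels)
R CMD INSTALL --no-docs --no-html --no-help .

# full test suite against the installed package (~17 min):
# per-module unit/property tests plus an acceptance file covering
# oracle-checked NMS and normalization, tracker identity and gap rules,
# classifier accuracy and temporal sensitivity, end-to-end detection,
# augmentation identity, metric fixed points, 4PL recovery and
# whole-pipeline determinism
NOT_CRAN=true Rscript -e 'testthat::test_dir("tests/testthat",
    package = "apodetect", load_package = "installed")'

# standalone acceptance report (~11 min)
Rscript scripts/acceptance.R --seed 1 --out report.json
```

`scripts/acceptance.R --seed 1` retrains from scratch at a reduced scale
(400 clips/class, 15 epochs, 192×192×80 evaluation movie) and printed:

```
nms_oracle_agreement            1.000   (n = 200 frames)
normalization_oracle_agreement  1.000   (n = 81,920 values)
classifier_val_accuracy         0.8125  (n = 96)
reversal_probability_shift      0.4732  (n = 45)
event_tpr                       0.889   (n = 18 truth events)
event_fpr                       0.059   (n = 17 predictions)
mean_spatial_error_px           1.385   (n = 16 matches)
mean_abs_temporal_offset_frames 1.3125  (n = 16 matches)
cumulative_pearson_r            0.9934  (n = 80 frames)
nn_mean_distance_px             1.52    (baseline 22.99)
fourpl_noise_free_max_param_error 2.7e-15
ec50_median_relative_error      0.063   (n = 200 simulations)
```

The held-out accuracy at that reduced training scale (0.8125, on a
96-clip validation set) is lower than at the full 500-clips/class,
20-epoch scale used in the worked example (0.9917); detection quality is
less sensitive because the 0.995 probability threshold rejects low-
confidence windows either way.
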