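# icgdx

Simulation and convolutional classification of multi-sensor impedance
cardiograms, for detecting aortic dissection in virtual patients.

## The problem

Impedance cardiography (ICG) records the time-varying thoracic impedance
over the cardiac cycle through injector/sensor electrode pairs. An aortic
dissection — blood flowing through a pathological secondary channel (the
*false lumen*) in the aortic wall — perturbs that waveform, but the
perturbation is faint per sample and buried in measurement noise, so
detecting it requires pooling evidence across 3 injectors × 5 sensors × 20
time steps. `icgdx` is a complete, reproducible *in silico* pipeline for
studying that detection problem:

* **Virtual-patient generator** — patients parameterised by true-lumen
  radius $R_{TL} \in [1.35, 1.95]$ cm, hematocrit
  $\theta \in [35, 55]$ %, and (diseased only) false-lumen radius
  $R_{FL} \in [3, 15]$ mm and angle $\alpha \in [0, 2\pi)$, all drawn
  uniformly; an analytic surrogate waveform model (healthy half-cycle pulse
  plus a delayed disease pulse growing as $R_{FL}^2$ and modulated
  sensor-wise by $\cos(\alpha - \phi_{is})$); i.i.d. Gaussian noise of
  standard deviation 0.5 on every sample.
* **Branch-fusion 1D CNN** — one convolution branch per injector (9
  filters, kernel 3, stride 1, valid padding, sensors as channels; ReLU,
  dropout 0.2, max-pool 2, flatten), branches concatenated into a 20-unit
  ReLU dense layer and a 2-class softmax: exactly **5354** trainable
  parameters. Forward pass, backpropagation, and reference
  softmax/cross-entropy operations are implemented in vectorised base R
  with no deep-learning framework, and trained by SGD with Nesterov
  momentum (constant learning rate 0.09, mini-batch 34) under loss-based
  early stopping with patience 3.
* **Evaluation** — exact confusion counts, accuracy / sensitivity /
  specificity with mean ± sd over seeded replicates, and the
  accuracy-versus-false-lumen-radius sweep under configurable noise.

Cohorts are tibbles with a list-column of 3 × 5 × 20 signal arrays; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods; everything is
deterministic from integer seeds.

## A worked example

```r
library(icgdx)
cfg <- generator_config()   # calibrated surrogate defaults

train_coh   <- make_cohort(800, 800, noise_std = 0.5, cfg, seed = 1)
monitor_coh <- make_cohort(400, 400, noise_std = 0.5, cfg, seed = 2,
                           split_tag = "validation")
test_coh    <- make_cohort(2000, 2000, noise_std = 0.5, cfg, seed = 3,
                           split_tag = "test")

fit <- train(build_model(model_spec(), init_seed = 4),
             train_coh, monitor_coh, train_config(train_seed = 5))
fit
#> <icg_fit> stopped after epoch 9 (early_stop)
#>   final: train loss 0.1474 / acc 0.9487, monitor loss 0.1782 / acc 0.9287

evaluate(fit$model, test_coh)
#> <icg_eval> n = 4000 | accuracy 0.9355, sensitivity 0.8870, specificity 0.9840
#>   confusion: tp 1774, fn 226, tn 1968, fp 32

sw <- rfl_noise_sweep(fit$model, cfg, rfl_steps = 5, noise_grid = 0.5,
                      n_per_cell = 500, seed = 6)
as.data.frame(sw)
#>   rfl_mm noise_std accuracy   n
#> 1      3       0.5    0.146 500
#> 2      6       0.5    0.994 500
#> 3      9       0.5    1.000 500
#> 4     12       0.5    1.000 500
#> 5     15       0.5    1.000 500
```

Reading the numbers: training stopped after 9 epochs by the patience rule;
on a balanced 4,000-patient test cohort at noise std 0.5 the classifier is
93.6 % accurate, catching 88.7 % of dissections (sensitivity) while
flagging 1.6 % of healthy patients (1 − specificity). The sweep shows why
sensitivity is not higher: a 3 mm false lumen perturbs the signal by only
4 % of the 15 mm signature and is mostly missed, while radii ≥ 6 mm are
detected essentially always — accuracy rises monotonically with the
false-lumen radius, the behaviour the sweep is designed to check.
`autoplot(fit)` and `autoplot(sw)` draw the learning curves and the sweep.

A command-line interface wrapping the same functions
(`simulate` / `train` / `evaluate` / `sweep`) is installed at
`system.file("cli/icgdx.R", package = "icgdx")`.

The methods vignette (`vignettes/icgdx-methods.Rmd`) documents the
surrogate waveform model and its calibration, the architecture arithmetic,
the training and stopping rules, and what the synthetic study does and
does not demonstrate.

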