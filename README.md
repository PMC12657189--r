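# acam — adaptive contrast adjustment for grayscale medical-image classification

Ultrasound image quality varies with the operator, the device and the
patient: contrast settings in particular change from scan to scan, and a
classifier trained on one contrast regime degrades on another. Sonographers
compensate manually — they turn the contrast up or down until the anatomy is
clear, then read the image. `acam` implements that workflow as a learnable,
differentiable preprocessing block for image classifiers, together with
everything needed to study it offline: a seeded ultrasound-phantom
generator, four training modes, and full classification metrics.

It is aimed at researchers studying robustness of medical-image classifiers
to acquisition variability, at desk scale (small images, CPU, minutes).

## The method

The core operation is the mean-preserving linear contrast transform

    I'(x, y) = α · (I(x, y) − μ) + μ,     μ = mean(I),

where the gain `α > 1` stretches and `α < 1` compresses the intensity
spread about the brightness center `μ`. A shallow *texture decision
network* — two strided 3×3 convolutions (1→8→16 channels, softplus), global
average pooling, and one fully connected layer, under 5,000 parameters —
reads the input image and predicts `K` raw values `x_1..x_K`. Each is
mapped into the clinically used gain range by the bounded, strictly
increasing function

    f(x) = 1 + 2 / (1 + e^(−x))  ∈  (1, 3),

and the image is expanded into a `K × H × W` stack of views, one per gain
(`K = 10` by default). The stack feeds the downstream classifier, either as
`K` input channels (default) or by averaging per-view class scores. The
whole path is differentiable in both the pixels and the network
parameters — analytic gradients are implemented exactly and verified
against central finite differences — so the contrast generator trains
jointly with the classifier, learning image-specific contrast "presets"
instead of random jitter.

Two training signals are supported:

* **joint** (`mode = "acam"`): the generator is trained end-to-end through
  the classification loss;
* **two-stage** (`mode = "acam_two_stage"`): the generator is first trained
  to regress the recorded ideal restoring contrast `α* = clamp(1/g, 1, 3)`
  of each contrast-degraded sample (mean-squared error on the mean of the
  `K` gains), then frozen while the classifier trains.

Baselines: `"plain"` (bare backbone) and `"rcj"` (random contrast
jittering, one uniform gain from `[1, 3]` per image per epoch).

## Worked example

```r
library(acam)

spec <- phantom_spec(n_total = 240, size = 32, seed = 42)
ds   <- generate_dataset(spec)

fit <- acam(ds, mode = "acam", config = acam_config(K = 10),
            train = train_config(epochs = 15, batch_size = 16, seed = 1))
fit
#> <acam_fit> mode 'acam', 6 classes
#>   contrast generator: K = 10, 1418 parameters
#>   backbone: 15542 parameters (10 input channels)
#>   trained 15 epochs; final train acc 0.899, test acc 0.722

round(predict(fit, ds$images[[1]], type = "contrast"), 3)
#> 2.882 2.979 2.996 2.973 2.947 2.974 2.993 2.984 2.932 2.979

evaluate(fit, ds, "test")
#> <metrics_report> accuracy 0.7222 over 72 samples
#>  class precision recall     f1    auc     ap support
#>      0    0.5000 0.2500 0.3333 0.9890 0.8042       4
#>      1    1.0000 0.3333 0.5000 0.9192 0.6861       6
#>      2    0.8000 0.4444 0.5714 1.0000 1.0000       9
#>      3    0.7778 0.7000 0.7368 0.9758 0.8408      10
#>      4    0.6957 0.8889 0.7805 0.9784 0.9584      18
#>      5    0.7097 0.8800 0.7857 0.9353 0.9074      25
#> macro    P 0.7472  R 0.5828  F1 0.6180
#> weighted P 0.7395  R 0.7222  F1 0.7019
```

The six phantom classes mimic fetal-ultrasound standard planes (abdomen,
femur, cervix, thorax, brain, other) with fully developed speckle,
operator-style contrast compression of known gain `g`, and brightness
jitter. The first image's ten predicted gains sit near the top of the
(1, 3) range — the generator has learned that these compressed speckle
images classify better with strong contrast restoration. On a test split
whose images receive *unseen, stronger* compression
(`test_gain_range = c(0.25, 0.4)`), the adaptive block beats the plain
backbone consistently across seeds; `tests/testthat/test-acceptance.R`
runs that experiment.

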