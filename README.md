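# latentks

Out-of-distribution (OOD) detection for grayscale medical images by GAN
inversion and Kolmogorov–Smirnov testing.

## The problem

Image-analysis models for chest radiography are usually trained on a single
acquisition view — typically the frontal view. Presented with a lateral
radiograph, such a model fails silently. `latentks` implements a
reconstruction-based detector for this situation, aimed at researchers and
engineers who need a statistically grounded ID/OOD gate in front of a
view-specific model:

1. Train a compact deep-convolutional GAN (generator $G$, discriminator $D$)
   on in-distribution images only.
2. For a test image $X$, reconstruct it by latent-space inversion: minimise
   $L(z) = \tfrac1P \sum_p (G(z)_p - X_p)^2$ over $z$ with Adam, the
   generator frozen. Stop when $L$ first reaches a threshold $\tau$, then
   run a fixed number of extra refinement steps; if $\tau$ is never reached,
   flag the image OOD outright.
3. Otherwise compare the pixel-intensity distributions of $G(\hat z)$ and
   $X$ with the two-sample Kolmogorov–Smirnov statistic
   $D=\sup_x|\hat F_{G(\hat z)}(x)-\hat F_X(x)|$ and flag OOD when the
   asymptotic p-value falls below $\alpha = 0.05$.

The package also ships the two classical comparators this method is usually
judged against (a Canny edge-fraction score and a histogram-intersection
score, each with an F1-maximising threshold search), a procedural phantom
generator producing frontal-like and lateral-like image families so the
whole pipeline is testable without any credentialed data, and an evaluation
harness (threshold sweeps, confusion-matrix metrics with OOD as the positive
class, one-way ANOVA over replicate accuracies).

All numerical machinery — transposed/strided convolutions lowered to GEMM,
batch normalisation, Adam, backpropagation, the ECDF/KS statistics — is
implemented inside the package (R plus a small Rcpp kernel); no deep-learning
runtime is required.

## Worked example

```r
library(latentks)

# two visually distinct phantom families standing in for the two views
train <- generate_dataset(200, 0, phantom_spec("FRONTAL", 64), seed = 11)
test  <- generate_dataset(20, 20, phantom_spec("FRONTAL", 64), seed = 999)

cfg <- gan_config(resolution = 64, base_feature_maps = 12,
                  train_steps = 999, batch_size = 16, seed = 0)
fit <- train_gan(build_gan(cfg), train, cfg)   # ~4-5 min on one CPU
autoplot(fit$trace)                            # adversarial loss curves

inv <- inversion_config(loss_threshold = 0.05, extra_steps = 200,
                        max_steps = 400, restarts = 3, z_seed = 5)
det <- detect_dataset(fit$models, test, inv)
dplyr::count(det, label, is_ood)
#> # A tibble: 3 x 3
#>   label   is_ood     n
#>   <chr>   <lgl>  <int>
#> 1 FRONTAL FALSE     18
#> 2 FRONTAL TRUE       2
#> 3 LATERAL TRUE      20

sw <- sweep_detector(fit$models, test, taus = c(0.02, 0.05, 0.1, 0.15, 0.2),
                     extra_steps = 200, base_config = inv)
sw[which.max(sw$accuracy), ]
#> # A tibble: 1 x 6
#>   loss_threshold extra_steps accuracy precision recall    f1
#>            <dbl>       <int>    <dbl>     <dbl>  <dbl> <dbl>
#> 1           0.02         200     0.95     0.909      1 0.952
```

At a tight threshold every held-out lateral fails to reconstruct (mean final
loss ≈ 0.13 against ≈ 0.002 for frontals) and is flagged OOD via the failure
route; frontal reconstructions pass the KS test against their own pixels.
Accuracy 0.95 with precision 0.909 means all 20 laterals were caught at the
cost of flagging 2 of 20 frontals. On the same fixture the classical
baselines reach accuracy ≈ 0.78 (Canny) and ≈ 0.70 (histogram), reproducing
the qualitative ordering GAN > edge-based > histogram-based.

Single images work the same way:

```r
x <- generate_phantom(phantom_spec("LATERAL", 64, seed = 3))
d <- detect_ood(fit$models, x, inv)
tidy(d)
#> # A tibble: 1 x 5
#>   is_ood p.value statistic  loss failure_mode
#>   <lgl>    <dbl>     <dbl> <dbl> <chr>
#> 1 TRUE    0.0344    0.0315 0.121 THRESHOLD_NOT_REACHED
```

A command-line front end covers the same pipeline
(`latentks synth | train | detect | baseline | evaluate`); see
`?run_command`.

## Package layout

- `R/phantom.R` — procedural frontal/lateral phantom generator
- `R/gan.R`, `R/nn.R`, `src/convtools.cpp` — GAN, training, network kernels
- `R/invert.R` — latent inversion and the OOD decision
- `R/ks.R` — ECDF, two-sample KS, one-way ANOVA
- `R/baselines.R`, `R/canny.R` — classical comparators
- `R/metrics.R` — confusion-matrix metrics, sweeps, replicate ANOVA
- `R/cli.R`, `exec/latentks` — command-line front end
- `vignettes/latentks-methods.Rmd` — model, assumptions, design choices
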