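# switchgan

Unpaired cross-contrast MRI synthesis with a **switchable CycleGAN**: a
single U-net generator whose nine adaptive instance normalization (AdaIN)
sites are driven by a domain code γ, so one network translates in both
directions —

```
G_{A→B}(x) = G(x; F(0)),        G_{B→A}(y) = G(y; F(1)),
F(γ) = (1−γ)·[1; 0] + γ·[σ_B; μ_B]
```

with learned domain-B moments (σ_B, μ_B) from a light-weight style coder.
Compared with the classical two-generator CycleGAN, the switchable model
trains roughly half the parameters (53% at the default width, coder
included) while optimizing the same objective

```
L_total = λ_adv·L_adv + λ_cyc·L_cyc + λ_id·L_id,     (λ_cyc, λ_id, λ_adv) = (10, 5, 1)
```

with least-squares (LSGAN) adversarial terms against PatchGAN
discriminators, L1 cycle-consistency, and L1 identity losses.

The package is aimed at researchers studying unpaired medical image
translation who want a fully inspectable, CPU-runnable implementation: the
convolutions, transposed convolutions, AdaIN, batch normalization and Adam
are implemented in the package itself (im2col/col2im C++ kernels + BLAS,
hand-derived backward passes), with no deep-learning framework dependency.
A registered two-contrast brain-phantom simulator stands in for MRI data,
so every mechanism — the γ switch, the losses, the replay buffer, the
schedule, PSNR/SSIM evaluation and the Wilcoxon signed-rank model
comparison — is trainable and testable without any download.

## Worked example

Simulate registered phantoms, train the switchable model at toy scale, and
evaluate on held-out registered pairs:

```r
library(switchgan)

man <- generate_dataset(n_subjects = 60, slices_per_subject = 5,
                        phantom_config(size = 64), master_seed = 99) |>
  subsample_manifest(400, seed = 7)          # 200 training slices per domain

fit <- train_translation(
  man, model = "switchable",
  config = train_config(epochs = 10, crop = 64, decay_start_epoch = 10, seed = 123),
  gen_config = generator_config(base_channels = 8),
  disc_base_channels = 4
)

ev <- synthesize_test_pairs(fit, man) |> evaluate_synthesis()
summary(ev)
#> # A tibble: 2 × 6
#>   direction     n psnr_mean psnr_sd ssim_mean ssim_sd
#>   <chr>     <int>     <dbl>   <dbl>     <dbl>   <dbl>
#> 1 a2b          60      13.7   0.302     0.122  0.0259
#> 2 b2a          60      16.7   0.764     0.407  0.0471
```

Each row summarizes one synthesis direction over the 60 registered test
pairs: `a2b` synthesizes the T2-like contrast from the T1-like input. The
SSIM of the input itself against the registered target (the "do nothing"
baseline) is 0.024 in both directions here, so ten CPU epochs already learn
a genuine cross-contrast mapping in each direction (the γ = 1 side, with
its learned style moments, converges faster at this scale). `tidy(ev)` exposes the per-image records;
`paired_signed_rank()` compares two models on them, and

```r
bm <- run_benchmark(man, sizes = c(50, 200),
                    config = train_config(epochs = 2, crop = 64,
                                          decay_start_epoch = 2, seed = 5),
                    gen_config = generator_config(8), disc_base_channels = 4)
glance(bm); compare_methods(bm, "ssim")
```

runs the dataset-size robustness comparison (switchable vs two-generator
baseline) end to end. `autoplot(fit)` plots the loss log, `plot_slice()`
renders slices, `save_checkpoint()`/`load_checkpoint()` round-trip trained
models, and `inst/scripts/switchgan` exposes
`simulate / train / synthesize / evaluate / benchmark` subcommands for
shell use.

Numbers above were produced by this code at the stated seeds; trained at
published scale (64-channel networks, 128×128 crops, 200 epochs, 30,340
real MRI slices) this model family reports PSNR ≈ 31.7 dB and SSIM ≈ 0.73–0.75 —
desk-scale phantom results are not comparable to those.

## Package layout

- `R/adain.R` — AdaIN transform, instance moments, the switchable style coder
- `R/generator.R`, `R/discriminator.R`, `R/layers.R`, `src/conv_ops.cpp` —
  networks and the layer toolkit with hand-derived backward passes
- `R/losses.R`, `R/trainer.R` — losses, Adam, schedule, buffer, training loop
- `R/phantom.R` — registered two-contrast phantom simulator and manifests
- `R/metrics.R`, `R/benchmark.R` — PSNR/SSIM, summary tables, signed-rank
  comparison, robustness harness
- `R/io.R` — NIfTI/PNG/JSON/YAML interchange, checkpoints
- `vignettes/switchable-cyclegan-methods.Rmd` — the model, the design
  decisions, and what the phantom experiments do and do not show
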