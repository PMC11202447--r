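# metaseg

Few-shot 3D medical image segmentation in R: **model-agnostic
meta-learning (MAML)** wrapped around an **enhanced residual 3D U-Net**,
with NIfTI I/O, CT-style preprocessing, Dice/IoU/95%-Hausdorff
evaluation, a seeded synthetic phantom benchmark, and a command-line
interface.

## Who this is for

Annotated 3D medical images are scarce: a new target organ typically
comes with 5–10 labelled CT volumes. `metaseg` treats each organ as a
*task* and meta-learns an initialization that adapts to an unseen task
from a handful of shots:

1. **Meta-training** — episodic MAML over source tasks. Inner loop:
   `θᵢ′ = θ − α ∇θ L_Tᵢ(f_θ)` on each task's support set (soft Dice
   loss). Outer loop: Adam on `Σᵢ L_Tᵢ(f_θᵢ′)` over the query sets, with
   second-order meta-gradients (or a cheaper first-order switch).
2. **Meta-testing** — fine-tune the learned `θ′` on the k ∈ {5, 10}
   labelled shots of a held-out task.
3. **Final testing** — evaluate `θ″` on unseen volumes of that task:
   DSC = 2|P∩G|/(|P|+|G|), IoU = |P∩G|/|P∪G|, and the 95th-percentile
   symmetric surface distance in mm (HD95).

The backbone is a five-level residual 3D U-Net (stride-2 convolutions
down, stride-2 transpose convolutions up, residual units, PReLU,
affine instance normalization, dropout 0.1) with exactly **4,808,917**
learnable parameters in its default configuration. The volumetric
network engine — convolutions, adjoints, normalizations, the lot — is
implemented in the package (Rcpp im2col/col2im + BLAS), since no
tensor framework exists for R in this stack.

Because the original CT corpora are not redistributable, the package
ships a seeded phantom generator: four task families (lobed blob,
capsule, two lateralized ellipsoids) with CT-like windowed contrast and
per-subject variability, so the entire pipeline runs and is tested at
desk scale without any download.

## Worked example

Meta-train on three phantom families at 32³, then 5-shot fine-tune on
the held-out family (desk-scale settings; ~2 min on one CPU):

```r
library(metaseg)

build_backbone(backbone_config(), rng_seed = 1)
#> <backbone_state> channels (16,32,64,128,256), strides (2,2,2,2), 2 residual unit(s), instance norm, dropout 0.1
#>   4,808,917 learnable parameters

plan <- build_plan(holdout_index = 1, k = 5, seed = 101, shape = c(32, 32, 32))
plan
#> <experiment_plan>
#>   meta-train:
#>     splenic      episodes 10/10 from pool of 20, eval 10
#>     renal_r      episodes 10/10 from pool of 20, eval 10
#>     renal_l      episodes 10/10 from pool of 20, eval 10
#>   meta-test:  hepatic      5 shot(s), 10 test image(s)

backbone <- backbone_config(channels = c(4, 8, 16), strides = c(2, 2),
                            num_res_units = 1, dropout = 0.1)
cfg <- meta_config(inner_lr = 0.05, outer_lr = 5e-3, fine_tune_lr = 2e-3,
                   patience_meta_train = 5, max_epochs = 15,
                   patience_fine_tune = 3, fine_tune_max_epochs = 6,
                   first_order = TRUE, seed = 101)
res <- run_experiment(plan, cfg, backbone = backbone)

res$report
#> <metric_report> 10 cases | mean DSC 0.9278, IoU 0.8691, HD95 1.624 mm (0 case(s) excluded)
#> # A tibble: 10 × 4
#>    case         dsc   iou  hd95
#>    <chr>      <dbl> <dbl> <dbl>
#>  1 hepatic_6  0.973 0.948  1.5
#>  2 hepatic_7  0.939 0.886  1.5
#>  3 hepatic_8  0.969 0.940  1.5
#>  ...
```

A mean DSC of 0.93 on ten unseen volumes of a family never shown during
meta-training, reached from five labelled shots, is the few-shot
adaptation the method is about; the test suite additionally verifies
that the same fine-tuning budget from a *random* initialization does
substantially worse, over five paired seeds. `tidy()`, `glance()` and
`autoplot()` methods are available on reports and training results.
Published defaults (α = 1e-4, β = 1e-6, weight decay 1e-5, patience
20/10) are the `meta_config()` defaults; the settings above are the
documented desk-scale preset.

## Command-line interface

```sh
Rscript inst/cli/metaseg.R simulate   --config cfg.json --out runs/data
Rscript inst/cli/metaseg.R meta-train --config cfg.json --seed 1 --out runs/exp1
Rscript inst/cli/metaseg.R meta-test  --config cfg.json --checkpoint runs/exp1/checkpoint_best.rds --shots 5
Rscript inst/cli/metaseg.R evaluate   --pred preds/ --gt labels/ --out runs/eval
```

The JSON config mirrors the hyperparameter names (alpha, beta,
weight decay, dropout, batch size, patience); every run writes its
resolved config, history CSV and checkpoints to its output directory,
and NIfTI task directories can replace the phantom source.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline end to end — phantom task generation, episodic
meta-training, 5-shot fine-tuning on the held-out task, and final
DSC/IoU/HD95 evaluation — printing a summary and writing the result
manifest to `--out`.

See `vignettes/metaseg-methods.Rmd` for the model, the conventions
adopted where the method description is ambiguous (normalization,
HD95 definition, windowing map, β), the phantom generator's scope, and
known limitations.
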