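# hyposeg

Automated segmentation and volumetry of a small midline brain structure
(modelled on the hypothalamus, ~0.8 cm³) and of the intracranial volume
(ICV) from T1-weighted MR volumes — as one seeded, end-to-end R pipeline
that is fully exercisable on built-in synthetic head phantoms.

## Who this is for

Neuroimaging methodologists who want to study the *machinery* of
CNN-based small-structure volumetry — segmentation losses, overlap and
boundary metrics, head-size normalization, outlier-based quality control,
and group-level atrophy statistics — with exact ground truth, controllable
effect sizes and no patient data. The package generates two-group phantom
cohorts with a known atrophy effect, trains a native 2-D encoder–decoder
segmenter per task (structure and ICV), and carries the predictions through
volumetry, QC and statistics.

## The core quantities

For binary masks \(P\) (prediction) and \(G\) (ground truth), per volume:

- Dice \(= 2|P\cap G| / (|P| + |G|)\), IoU \(= |P\cap G|/|P\cup G|\)
  (with \(D = 2J/(1+J)\) identically), precision, recall;
- HD95: the maximum over both directions of the 95th-percentile
  nearest-boundary distance (mm, anisotropic spacing honoured);
- normalized volume
  \(V_{\mathrm{norm}} = V_{\mathrm{struct}} / V_{\mathrm{ICV}} \cdot
  \overline{V}_{\mathrm{ICV}}^{\,\mathrm{(control)}}\);
- QC: per-group Tukey fences \([Q_1 - 1.5\,\mathrm{IQR},\;
  Q_3 + 1.5\,\mathrm{IQR}]\) applied in a fixed cascade
  (empty → ICV → raw volume → normalized volume);
- statistics: Shapiro–Wilk-gated paired t / Wilcoxon signed-rank agreement
  test, pooled-variance unpaired t for the group contrast, Bland–Altman
  limits of agreement with approximate t-based confidence intervals, and the
  percent difference \((\bar{x}_{\mathrm{con}} - \bar{x}_{\mathrm{case}})
  / \bar{x}_{\mathrm{con}} \times 100\).

The segmenter is a configurable "U"-topology encoder–decoder (vgg-like /
resnet-like / inception-like / efficient-like block styles) trained
slice-wise with cross-entropy + soft-Jaccard loss, Adam, and
validation-loss early stopping; convolutions and backpropagation are
implemented natively on BLAS (no deep-learning framework required).

## Worked example

```r
library(hyposeg)

cfg <- run_config(seed = 1)   # 60 + 60 study subjects, desk-scale grids
run <- run_pipeline(cfg)      # simulate -> train -> segment -> QC -> stats
print(run)
```

```
<hyposeg_run> /tmp/.../hyposeg_run_...
  study subjects: 120 (accepted 90.0%)
  mean Dice (target task): 0.964   mean HD95: 0.82 mm
  normalized volume reduction (case vs control): 7.6% (p = 1.84e-07)
```

The cohort was simulated with a 10% case-group volume reduction; the run
recovers a 7.6% reduction in ICV-normalized volumes with a highly
significant pooled-variance t-test, after rejecting 10% of subjects by the
IQR quality-control cascade. Held-out segmentation quality (mean Dice 0.964,
HD95 0.82 mm) and method agreement are also computed:

```r
run$stats$group_summary
#>     group  n     mean       sd   median
#> 1 control 54 229.6452 17.59013 230.4623
#> 2    case 54 212.0983 14.97001 211.0620

run$stats$agreement_test$test_name   # "paired_t" (gate: differences normal)
run$stats$bland_altman               # bias -0.6 mm3, LoA [-15.8, 14.5]
```

All artifacts (NIfTI volumes and masks, metrics CSV, cohort results CSV, QC
summary and stats JSON, provenance with config hash and stage seeds) are
written under `cfg$out_dir`; each stage is independently runnable
(`stage_simulate()`, `stage_train()`, …) and a thin CLI wrapper lives at
`inst/cli/hyposeg.R`.

## Package layout

- `R/phantom.R` — phantom and cohort generators (`generate_phantom()`,
  `generate_cohort()`, `write_cohort()`)
- `R/preprocess.R` — rigid landmark alignment, analysis-block resampling
- `R/augment.R` — contrast-shift augmentation
- `R/layers.R`, `R/unet.R` — the native encoder–decoder and training loop
- `R/metrics.R` — confusion/overlap metrics, HD95, Bland–Altman
- `R/volumetry.R` — mask volumes, ICV normalization, IQR quality control
- `R/group_stats.R` — gated paired tests, unpaired t, percent differences
- `R/pipeline.R` — `run_config()`, stage functions, `run_pipeline()`
- `vignettes/hyposeg-methods.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
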