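# nucmorph

Weakly supervised live/dead classification of neurons from fluorescence
morphology, with a fully synthetic ground-truth world.

## The problem

In longitudinal imaging of neurons, death is scored either by eye (slow,
inconsistent) or with a genetically encoded death indicator (GEDI): a
calcium-sensitive green biosensor that switches on irreversibly when a cell
loses membrane homeostasis. Co-expressing the biosensor with a red
morphology marker gives every cell a ratiometric death readout

    GEDI ratio = mean(death-indicator intensity) / mean(morphology intensity)

that is independent of transfection level. Cells below an empirical
threshold are live, above a second threshold dead, and the ambiguous band in
between is discarded. Those free labels can then train a *biomarker-optimized
CNN* (BO-CNN) that calls death from the morphology image alone — including
from a nuclear-localized marker (NLS), where death shows up as leakage of
nuclear signal into the soma and neurites, an *increase* in fluorescent
area, and a small dense intranuclear punctum, rather than the classical
neurite fragmentation and soma shrinkage of a diffuse marker.

`nucmorph` re-implements this analysis as a reusable, testable pipeline.
Because no raw microscopy is deposited, the package ships a synthetic
two-channel time-lapse simulator whose cells carry complete ground truth
(state, death time, phenotype masks, true ratio); every downstream claim is
tested against that world:

1. **simulate** — two-channel fields, both marker types, stage drift,
   Poisson + Gaussian camera noise (`sim_config()`, `simulate_field()`,
   `simulate_crop_dataset()`, `write_dataset()`)
2. **process** — median background subtraction, phase-correlation
   registration, Otsu segmentation, greedy centroid tracking,
   centroid-centered crops (`process_field()` and stage functions)
3. **label** — GEDI ratios, three-way bucketing at the empirical thresholds
   (diffuse 0.1/0.25, NLS 0.03/0.055), class balancing, stratified
   80/10/10 splits with largest-remainder rounding (`build_labeled_dataset()`)
4. **train** — a residual CNN (native R/C++ engine: im2col + BLAS, Adam,
   batches of 32, lr 1e-3, min-validation-loss checkpoint; `build_model()`,
   `train_model()`), plus zero-shot cross-marker evaluation
5. **attribute** — guided Grad-CAM maps and their enrichment in ground-truth
   phenotype masks (`guided_gradcam()`, `cohort_localization()`)
6. **stats** — precision-recall curves, simulated curator panels with
   majority consensus, one-sample/paired tests against the 50% chance mean,
   and pre/post-treatment area trajectories with Monte-Carlo Dunnett
   comparisons (`pr_curve()`, `simulate_curators()`, `area_trajectory_test()`)

## Worked example

```r
library(nucmorph)

cfg <- sim_config(marker = "nls")
ds  <- simulate_crop_dataset(500, "nls", cfg, seed = 11)
mg  <- measure_crop_means(ds$crops, ds$gedi)
lab <- build_labeled_dataset(ds$crops, mg$mean_gedi, mg$mean_morph,
                             labeling_config("nls"), seed = 11)
table(lab$split)
#> train   val  test
#>   782    98    98

m  <- train_model(build_model(seed = 2), lab, train_config(max_steps = 2000))
te <- which(lab$split == "test")
ev <- evaluate_model(m, lab$crops[, , te], lab$labels[te])
ev$accuracy
#> [1] 1
ev$confusion
#>       pred
#> truth  live dead
#>   live   49    0
#>   dead    0   49
```

A model trained the same way on the diffuse marker scores 0.50 (chance) on
these NLS crops — the zero-shot asymmetry of the original analysis — and
guided Grad-CAM maps of the NLS model enrich the intranuclear punctum
~68x over area for dead calls and the nuclear membrane ~50x for live calls
(`cohort_localization()`; numbers printed by the acceptance suite on these
seeds).

The whole pipeline, both markers, one seed:

```r
s <- run_pipeline(run_config(seed = 1), "runs/demo")
write_report("runs/demo")
```

A CLI wrapper is installed at `inst/cli/nucmorph`
(`nucmorph simulate|process|label|run|report`).

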