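# melachip

Label-free, quantitative grading of 3D pigmented epidermis-on-a-chip models
from brightfield microscopy images.

Pigmented epidermis-on-a-chip cultures (keratinocytes + melanocytes
stratified under air–liquid interface conditions) are a key in vitro
platform for studying melanogenesis, pigmentary disorders and whitening
agents — but judging whether a chip is a usable testing platform is
typically done by eye. `melachip` replaces that judgement with a
reproducible pipeline for lab scientists and image-analysis engineers:

1. **Segmentation** — MEM-ViT, a Vision-Transformer encoder–decoder with a
   U-shaped multi-branch decoder (five skip connections: one raw-image
   branch, four intermediate-token branches), trained with a composite loss
   `L = λ·L_BCE + (1−λ)·L_Dice` (positive-class weight 0.5 in the BCE term),
   Adam (1e-3, β₁ = 0.9, β₂ = 0.99), plateau learning-rate decay (×0.5
   after 10 stagnant epochs) and early stopping. Probability maps are
   binarised at 0.45. The network and all of its backward passes are
   implemented natively in R/C++ and verified against finite differences.
2. **Quantification** — melanin patches are connected components of the
   mask; four indicators are extracted: total patch area
   `A_total = Σ A_i`, mean patch area `A_mean = A_total/N`, transmittance
   `T = I/I₀ × 100%`, and optical density `OD = −log₁₀(I/I₀)`.
3. **Scoring** — each indicator is min–max rescaled to [0, 100] and fused as
   `score = 0.35·A′_total + 0.10·A′_mean + 0.15·T′ + 0.30·OD′`
   (higher = heavier deposition, reachable range [0, 90]); scores at or
   above the cutoff classify the chip as *poor*, below as *good*.
4. **Cohort analysis** — confusion matrix against manual labels, overall
   agreement %, and Pearson correlations between the metrics and the
   labels.

A seeded synthetic brightfield generator emulates both phenotypes (fine
discrete micro-spots vs. large fused islands with ring artifacts) plus
imaging artifacts (illumination gradients, defocus, noise) with exact
ground-truth masks, so the full pipeline trains and tests without any real
data. Everything tabular flows as tibbles and pipes; models and reports have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(melachip)

# 1. simulate a small labelled cohort of brightfield wells
cohort <- generate_cohort(n_good = 6, n_poor = 6, base_seed = 42,
                          image_size = c(128, 128))

# 2. quantify melanin deposition from the masks and score each sample
scores <- cohort |>
  quantify_cohort() |>
  score_samples(cutoff = 45)

# 3. compare the algorithmic calls with the generator's labels
report <- cohort_analysis(scores, scores$label)
```

The scores table shows the four indicators and the fused score per sample:

```
   sample_id label n_patches a_total_px transmittance_pct optical_density  score
 1 sample_0… good         12        344              60.9           0.216  5.81
 4 sample_0… good         12        455              57.8           0.238 13.5
 7 sample_0… poor          1        850              43.5           0.361 58.2
 9 sample_0… poor          2       1165              38.2           0.418 73.6
12 sample_0… poor          3       1676              40.9           0.388 80.9
```

Good wells carry many small patches with high transmittance and low optical
density, so their composite scores sit far below the cutoff; poor wells
fuse into few large dark islands and score high. The cohort report prints
the agreement with the manual labels:

```
<melachip_cohort_report> n = 12, overall agreement 91.7%
         manual
predicted good poor
     good    6    1
     poor    0    5
```

(one borderline poor well scored 28.6 and was called good). To train the
segmentation network itself and run every stage end to end:

```r
res <- run_pipeline(list(
  stages = c("synth", "train", "segment", "evaluate", "quantify", "score",
             "report"),
  synth = list(n_good = 24, n_poor = 24, image_size = c(128, 128)),
  train = list(preset = "tiny", max_epochs = 30)
), out_dir = "runs/demo")

autoplot(res$model)   # loss curves
autoplot(res$report)  # metric/label correlation heatmap
```

A thin command-line wrapper with the same stages lives at
`inst/cli/melachip.R` (`Rscript melachip.R synth --preset good --n 8 --seed 1
--out synth_out`, etc.).

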