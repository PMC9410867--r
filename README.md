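# cfsgunet — rib-fracture detection in chest CT with a dual-attention 3D U-Net

Rib fractures are among the most common findings in chest trauma and among
the most commonly missed on CT: the lesions are small, irregular, and
scattered across hundreds of thin slices. `cfsgunet` implements a complete
segmentation-based detection pipeline for this problem — the CFSG U-Net, a
residual 3D encoder–decoder whose skip connections are refined by
channel-wise fusion attention (CFAM) and whose decoder features are refined
by spatial-wise group attention (SGAM) — together with every stage around
it:

* **Preprocessing**: morphological bone-region extraction from
  Hounsfield-unit volumes (binarize at 180 HU → drop components < 4000 mm³
  → dilate → keep the largest component → fill outside with −300 HU →
  bone-window normalization, level 300 / width 1200, to [0, 1]).
* **Network**: residual 3D U-Net (4 encoder / 3 decoder stages). CFAM
  computes per-channel statistics `s_e, s_d ∈ R^C` of the encoder and
  decoder features by global average pooling and reweights both sides with
  `σ(f_n([s_e, s_d]))` (one 1D convolution, kernel n = 5). SGAM splits
  channels into G = 4 groups, collapses each with a 1×1×1 convolution, and
  reweights each group spatially with `σ(f_7×7×7(s_i))`.
* **Objective**: `L = L_Dice + L_WBCE` with
  `L_Dice = 1 − 2Σyŷ/(Σy + Σŷ)` and
  `L_WBCE = −mean[α·y·log ŷ + (1−y)·log(1−ŷ)]`, α = 5; Adam, 60/40
  positive/negative patch sampling, flip/rotation/scale augmentation.
* **Inference**: 96³ sliding window with stride 48, background windows
  skipped, overlap-averaged fusion; proposals are connected components of
  the map thresholded at 0.4, minus components under 300 voxels, scored by
  mean fused probability.
* **Evaluation**: FROC — greedy one-to-one matching at voxel IoU > 0.2,
  sensitivity at 0.5/1/2/4/8 FPs per scan and their mean.
* **Phantoms**: a synthetic thorax generator (spine-connected ribcage,
  sternum, debris, cortical-notch lesions with ground-truth masks) so that
  the entire pipeline is testable without clinical data.

The network forward *and* backward passes are implemented natively (Rcpp
kernels plus a small reverse-mode tape); no deep-learning framework is
required. The modelling surface follows the classic R idiom: `cfsg_fit()`
returns a `cfsg_unet` object with `print`, `summary`, `coef`, `plot` and
`predict` methods.

## Worked example

Generate phantoms, preprocess, train a small model, and evaluate detection
on a held-out scan:

```r
library(cfsgunet)

cfg <- phantom_config_easy()                      # 96^3 thorax phantoms
scans <- lapply(1:4, function(i)
  generate_phantom(cfg, seed = i, id = paste0("ph", i)))
pp <- lapply(scans, function(s) preprocess_pipeline(s$volume))

fit <- cfsg_fit(
  x = lapply(pp[1:3], `[[`, "normalized"),
  y = lapply(scans[1:3], `[[`, "gt"),
  model = model_config(base_channels = 4),
  control = train_config(epochs = 5, batch_size = 4, patch_size = 48,
                         patches_per_epoch = 48, lr = 1e-2, seed = 1))
print(fit)
#> Fitted CFSG U-Net rib-fracture detector
#> CFSG U-Net: base 4 channels (4/8/16/32), CFAM on (n=5), SGAM on (G=4), 93047 parameters
#> 5 epochs; final train loss 0.7845; best validation loss 0.7845

props <- predict(fit, pp[[4]]$normalized, type = "proposals",
                 window = 48, step = 24, min_voxels = 20)
ev <- match_scan(props, gt_lesions(scans[[4]]$gt))
print(froc(list(ev)))
#> FROC analysis: 3 lesions over 1 scans
#>  FPs/scan sensitivity (%)
#>       0.5          100.00
#>       1.0          100.00
#>       2.0          100.00
#>       4.0          100.00
#>       8.0          100.00
#> average sensitivity: 100.00%
```

The model prints its architecture (channel widths 4/8/16/32 here; 32/64/128/256
at full scale), the attention settings and the parameter count, then the
training summary. The FROC table lists, for each allowed false-positive
load (FPs/scan), the fraction of true lesions detected — here all three
lesions of the held-out phantom are found with no false positives at any
operating point — and the closing line is the mean over the five operating
points. A few minutes of CPU training suffice on easy phantom lesions; see
`vignette("cfsg-unet-methods")` for what this does and does not demonstrate
about clinical data.

A command-line interface wrapping the same functions ships in
`inst/cli/cfsg`:

```sh
cfsg simulate --n 10 --out data/ --seed 7 --easy
cfsg preprocess --in data/phantom001.nii.gz --out prep.nii.gz
cfsg train --data-dir data/ --out ckpt.rds --epochs 5
cfsg predict --model ckpt.rds --in prep.nii.gz --proposals-out props.json
cfsg evaluate --proposals-dir . --gt-dir data/ --out froc.csv
```

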