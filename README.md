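# segfuse

Multi-class semantic segmentation of laparoscopic scenes is often built
from **one-vs-all binary models**: one network per organ class (uterine
artery, ureter, nerve), each emitting a confidence map
`P_i(x, y) ∈ [0, 1]`. `segfuse` fuses those per-class maps into a single
multi-class label map `P(x, y) ∈ {0, 1, 2, 3}` (0 = background) and
evaluates the result. It is model-agnostic — the maps can come from any
source — and ships a synthetic generator so the whole pipeline runs
without surgical data or trained networks.

Four ensemble operators are provided:

* **Pixel-wise** — background where all confidences fall below the 0.5
  gate, otherwise `argmax_i P_i(x, y)`:

  `P(x,y) = 0 if ∀i P_i(x,y) < 0.5, else argmax_i P_i(x,y)`

* **Weighted pixel-wise** — each member is scaled by its accuracy
  `w_i ∈ (0, 1]` before gate and argmax: `argmax_i w_i P_i(x,y)`.
  Down-weighting a noisy member removes its low-confidence false
  positives.
* **Region-based** — the pixel-wise map's foreground is split into
  connected components (8-connectivity by default) and every component
  `r_k` is relabeled with its majority class:
  `RP(x',y') = argmax_i |{(x',y') ∈ r_k : P(x',y') = i}|`,
  eliminating inconsistent labels inside one structure.
* **Weighted region-based** — the majority relabeling applied to the
  weighted pixel-wise map.

Around the operators: image-level and class-level **Jaccard/Dice**
metrics with explicit handling of classes absent from both maps;
**boundary-polygon rasterization** and mask merging; per-class
**binarization**; label-constrained **512×512 crop augmentation** (24
crops per frame, each holding ≥ 1/3 of the frame's labeled pixels); and
**video-grouped k-fold splitting** that never separates frames of one
video. See the vignette `vignettes/ensemble-fusion.Rmd` for the methods
and design notes.

## Worked example

Simulate a noisy scene, fuse it three ways, and score against the exact
ground truth:

```r
library(segfuse)

cfg <- scenario_config(seed = 2001, confusion_rate = 0.15,
                       false_blob_rate = c(0.5, 0.5, 6),
                       speckle_rate = 0.001)
scn <- generate_scene(cfg)                      # RGB frame + label map
pm  <- simulate_probability_maps(scn$labels, cfg)

rep <- evaluate_dataset(
  list(list(gt = scn$labels, pred = fuse_pixelwise(pm)),
       list(gt = scn$labels, pred = fuse_regionwise(pm)),
       list(gt = scn$labels, pred = fuse_pixelwise_weighted(pm, c(1, 1, 0.6)))),
  ids = c("pixel", "region", "weighted-pixel"))
rep$per_image[, c("image", "jaccard", "dice", "jaccard_1", "jaccard_3")]
```

```
           image jaccard  dice jaccard_1 jaccard_3
1          pixel   0.941 0.970     0.714         0
2         region   0.972 0.986     0.909         0
3 weighted-pixel   0.968 0.984     0.816         0
```

This scene contains one artery (class 1). Cross-class confusion sprinkles
wrong-class pixels inside it, which the pixel-wise argmax keeps
(`jaccard_1 = 0.714`); the region majority vote repairs them
(`0.909`). The class-3 member also fires spurious blobs: they survive
pixel-wise fusion (`jaccard_3 = 0` — predicted support with no ground
truth), and scaling that member by `w_3 = 0.6` pushes its blob
confidences below the 0.5 gate, which lifts the global Jaccard from
0.941 to 0.968. Each `jaccard` row-pair satisfies `j = d/(2 − d)`
exactly.

A command-line front end wraps the same functions
(`inst/cli/segfuse.R`):

```sh
Rscript inst/cli/segfuse.R simulate --n-videos 3 --frames 2 --out data --seed 1
Rscript inst/cli/segfuse.R fuse --method region-weighted \
    --weights 0.9,0.85,0.7 --in data/probs --out fused
Rscript inst/cli/segfuse.R eval --gt data/masks --pred fused --report report.json
```

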