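---
title: "Fusing one-vs-all segmentation maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing one-vs-all segmentation maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segfuse)
```

## The problem

In laparoscopic hysterectomy the surgeon must distinguish the uterine
artery, the ureter and nearby nerves from visual information alone; the
structures are elongated, tubular and easily confused. A practical
segmentation strategy is one-vs-all decomposition: train one binary
segmentation model per organ class, then fuse the resulting per-class
confidence maps $P_i(x, y) \in [0, 1]$ into a single multi-class label map
$P(x, y) \in \{0, 1, 2, 3\}$ (0 = background; 1 = uterine artery,
2 = ureter, 3 = nerve by default). `segfuse` implements that fusion step,
its evaluation, and the data preparation around it. It is model-agnostic:
the confidence maps can come from any source.

## The four fusion operators

**Pixel-wise** (`fuse_pixelwise()`). A pixel is background when every
class confidence lies strictly below the gate $\tau = 0.5$; otherwise it
takes the class of maximal confidence:

$$
P(x,y) =
\begin{cases}
0, & \text{if } \forall i\; P_i(x,y) < \tau,\\
\operatorname*{argmax}_{i} P_i(x,y), & \text{otherwise.}
\end{cases}
$$

The background never competes in the argmax; it arises only from the
gate. A confidence of exactly $\tau$ counts as positive (the strict
inequality belongs to the background case). Argmax ties are broken
deterministically toward the lowest class id; with continuous confidences
ties have measure zero, so the rule matters only for degenerate inputs.

**Weighted pixel-wise** (`fuse_pixelwise_weighted()`). Each member model
is weighted by a scalar $w_i \in (0, 1]$, typically its held-out accuracy
(we suggest the member's binary Dice): every $P_i$ is replaced by
$w_i P_i$ *before* both the gate and the argmax. Down-weighting a noisy
member therefore shrinks its foreground support — spurious responses with
confidence below $\tau / w_i$ drop out — and weakens it in class
competitions. Weights above 1 are rejected because they would lower the
effective gate below $\tau$; weights are otherwise taken verbatim, with no
normalization.

**Region-based** (`fuse_regionwise()`). The pixel-wise output is
binarized into foreground vs background; the maximal connected components
$R = [r_k]$ of that class-agnostic foreground are extracted; every
component is relabeled with the most frequent class it contains:

$$
RP(x', y') = \operatorname*{argmax}_i \left|\{(x', y') \in r_k :
P(x', y') = i\}\right|.
$$

This removes isolated wrong-class pixels inside a single structure: a
connected component is almost always one anatomical object, so it should
carry one label. Majority ties again resolve to the lowest class id. The
foreground support is untouched — only labels inside it change — and
every output component is homogeneous by construction.

**Weighted region-based** (`fuse_regionwise_weighted()`). The same
relabeling applied to the *weighted* pixel-wise map; components are
extracted from the weighted map's foreground, since that is the map being
relabeled.

With all weights equal to 1 the weighted operators are bit-identical to
their unweighted counterparts; the test suite asserts this, along with
exact agreement of all four operators with literal brute-force
evaluations of the rules above on random inputs.

### Connectivity

Components use 8-connectivity by default: the target structures are thin
and curved, and a diagonal step should not sever them. 4-connectivity is
available via the `connectivity` argument everywhere components are
formed. Components are built on a pixel adjacency graph
(`igraph::components()`), which keeps one code path for both settings.

### When region fusion helps — and when it cannot

The majority vote repairs *intra-region* confusion (scattered wrong-class
pixels inside one structure). It cannot help — and actively hurts — when
two structures of different classes merge into one connected component:
the minority class is then voted away entirely. The operator is the right
tool when distinct organs occupy spatially separated supports, which is
the regime the synthetic generator reproduces (see below).

## Evaluation metrics

Global scores treat the two maps as sets of (pixel, label) pairs over all
$N = W \cdot H$ pixels, background included; with $a$ agreeing pixels,

$$
\mathrm{Jaccard}(gt, P) = \frac{a}{2N - a}, \qquad
\mathrm{Dice}(gt, P) = \frac{a}{N},
$$

so global Dice is the pixel agreement rate and the exact identity
$j = d / (2 - d)$ holds per image. Counting background agreement is
deliberate: most of a surgical frame is background, and a map that
hallucinates foreground everywhere should score poorly globally.

Class scores restrict both maps to the binary support of one class $c$:

$$
\mathrm{Jaccard}_c = \frac{|gt_c \cap P_c|}{|gt_c \cup P_c|}, \qquad
\mathrm{Dice}_c = \frac{2\,|gt_c \cap P_c|}{|gt_c| + |P_c|},
$$

with $D_c = 2J_c / (1 + J_c)$ exactly. When class $c$ is absent from both
maps the score is 0/0: we report `NA` and exclude the image from that
class's mean, rather than scoring it 1 (which would inflate rare-class
results) or 0 (which would punish correct absence). Because the
convention is not universal, `evaluate_dataset()` always reports the
defined-image count next to each mean. Aggregation is the unweighted mean
over images; a pooled-pixel alternative
(`aggregation = "pooled"`) is provided but is not the default, since
per-image averaging matches the usual test-set reporting style.

## Data preparation

**Rasterization** (`rasterize_boundary()`). Expert annotations arrive as
closed boundary polygons; masks are their filled interiors. We use the
even-odd rule evaluated at integer pixel centers ((x, y), 0-based, x =
column), with centers lying exactly on an edge counted as foreground.
The choice of fill rule only matters for self-intersecting polygons, and
boundary-inclusion only shifts masks by at most the boundary pixels; both
are fixed here deterministically.

**Merging** (`merge_class_masks()`). Per-class masks merge into one label
map; where annotations overlap, the lowest class id wins
deterministically and the overlap pixel count is attached to the result
so conflicting annotations are visible. `binarize_mask()` inverts the
merge per class (one-vs-all), and for non-overlapping annotations the
rasterize → merge → binarize round trip is exact.

**Crop augmentation** (`slice_crops()`). Multi-class training needs more
images than annotation budgets allow, so each frame is expanded into 24
random 512×512 sub-images. Each crop must contain at least 1/3 *of the
frame's total labeled pixel count* — not "1/3 of the crop labeled",
which a small organ in a 512×512 window could never satisfy. Windows are
drawn by seeded rejection sampling of uniform top-left corners (default
budget 1000 attempts per crop) against a summed-area table of the
foreground; if a draw exhausts its budget, a deterministic fallback takes
the window centered on the foreground centroid (clamped to the image),
or, should that window itself fail the constraint, the window of maximum
labeled coverage, which exists whenever the constraint is satisfiable at
all — unsatisfiable configurations abort with the best achievable
fraction. Duplicate windows are permitted, matching the spirit of random
augmentation.

**Grouped splitting** (`group_split()`). Frames from one video are
near-duplicates; a split that scatters them across folds leaks
information. All frames of a video therefore share one assignment.
Designated test videos are held out entirely; the rest are shuffled
(seeded), then assigned largest-video-first to the currently smallest
fold, greedily balancing image counts. Fold sizes consequently differ by
at most the largest single video.

## The synthetic generator

`generate_scene()` renders 0–3 families of smooth tubular structures
(cubic-spline centerlines of 5 control points, stamped with discs of the
configured half-width) on a textured background, one family per present
class. Defaults: 192×192 scenes, presence probabilities
(0.80, 0.43, 0.25) mirroring the artery ≫ ureter ≫ nerve frequency
imbalance of annotated surgical frames, 1–2 tubes of width 6–14 px per
present class. Structures are placed with at least a one-pixel separation
margin (a candidate is redrawn up to 25 times, then dropped), because
distinct organs co-occur in a frame without sharing pixels; this is also
precisely the regime in which region-based fusion is well posed.
`generate_dataset()` groups frames into synthetic "videos" that share
their structure geometry, with small per-frame control-point jitter —
reproducing the within-video similarity that motivates grouped splitting.

`simulate_probability_maps()` stands in for the trained binary members.
Per class, the binarized ground truth passes through, in order:

1. **Gaussian blur** (`blur_sigma`, default 1.5 px; `EBImage::gblur`) —
   soft, uncertain structure boundaries;
2. **logistic calibration** with slope `calibration_sharpness` (default
   8) around 0.5 — interiors sit near 1, background near 0, without being
   saturated; `Inf` gives hard 0/1 maps;
3. **cross-class confusion** (`confusion_rate`, default 0.1): that
   fraction of *other* classes' support pixels receives a confidently
   wrong response (confidence drawn from U(0.96, 1)), emulating visually
   similar organs — the failure mode the region majority vote repairs;
4. **speckle** (`speckle_rate`, default 0.002): isolated confidence flips
   `p -> 1 - p` in either direction;
5. **false blobs** (`false_blob_rate`, default 1 expected blob per map):
   compact spurious activations with confidence U(0.55, 0.8) on the
   background — the failure mode that down-weighting a member suppresses,
   since `w * 0.8 < 0.5` already for `w < 0.625`.

With every channel off and infinite sharpness (`noiseless_config()`) each
map equals its binarized ground truth exactly, all four operators return
the ground truth bit-for-bit, and every metric equals 1 — the suite
checks this over 20 seeds.

What the generator does *not* emulate: photorealistic tissue appearance,
specular highlights, camera motion, occlusion, and miscalibration
patterns of real networks beyond the parametric family above. Passing
tests therefore demonstrate the correctness and the qualitative behaviour
of the operators, not clinical performance; absolute scores on real
surgical data depend on the trained members and are out of scope here.

## The directional experiment

The package's headline behavioural claim is qualitative: under moderate
intra-region confusion, region-based fusion should beat pixel-wise fusion
on mean class-level Jaccard, and down-weighting a blob-heavy member
should beat unweighted fusion. `scripts/acceptance.R` (and the matching
test) runs 50 scenes at the default geometry with `confusion_rate =
0.15`, `false_blob_rate = (0.5, 0.5, 6)` — a noisy third member — and
weights (1, 1, 0.6) for the weighted arm, then applies one-sided sign
tests (`binom.test`) to the per-scene paired differences at
$\alpha = 0.05$. Both directions hold with large margins (typically
45+ positive differences out of ~49 scenes that contain any structure).

```{r directional, eval = FALSE}
cfg <- scenario_config(seed = 2001, confusion_rate = 0.15,
                       false_blob_rate = c(0.5, 0.5, 6),
                       speckle_rate = 0.001)
scn <- generate_scene(cfg)
pm <- simulate_probability_maps(scn$labels, cfg)
sapply(list(pixel = fuse_pixelwise(pm), region = fuse_regionwise(pm)),
       function(pred) mean(sapply(1:3, function(cc)
         jaccard_class(scn$labels, pred, cc)), na.rm = TRUE))
```

## Numerical and degenerate-input choices

* The gate comparison is `>= threshold` for positivity, i.e. background
  iff all weighted confidences are strictly below the gate.
* Tie-breaks (argmax and majority) always take the lowest class id;
  `max.col(ties.method = "first")` and `which.max` over ascending-id
  columns implement this without a separate code path.
* All-background label maps produce an empty region set and are valid
  fusion outputs; all-background ground truth makes every per-class
  metric undefined while the global metrics remain defined.
* Probability maps are validated to `[0, 1]` on construction; label maps
  to `{0} ∪ class_ids` on every read, naming offending values.
* On-disk formats: 8-bit PNG label masks (lossless), 16-bit TIFF
  probability maps (error ≤ 1/65535, endpoints exact), CSV indices, JSON
  annotations/reports/manifests. `run_pipeline()` writes a manifest
  (config echo, seed, stage timings) sufficient to reproduce a run, and
  output files are never overwritten without `force`.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale: 64×64 random map sets for brute-force oracle
comparisons (100 sets), 72–96 px scenes for recovery and invariant
checks, 50 default-size (192×192) scenes for the directional experiment,
and one full-resolution 1340×648 frame for the crop-augmentation
guarantee. These sizes exercise every code path — component extraction,
rejection sampling, fallbacks — while keeping the whole suite around half
a minute.
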