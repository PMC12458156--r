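---
title: "Few-shot particle picking: model, post-processing and statistical protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot particle picking: model, post-processing and statistical protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fewpick)
```

## The problem

Single-particle cryo-EM reconstructs a protein structure from hundreds of
thousands of noisy 2-D projections ("particles") scattered across
micrographs. Locating those particles is the picking step. It is hard
because micrographs have very low signal-to-noise ratios, particle contrast
varies across the field, particles crowd and overlap, and contaminants
(ice, carbon edges) mimic particles. Supervised pickers need large
annotation budgets; this package implements a *few-shot* alternative: a
large frozen hierarchical image encoder is adapted to a new protein with
lightweight residual adapters trained on as few as 1-10 annotated
micrographs, and the predicted segmentation masks are converted to
coordinates by classical morphological post-processing.

## The adapter model

The encoder is a four-stage hierarchy: stage $i$ processes features of
embedding dimension $d_i$ at spatial scale $s_i$, through $n_i$ transformer
blocks. The reference large layout is $d = (144, 288, 576, 1152)$ with
depths $n = (2, 6, 36, 4)$ at scales $(4, 8, 16, 32)$ and a 1024-px model
input. Every block $j$ of stage $i$ receives an adapter computing

$$\mathrm{feat}^{\text{adapter}}_{(i,j)}
  = W^{\text{shared}} \,\sigma\!\left(W^{\text{unshared}}_{(i,j)}\,
    \mathrm{feat}_{(i,j)}\right),\qquad
\mathrm{feat}^{\text{final}}_{(i,j)} = \mathrm{feat}_{(i,j)} +
  \mathrm{feat}^{\text{adapter}}_{(i,j)},$$

with $\sigma$ the exact GELU ($z\,\Phi(z)$). The adapted feature is then
forwarded through the (frozen) block. The unshared down-projection is
private to each block; the shared up-projection is one object per sharing
group. Because the up-projections initialize at zero, the model starts
*exactly* at the pretrained function (residual identity), and only adapters
plus the small decoder head are ever updated.

**Sharing semantics.** The text description of the architecture calls the
up-projection "common across all adapters", but stages have different
embedding dimensions and the residual sum forces the adapter output
dimension to equal its input dimension, so one literal global matrix cannot
serve stages of width 144 and 1152 at once. We therefore default to one
shared up-projection per stage (`sharing = "per_stage"`), and expose
`sharing = "global"` for layouts whose stages agree on both the embedding
and bottleneck dimension; heterogeneous layouts are rejected with an
explanation. Neither choice is claimed to be the original authors' exact
construction.

**Bottleneck width.** The inner adapter dimension is not specified in the
source description; we use the common adapter-tuning default of
`bottleneck_ratio = 0.25` of the stage width, exposed as a parameter.

**Adapter placement.** One adapter per block, placed before the block
(the adapted feature feeds the block), matching the forward recursion
above. The per-stage adapter counts equal the block depths.

**The test backbone.** The pretrained encoder and mask decoder are
deliberately out of scope (they are multi-hundred-megabyte artifacts).
Any backbone implementing the contract -- stage specs, per-block
transform, freeze flag -- plugs in. The bundled `toy_backbone()` is a
frozen random-weight pyramid: non-overlapping patch embedding, residual
tanh channel-mixing blocks $x + \gamma \tanh(xW + b)$, and mean-pool +
linear stage transitions. It exercises every adapter code path (including
gradient flow through all 48 blocks of the default layout) on one CPU.
`make_stage_specs("toy", toy_scale = 8)` keeps the depths and scales of
the large layout with widths divided by 8. The bundled `toy_decoder()` is
a linear per-pixel head over the normalized input image concatenated with
every stage's feature map upsampled to model resolution -- the smallest
decoder that can fuse multi-scale context with pixel-level evidence.

## Training

Training minimizes class-balanced binary cross-entropy with logits against
ground-truth masks. "Balanced" is interpreted as foreground weighting with
`pos_weight` equal to the background/foreground pixel ratio of each batch
(`pos_weight_mode = "auto"`); fixed and unweighted modes are exposed, since
the source description does not give a formula. The loss is evaluated in
softplus form, so saturated logits cannot overflow.

Optimization is plain Adam. The `paper` profile records the published
settings (batch 2, learning rate 1e-4, up to 4000 epochs, 1024-px inputs).
The `toy` profile -- used by every test and example here -- runs 200 epochs
at learning rate 5e-3 on 96-px inputs: the toy decoder head starts at zero
and has few parameters, so larger steps are appropriate, and 200 epochs
brings the 5-shot toy problem to a loss plateau. No learning-rate schedule
and no augmentation are used because none are described for the original
system. Inputs are normalized by a 1st-99th percentile clip followed by
min-max scaling to $[0,1]$, a robust choice for micrographs with hot
pixels; the original normalization is unspecified.

Gradients are computed by hand-derived reverse-mode differentiation through
the decoder, blocks, transitions and adapters (the test suite checks every
parameter against central finite differences). Only adapter and decoder
parameters are enumerated for updates, which makes the frozen-backbone
contract structural: the suite additionally asserts the backbone is
bit-identical after training.

## Post-processing

A logit map becomes coordinates via:

1. **Binarize** at `logit_threshold` (default 0).
2. **Euclidean distance transform** of the foreground.
3. **Multi-scale peak detection**: local maxima of the distance map under
   disc max-filters with minimum separations `peak_scales` = \{0.5 d,
   0.75 d\} (d = expected particle diameter), merged across scales, with
   near-duplicate seeds collapsed to the highest peak.
4. **Marker-controlled watershed** on the negated distance map (priority
   flood, 8-connected -- 4-connectivity fragments round regions along the
   axes), one region per seed.
5. **Geometric filtering**: region area within `(0.3, 2.5)` times the
   nominal disk area $\pi(d/2)^2$ and circularity $4\pi A/P^2 \ge 0.6$.
   The perimeter $P$ counts exposed 4-neighbour pixel edges scaled by
   $\pi/4$ (the isotropic Crofton correction), so a rasterized disk scores
   near 1 rather than the inflated Manhattan perimeter.
6. **Dual pass**: accepted regions are removed from the mask and steps 2-5
   repeat with the relaxed circularity cutoff 0.4, recovering touching or
   partially occluded particles whose first-pass shapes were distorted.
7. **Deduplication** at `0.5 d`, keeping the larger region on conflicts
   (deterministic). Centers are region centroids, which are robust to
   peak-localization jitter; seed positions are not reported.

The detailed algorithm of the original post-processing stage lives in
unavailable supplementary material; every threshold above is this
package's own default, chosen once from standard practice, exposed in
`postproc_params()`, and *not* claimed to match the original values.

## Evaluation and statistics

Predictions are matched to ground truth one-to-one, greedily by ascending
center distance with matches only within a threshold (default $d/2$ --
the matching rule of the original evaluation is unspecified; this is the
common convention in picking benchmarks). Precision, recall and F1 follow
the usual detection formulas, with degenerate denominators returning
flagged zeros so dataset means stay defined. Particle IoU rasterizes both
coordinate sets as unions of $d$-diameter disks and reports pixel
intersection over union; whether the original IoU is particle-rasterized
or mask-level is ambiguous, and we implement the particle reading of the
overlap formula. Greedy matching can in principle lose one match versus
the optimal assignment; the suite monitors `greedy >= optimal - 1` against
an exhaustive oracle on small configurations.

The comparison harness runs one paired two-sided Wilcoxon signed-rank test
per (competitor, dataset) cell on per-micrograph values. Zero differences
are dropped (Wilcoxon's original treatment; count reported), ties are
mid-ranked; p-values are exact for $N \le 15$ without ties and otherwise
use the tie-corrected normal approximation with continuity correction.
The z sign is positive when the reference method wins. Effect sizes are
reported in both conventions -- $z/N$ exactly as printed in the source
tables, and the conventional $z/\sqrt{N}$ -- because the printed formula
conflicts with the cited rank-biserial convention and the intended one is
unknowable from the text; both are labeled, neither claimed correct.
Benjamini-Hochberg adjustment is applied within each metric family.
Threshold success rates report the fraction of micrographs at or above a
metric cutoff.

## The synthetic-data generator

`simulate_micrograph()` emulates what makes picking hard while keeping
exact ground truth: particles are radially symmetric Gaussian bumps
(sd $= d/4$) truncated at the stated diameter -- a soft-edged,
low-contrast stand-in for projection images that deliberately does not
model CTF or defocus; a configurable fraction of particles is placed
within 0.5-1.0 diameters of an anchor to exercise instance splitting;
per-particle amplitudes jitter multiplicatively; ice-like contaminant
blobs (2-5x amplitude, 0.5-3x radius) reproduce the bright-blob
false-positive hazard; and white Gaussian noise of sd = amplitude/SNR sets
the contrast. Ground truth records exact centers and the exact rasterized
disk-union mask (contaminants excluded). Default conditions (256 px, 40
particles of 20 px, SNR 2, 10% overlap, 2 blobs, 20% jitter) represent a
moderately hard synthetic field; the few-shot studies in the tests use
96-px, 10-particle, SNR-8 fields so that five shots suffice for the toy
backbone. Because point annotations in real datasets do not state a mask
radius, the disk-rendering convention here is a stand-in for however the
original training masks were derived.

What passing tests on these synthetics do *not* show: robustness to CTF
oscillations, structured noise, carbon edges, non-convex particles, or
drifting illumination -- real-data performance claims require real data
and the real pretrained backbone, which plug in through the backbone
contract.

## Numerical choices and degenerate inputs

* Exact GELU (`x * pnorm(x)`), not the tanh approximation, so the scalar
  closed-form tests are exact.
* Seeds: every stochastic routine takes an explicit seed; multi-micrograph
  datasets derive child seeds by a fixed integer mix, keeping runs
  reproducible yet distinct. RNG state of the caller is always restored.
* Constant-intensity images normalize to all-0.5 with a warning and
  proceed.
* Watershed ties (equal heights) resolve by insertion order --
  deterministic across runs and platforms.
* A mask with no background returns its trivial distance map rather than
  erroring; empty masks yield empty particle sets, and empty particle sets
  write valid zero-row STAR files.
* MRC output is mode-2 float32; reading back is exact at float32
  precision, and a written file round-trips bit-identically thereafter.
  Coordinates are 0-based from the top-left pixel with x = column,
  y = row, everywhere.

## Problem sizes used by the checks

The bundled studies are sized for a laptop CPU: the end-to-end acceptance
check trains the toy backbone (dims 18/36/72/144, depths 2/6/36/4, 96-px
input, ~78k trainable parameters) on five synthetic shots for 200 epochs,
then evaluates on five held-out micrographs; the recovery property uses up
to 100 disks per 460-px mask over 20 seeds; the null calibration uses 2000
simulated repetitions at N = 30. These sizes are the package's own choice
of a thorough-but-quick regime.

## Known limitations

* The toy backbone is random, not pretrained: it demonstrates the
  machinery (residual identity, frozen-backbone training, gradient
  locality, end-to-end picking on easy synthetics), not transfer learning.
* The published trainable-parameter total (~3.94 M) depends on the real
  mask decoder and is not reproducible here; `count_trainable_params()`
  reports the analytic count for whatever model is assembled.
* Extreme aggregation or irregular particle shapes violate the
  circularity/area assumptions of the post-processing stage, producing
  merged picks or missed centers -- a known failure mode of this class of
  pipeline.
* `compare_methods()` reproduces the statistical protocol, not the
  original p-values, which would require the original per-micrograph
  results.

## A worked example

```{r example, eval = FALSE}
## five-shot study on synthetic micrographs
simp <- sim_params(image_size = 96, n_particles = 10, particle_diameter = 12,
                   snr = 8, overlap_fraction = 0, n_ice_blobs = 0, seed = 100)
shots <- make_fewshot_dataset(5, simp)

specs <- make_stage_specs("toy", toy_scale = 8)
model <- fewshot_model(toy_backbone(specs, input_size = 96, seed = 11),
                       init_adapters(specs, seed = 12))
pairs <- lapply(shots, function(s)
  list(micrograph = s$micrograph, mask = s$ground_truth$mask))
fit <- train_few_shot(pairs, model, train_config("toy", seed = 1))

held <- simp; held$seed <- 900
test_set <- make_fewshot_dataset(5, held)
pp <- postproc_params(expected_diameter = 12)
rows <- do.call(rbind, lapply(test_set, function(s) {
  picks <- extract_particles(predict_mask(s$micrograph, model), pp)
  evaluate_picks(picks, s$ground_truth$particles, image_size = 96)
}))
aggregate_report(rows[, c("precision", "recall", "f1", "iou")])
```
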