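# fewpick

Few-shot particle picking for cryo-EM micrographs in R.

Single-particle cryo-EM needs the (x, y) centers of hundreds of thousands
of protein projections in extremely noisy micrographs before any 3-D
structure can be reconstructed. Supervised pickers demand large annotation
budgets and generalize poorly to new proteins. `fewpick` implements the
parameter-efficient alternative: a frozen hierarchical image encoder is
adapted to a new protein with lightweight residual bottleneck adapters
trained on 1-10 annotated micrographs, and the predicted segmentation
masks are turned into coordinates by classical morphology.

For block *j* of encoder stage *i*, the adapter computes

    feat_final(i,j) = feat(i,j) + W_shared · σ( W_unshared(i,j) · feat(i,j) )

with σ the exact GELU; the adapted feature is forwarded through the frozen
block. Shared up-projections start at zero, so training starts exactly
from the pretrained function, and only adapters plus a small decoder head
are updated (the backbone is asserted bit-identical after training).
Training minimizes class-balanced binary cross-entropy with logits under
Adam. Masks become particles via Euclidean distance transform →
multi-scale peak detection → marker-controlled watershed → circularity and
area filtering (4πA/P² with a Crofton-corrected perimeter) → a dual-pass
recovery for touching particles. Detection quality is scored by greedy
one-to-one matching (precision, recall, F1) and rasterized particle IoU,
and methods are compared per-micrograph with Wilcoxon signed-rank tests,
rank-biserial effect sizes (both z/N and z/√N conventions), and
Benjamini-Hochberg correction.

The package ships a synthetic micrograph simulator with exact ground
truth (low SNR, overlapping particles, contrast jitter, ice-like blobs),
a miniature frozen backbone + decoder so the whole pipeline runs on one
CPU, and MRC / PNG / TIFF / STAR (RELION-dialect) input and output. The
real pretrained encoder is an optional plug-in behind the backbone
contract; it is not required by anything here.

## Worked example

Train on five synthetic shots, pick on five held-out micrographs:

```r
library(fewpick)

simp <- sim_params(image_size = 96, n_particles = 10, particle_diameter = 12,
                   snr = 8, overlap_fraction = 0, n_ice_blobs = 0, seed = 100)
shots <- make_fewshot_dataset(5, simp)

specs <- make_stage_specs("toy", toy_scale = 8)   # dims 18/36/72/144, depths 2/6/36/4
model <- fewshot_model(toy_backbone(specs, input_size = 96, seed = 11),
                       init_adapters(specs, seed = 12))
count_trainable_params(model)
#> [1] 77752

pairs <- lapply(shots, function(s) list(micrograph = s$micrograph,
                                        mask = s$ground_truth$mask))
fit <- train_few_shot(pairs, model, train_config("toy", seed = 1))
round(range(fit$loss_trace), 3)
#> [1] 0.274 1.272

held <- simp; held$seed <- 900
test_set <- make_fewshot_dataset(5, held)
pp <- postproc_params(expected_diameter = 12)
rows <- do.call(rbind, lapply(test_set, function(s) {
  picks <- extract_particles(predict_mask(s$micrograph, model), pp)
  evaluate_picks(picks, s$ground_truth$particles, image_size = 96)
}))
round(aggregate_report(rows[, c("precision", "recall", "f1", "iou")]), 3)
#>   precision recall    f1   iou
#> 1     0.948      1 0.972 0.846
```

The loss falls from 1.27 to 0.27 over 200 epochs, and the trained model
recovers every held-out particle at 95% precision — mean F1 0.97 and
particle IoU 0.85 against exact synthetic ground truth. Picks can be
written for downstream tools with `write_star()`, and a command-line
front end (`inst/cli/fewpick`) exposes `simulate`, `train`, `pick`,
`evaluate` and `compare` subcommands.

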