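## Hierarchical backbone layout and the miniature test backbone.
##
## The encoder is a four-stage hierarchy: spatial resolution drops and channel
## width grows stage by stage, mirroring hierarchical vision transformers.
## The pretrained encoder itself is out of scope; any backbone satisfying the
## contract below (stage specs + per-block transform + freeze flag) can be
## plugged in. The bundled test backbone is a frozen strided-convolution
## pyramid with random weights: cheap enough for a desk CPU while exercising
## every adapter code path.

#' Describe one encoder stage
#'
#' @param stage_index stage position, 1-based.
#' @param embed_dim channels per token in this stage; positive.
#' @param depth number of transformer blocks (= number of adapters attached).
#' @param spatial_scale downsampling factor of this stage's feature grid
#'   relative to the model input (e.g. 4 means input_size/4 pixels per side).
#' @return an object of class `stage_spec`.
#' @export
stage_spec <- function(stage_index, embed_dim, depth, spatial_scale) {
  if (embed_dim < 1 || depth < 1) {
    stopf("stage_spec: embed_dim and depth must be strictly positive")
  }
  structure(list(stage_index = as.integer(stage_index),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth),
                 spatial_scale = as.integer(spatial_scale)),
            class = "stage_spec")
}

#' Standard stage layouts
#'
#' `paper_large` is the published large hierarchical layout: embedding dims
#' (144, 288, 576, 1152) with per-stage block/adapter counts (2, 6, 36, 4) at
#' spatial scales (4, 8, 16, 32). `toy` keeps the depths and scales but
#' divides every embedding dim by `toy_scale`, giving a model small enough
#' for CPU tests while preserving the hierarchy.
#'
#' @param preset `"paper_large"` or `"toy"`.
#' @param toy_scale integer divisor of all dims (toy preset only).
#' @return list of [stage_spec()] objects.
#' @export
make_stage_specs <- function(preset = c("paper_large", "toy"), toy_scale = 8) {
  preset <- match.arg(preset)
  dims <- c(144L, 288L, 576L, 1152L)
  depths <- c(2L, 6L, 36L, 4L)
  scales <- c(4L, 8L, 16L, 32L)
  if (preset == "toy") {
    if (any(dims %% toy_scale != 0)) {
      stopf("make_stage_specs: toy_scale %d does not divide all stage dims (%s)",
            toy_scale, paste(dims, collapse = ", "))
    }
    dims <- dims %/% toy_scale
  }
  lapply(1:4, function(i) stage_spec(i, dims[i], depths[i], scales[i]))
}

spec_dims <- function(specs) vapply(specs, `[[`, integer(1), "embed_dim")
spec_depths <- function(specs) vapply(specs, `[[`, integer(1), "depth")
spec_scales <- function(specs) vapply(specs, `[[`, integer(1), "spatial_scale")

validate_specs <- function(specs) {
  dims <- spec_dims(specs)
  if (is.unsorted(dims)) stopf("stage dims must be non-decreasing across stages")
  scales <- spec_scales(specs)
  if (length(scales) > 1 && any(scales[-1] %% scales[-length(scales)] != 0)) {
    stopf("each spatial_scale must be an integer multiple of the previous one")
  }
  invisible(specs)
}

#' Build the miniature test backbone
#'
#' A frozen random-weight pyramid implementing the backbone contract:
#' a patch-embedding (non-overlapping `scales[1]` x `scales[1]` patches
#' projected to the first stage's channels), per-block residual tanh
#' transforms `x + gain * tanh(x W + b)`, and mean-pool + linear projections
#' between stages. All weights are fixed at construction; `frozen = TRUE`
#' marks them off-limits to the trainer.
#'
#' @param specs list of [stage_spec()]; see [make_stage_specs()].
#' @param input_size model-space image side in pixels; must be divisible by
#'   the last stage's spatial scale.
#' @param seed RNG seed for the random frozen weights.
#' @param block_gain residual gain of each block transform.
#' @return an object of class `toy_backbone`.
#' @export
toy_backbone <- function(specs, input_size, seed = 1L, block_gain = 0.5) {
  validate_specs(specs)
  scales <- spec_scales(specs)
  if (input_size %% scales[length(scales)] != 0) {
    stopf("input_size %d must be divisible by the final spatial scale %d",
          input_size, scales[length(scales)])
  }
  dims <- spec_dims(specs)
  depths <- spec_depths(specs)
  params <- new.env(parent = emptyenv())
  with_seed(seed, {
    f1 <- scales[1]
    params$patch_W <- matrix(rnorm(f1 * f1 * dims[1], sd = 1 / f1), f1 * f1, dims[1])
    params$patch_b <- numeric(dims[1])
    params$blocks <- lapply(seq_along(specs), function(s) {
      lapply(seq_len(depths[s]), function(j) {
        list(W = matrix(rnorm(dims[s]^2, sd = 1 / sqrt(dims[s])), dims[s], dims[s]),
             b = numeric(dims[s]))
      })
    })
    params$transitions <- lapply(seq_len(length(specs) - 1), function(s) {
      list(W = matrix(rnorm(dims[s] * dims[s + 1], sd = 1 / sqrt(dims[s])),
                      dims[s], dims[s + 1]),
           b = numeric(dims[s + 1]))
    })
  })
  structure(list(specs = specs, input_size = as.integer(input_size),
                 frozen = TRUE, block_gain = block_gain, params = params,
                 seed = as.integer(seed)),
            class = "toy_backbone")
}

#' Snapshot all backbone parameters as one numeric vector
#'
#' Used to assert the frozen-backbone contract: the snapshot must be
#' bit-identical before and after any training run.
#'
#' @param backbone a backbone object.
#' @return numeric vector of all backbone weights.
#' @export
backbone_state <- function(backbone) {
  p <- backbone$params
  unlist(list(p$patch_W, p$patch_b,
              lapply(p$blocks, function(st) lapply(st, function(b) list(b$W, b$b))),
              lapply(p$transitions, function(t) list(t$W, t$b))),
         use.names = FALSE)
}

## ---- internal forward pieces (shared with the trainer's backprop) ----

## Split an H x W matrix into non-overlapping f x f patches, flattened into
## rows ordered column-major over the patch grid.
patchify <- function(x, f) {
  H <- nrow(x); W <- ncol(x)
  Hb <- H %/% f; Wb <- W %/% f
  dim(x) <- c(f, Hb, f, Wb)
  xp <- aperm(x, c(2, 4, 1, 3))
  dim(xp) <- c(Hb * Wb, f * f)
  xp
}

## 2x2 (factor f) mean pooling of a (h*w) x c feature matrix.
pool_mean <- function(feat, h, w, f) {
  c_ <- ncol(feat)
  a <- array(feat, c(h, w, c_))
  dim(a) <- c(f, h %/% f, f, w %/% f, c_)
  ap <- aperm(a, c(2, 4, 5, 1, 3))
  dim(ap) <- c((h %/% f) * (w %/% f) * c_, f * f)
  matrix(rowMeans(ap), ncol = c_)
}

## Backward of pool_mean: spread each parent gradient over its f*f children.
pool_mean_grad <- function(g, h2, w2, f) {
  c_ <- ncol(g)
  a <- array(g / (f * f), c(h2, w2, c_))
  idx_r <- rep(seq_len(h2), each = f)
  idx_c <- rep(seq_len(w2), each = f)
  big <- a[idx_r, idx_c, , drop = FALSE]
  matrix(big, ncol = c_)
}

## Column-major index map for nearest-neighbour upsampling by factor f of an
## h x w grid to (f*h) x (f*w).
upsample_map <- function(h, w, f) {
  rows <- ceiling(seq_len(h * f) / f)
  cols <- ceiling(seq_len(w * f) / f)
  as.vector(outer(rows, (cols - 1) * h, "+"))
}
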