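## Residual bottleneck adapters over a frozen hierarchical backbone.
##
## Each transformer block j of stage i gets an adapter computing
##   feat + W_shared %*% gelu(W_unshared %*% feat)
## where the down-projection W_unshared is private to the block and the
## up-projection W_shared is one object shared across the blocks of a
## sharing group (a stage by default). The residual form guarantees the
## pretrained function at zero-initialized shared weights; sharing is by
## reference (environments), so mutating a shared layer changes every
## adapter in its group.

#' Initialize adapter parameters for a stage layout
#'
#' One unshared down-projection per block (small random init, sd 0.02) and
#' one shared up-projection per sharing group (zero init, so training starts
#' exactly from the frozen backbone's function).
#'
#' With `sharing = "per_stage"` each stage owns one shared up-projection used
#' by all its blocks. With `sharing = "global"` a single up-projection is
#' shared across every block of every stage; the residual sum then requires
#' all stages to agree on both the bottleneck and the embedding dimension,
#' and layouts that do not are rejected.
#'
#' @param specs list of [stage_spec()].
#' @param bottleneck_ratio bottleneck width as a fraction of the stage's
#'   embedding dim, in (0, 1].
#' @param sharing `"per_stage"` (default) or `"global"`.
#' @param seed RNG seed for the unshared-layer init.
#' @return an object of class `adapter_set`: per-stage lists of per-block
#'   parameter environments plus the shared environment(s).
#' @export
init_adapters <- function(specs, bottleneck_ratio = 0.25,
                          sharing = c("per_stage", "global"), seed = 1L) {
  sharing <- match.arg(sharing)
  if (bottleneck_ratio <= 0 || bottleneck_ratio > 1) {
    stopf("init_adapters: bottleneck_ratio must lie in (0, 1], got %g",
          bottleneck_ratio)
  }
  validate_specs(specs)
  dims <- spec_dims(specs)
  bdims <- pmax(1L, as.integer(round(bottleneck_ratio * dims)))
  if (sharing == "global") {
    if (length(unique(bdims)) != 1 || length(unique(dims)) != 1) {
      stopf(paste0(
        "init_adapters: global sharing needs one up-projection valid for every ",
        "stage, but per-stage bottleneck dims are (%s) and embedding dims are ",
        "(%s); the residual sum requires both to match across stages. ",
        "Use sharing = 'per_stage', or a layout with equal dims."),
        paste(bdims, collapse = ", "), paste(dims, collapse = ", "))
    }
  }
  with_seed(seed, {
    shared_env <- function(b, d) {
      e <- new.env(parent = emptyenv())
      e$W <- matrix(0, b, d)   # zero init: adapter == identity at start
      e$b <- numeric(d)
      e
    }
    global_shared <- if (sharing == "global") shared_env(bdims[1], dims[1]) else NULL
    stages <- lapply(seq_along(specs), function(s) {
      sh <- if (sharing == "global") global_shared else shared_env(bdims[s], dims[s])
      blocks <- lapply(seq_len(specs[[s]]$depth), function(j) {
        e <- new.env(parent = emptyenv())
        e$W <- matrix(rnorm(dims[s] * bdims[s], sd = 0.02), dims[s], bdims[s])
        e$b <- numeric(bdims[s])
        e
      })
      list(shared = sh, blocks = blocks, embed_dim = dims[s],
           bottleneck_dim = bdims[s])
    })
    structure(list(stages = stages, sharing = sharing,
                   bottleneck_ratio = bottleneck_ratio),
              class = "adapter_set")
  })
}

## The adapter attached to block j of stage s, as a pair of parameter
## environments.
get_adapter <- function(adapters, s, j) {
  st <- adapters$stages[[s]]
  list(unshared = st$blocks[[j]], shared = st$shared)
}

#' Apply one adapter to a feature map
#'
#' Computes `feat + gelu(feat W_unshared + b_unshared) W_shared + b_shared`
#' (row-vector convention), preserving the input shape. Accepts a plain
#' `n x c` matrix, an `h x w x c` array, or a `batch x h x w x c` array;
#' channels are the last axis and must equal the adapter's input dim.
#'
#' @param adapter an element of an [init_adapters()] set (list with
#'   `unshared` and `shared` parameter environments), e.g. from stage s,
#'   block j.
#' @param feat numeric matrix or array of features.
#' @return object of the same shape as `feat`.
#' @export
adapter_apply <- function(adapter, feat) {
  dims_in <- dim(feat) %||% c(1L, length(feat))
  c_in <- dims_in[length(dims_in)]
  if (nrow(adapter$unshared$W) != c_in) {
    stopf("adapter_apply: feature channels (%d) do not match adapter input dim (%d)",
          c_in, nrow(adapter$unshared$W))
  }
  x <- matrix(feat, ncol = c_in)
  h <- sweep(x %*% adapter$unshared$W, 2, adapter$unshared$b, "+")
  up <- sweep(gelu(h) %*% adapter$shared$W, 2, adapter$shared$b, "+")
  out <- x + up
  dim(out) <- dims_in
  out
}

#' Encode an image through the adapter-augmented backbone
#'
#' For every block: adapter first, then the frozen block transform (the
#' adapted feature is forwarded through the block). Returns the final
#' feature map of each stage at its spatial scale. With all shared adapter
#' weights at zero this reproduces the backbone-only forward pass exactly.
#'
#' @param image a [micrograph()] or numeric matrix; resized to the
#'   backbone's input size if needed (no intensity normalization is applied
#'   here -- see [predict_mask()] for the full inference path).
#' @param backbone a backbone object (e.g. [toy_backbone()]).
#' @param adapters an [init_adapters()] set matching the backbone's specs,
#'   or `NULL` for a backbone-only forward pass.
#' @return list of per-stage feature arrays `h x w x c` (attributes `stage`).
#' @export
encode <- function(image, backbone, adapters = NULL) {
  fw <- encoder_forward(image, backbone, adapters, keep_cache = FALSE)
  fw$stage_outputs
}

## Full forward pass; optionally caches every intermediate needed for
## backprop. Feature matrices are (h*w) x c with pixels in column-major
## order of the h x w grid.
encoder_forward <- function(image, backbone, adapters, keep_cache = FALSE) {
  x <- as_image_matrix(image)
  n_in <- backbone$input_size
  if (nrow(x) != n_in || ncol(x) != n_in) {
    x <- resize_bilinear(x, n_in, n_in)
  }
  specs <- backbone$specs
  if (!is.null(adapters)) {
    a_dims <- vapply(adapters$stages, `[[`, integer(1), "embed_dim")
    if (!identical(a_dims, spec_dims(specs))) {
      stopf("encode: adapter dims (%s) do not match backbone stage dims (%s)",
            paste(a_dims, collapse = ","), paste(spec_dims(specs), collapse = ","))
    }
    n_blocks <- vapply(adapters$stages, function(s) length(s$blocks), integer(1))
    if (!identical(n_blocks, spec_depths(specs))) {
      stopf("encode: adapter block counts do not match backbone depths")
    }
  }
  p <- backbone$params
  scales <- spec_scales(specs)
  depths <- spec_depths(specs)
  gain <- backbone$block_gain
  f1 <- scales[1]
  P <- patchify(x, f1)
  feat <- sweep(P %*% p$patch_W, 2, p$patch_b, "+")
  h <- n_in %/% f1; w <- n_in %/% f1
  cache <- if (keep_cache) list(stages = vector("list", length(specs))) else NULL
  stage_outputs <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    blk_cache <- if (keep_cache) vector("list", depths[s]) else NULL
    for (j in seq_len(depths[s])) {
      a_in <- feat
      if (!is.null(adapters)) {
        ad <- get_adapter(adapters, s, j)
        hpre <- sweep(a_in %*% ad$unshared$W, 2, ad$unshared$b, "+")
        g <- gelu(hpre)
        feat_ad <- a_in + sweep(g %*% ad$shared$W, 2, ad$shared$b, "+")
      } else {
        hpre <- NULL; g <- NULL; feat_ad <- a_in
      }
      bp <- p$blocks[[s]][[j]]
      tpre <- sweep(feat_ad %*% bp$W, 2, bp$b, "+")
      tb <- tanh(tpre)
      feat <- feat_ad + gain * tb
      if (keep_cache) {
        blk_cache[[j]] <- list(a_in = a_in, hpre = hpre, g = g,
                               feat_ad = feat_ad, tb = tb)
      }
    }
    out <- array(feat, c(h, w, ncol(feat)))
    attr(out, "stage") <- s
    stage_outputs[[s]] <- out
    if (keep_cache) {
      cache$stages[[s]] <- list(blocks = blk_cache, h = h, w = w,
                                feat_out = feat)
    }
    if (s < length(specs)) {
      f <- scales[s + 1] %/% scales[s]
      pooled <- pool_mean(feat, h, w, f)
      if (keep_cache) cache$stages[[s]]$pooled <- pooled
      tr <- p$transitions[[s]]
      feat <- sweep(pooled %*% tr$W, 2, tr$b, "+")
      h <- h %/% f; w <- w %/% f
    }
  }
  list(stage_outputs = stage_outputs, cache = cache, image_model = x)
}

#' Count trainable parameters of a model
#'
#' Counts parameters in trainable components only: the adapters (shared
#' layers counted once per sharing group) and the decoder head when
#' trainable, plus the backbone only if it is unfrozen.
#'
#' @param model a [fewshot_model()].
#' @return integer parameter count.
#' @export
count_trainable_params <- function(model) {
  n <- 0L
  seen <- list()
  for (st in model$adapters$stages) {
    for (blk in st$blocks) n <- n + length(blk$W) + length(blk$b)
    already <- any(vapply(seen, identical, logical(1), st$shared))
    if (!already) {
      seen[[length(seen) + 1]] <- st$shared
      n <- n + length(st$shared$W) + length(st$shared$b)
    }
  }
  if (isTRUE(model$decoder$trainable)) {
    n <- n + length(model$decoder$params$w) + length(model$decoder$params$b)
  }
  if (!isTRUE(model$backbone$frozen)) {
    n <- n + length(backbone_state(model$backbone))
  }
  as.integer(n)
}
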