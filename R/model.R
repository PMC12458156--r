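## Model assembly: decoder head + full segmentation model + inference.

#' Build the miniature segmentation decoder
#'
#' A linear per-pixel head over the normalized model-space image plus every
#' stage's feature map upsampled (nearest-neighbour) to model resolution.
#' Output is one logit channel at the model input size. Weights initialize
#' at zero, so an untrained model predicts all-zero logits.
#'
#' @param specs list of [stage_spec()] the features will come from.
#' @param input_size model-space image side in pixels.
#' @param trainable logical; the trainer updates the head only when `TRUE`.
#' @return an object of class `toy_decoder`.
#' @export
toy_decoder <- function(specs, input_size, trainable = TRUE) {
  in_dim <- 1L + sum(spec_dims(specs))
  params <- new.env(parent = emptyenv())
  params$w <- numeric(in_dim)
  params$b <- 0
  structure(list(params = params, in_dim = in_dim,
                 input_size = as.integer(input_size),
                 specs = specs, trainable = isTRUE(trainable)),
            class = "toy_decoder")
}

## Stack [image, upsampled stage features] into the decoder design matrix.
## Returns the matrix plus the per-stage upsample index maps (needed for
## backprop).
decoder_design <- function(decoder, stage_outputs, image_model) {
  n_in <- decoder$input_size
  scales <- spec_scales(decoder$specs)
  cols <- vector("list", length(stage_outputs) + 1)
  cols[[1]] <- matrix(as.vector(image_model), ncol = 1)
  maps <- vector("list", length(stage_outputs))
  for (s in seq_along(stage_outputs)) {
    a <- stage_outputs[[s]]
    h <- dim(a)[1]; w <- dim(a)[2]; c_ <- dim(a)[3]
    f <- n_in %/% h
    maps[[s]] <- upsample_map(h, w, f)
    fm <- matrix(a, ncol = c_)
    cols[[s + 1]] <- fm[maps[[s]], , drop = FALSE]
  }
  list(X = do.call(cbind, cols), maps = maps)
}

decoder_forward <- function(decoder, stage_outputs, image_model) {
  dd <- decoder_design(decoder, stage_outputs, image_model)
  z <- as.vector(dd$X %*% decoder$params$w) + decoder$params$b
  n_in <- decoder$input_size
  list(logits = matrix(z, n_in, n_in), design = dd)
}

#' Assemble a few-shot segmentation model
#'
#' @param backbone a backbone object (e.g. [toy_backbone()]); typically
#'   frozen.
#' @param adapters an [init_adapters()] set matching the backbone.
#' @param decoder a decoder (e.g. [toy_decoder()]); defaults to a fresh toy
#'   decoder for the backbone's layout.
#' @return an object of class `fewpick_model`.
#' @export
fewshot_model <- function(backbone, adapters, decoder = NULL) {
  decoder <- decoder %||% toy_decoder(backbone$specs, backbone$input_size)
  structure(list(backbone = backbone, adapters = adapters, decoder = decoder,
                 input_size = backbone$input_size),
            class = "fewpick_model")
}

#' @export
print.fewpick_model <- function(x, ...) {
  cat(sprintf("<fewpick_model> %d stages, input %d px, %d trainable params (backbone %s)\n",
              length(x$backbone$specs), x$input_size,
              count_trainable_params(x),
              if (isTRUE(x$backbone$frozen)) "frozen" else "unfrozen"))
  invisible(x)
}

#' Predict a segmentation logit map for a micrograph
#'
#' Normalizes intensities (1st-99th percentile clip, then min-max to
#' `[0, 1]`), resizes to the model input size, runs the adapter-augmented
#' encoder and the decoder head, and returns logits at model resolution.
#' The returned matrix carries the native size and model-to-native scale
#' factors as attributes, so coordinates can be mapped back.
#'
#' @param mic a [micrograph()] or numeric matrix.
#' @param model a [fewshot_model()].
#' @return numeric logit matrix (`input_size` x `input_size`) with
#'   attributes `native_size` (rows, cols) and `frame_model` /
#'   `frame_native` ([coord_frame()]s).
#' @export
predict_mask <- function(mic, model) {
  x <- as_image_matrix(mic)
  native <- dim(x)
  xn <- normalize_intensity(x)
  xm <- resize_bilinear(xn, model$input_size, model$input_size)
  fw <- encoder_forward(xm, model$backbone, model$adapters, keep_cache = FALSE)
  dec <- decoder_forward(model$decoder, fw$stage_outputs, fw$image_model)
  logits <- dec$logits
  attr(logits, "native_size") <- native
  attr(logits, "frame_model") <- coord_frame("model", model$input_size,
                                             model$input_size)
  attr(logits, "frame_native") <- coord_frame("native", native[2], native[1])
  logits
}
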