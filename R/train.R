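## Few-shot trainer: class-balanced logistic loss, reverse-mode gradients
## through decoder, blocks and adapters (hand-derived -- the backbone stays
## frozen and only adapter + decoder parameters receive updates), and Adam.

#' Training configuration
#'
#' The `paper` profile carries the published settings (batch size 2, Adam at
#' 1e-4, up to 4000 epochs, 1024-px inputs). The `toy` profile is the
#' desk-scale default used by the test models: far fewer epochs and a larger
#' step size, appropriate for the zero-initialized linear head of the
#' miniature decoder.
#'
#' @param profile `"toy"` or `"paper"`.
#' @param batch_size micrographs per optimization step.
#' @param learning_rate Adam step size.
#' @param max_epochs passes over the training pairs.
#' @param pos_weight_mode `"auto"` (foreground weight = background/foreground
#'   pixel ratio of each batch), `"fixed"` (use `pos_weight`), or `"none"`
#'   (unweighted).
#' @param pos_weight fixed foreground weight when `pos_weight_mode = "fixed"`.
#' @param input_size model-space image side in pixels.
#' @param seed RNG seed controlling shuffling (and hence the whole run).
#' @return an object of class `train_config`.
#' @export
train_config <- function(profile = c("toy", "paper"), batch_size = NULL,
                         learning_rate = NULL, max_epochs = NULL,
                         pos_weight_mode = c("auto", "fixed", "none"),
                         pos_weight = 1, input_size = NULL, seed = 1L) {
  profile <- match.arg(profile)
  pos_weight_mode <- match.arg(pos_weight_mode)
  def <- if (profile == "paper") {
    list(batch_size = 2L, learning_rate = 1e-4, max_epochs = 4000L,
         input_size = 1024L)
  } else {
    list(batch_size = 2L, learning_rate = 5e-3, max_epochs = 200L,
         input_size = 96L)
  }
  cfg <- list(profile = profile,
              batch_size = as.integer(batch_size %||% def$batch_size),
              learning_rate = as.numeric(learning_rate %||% def$learning_rate),
              max_epochs = as.integer(max_epochs %||% def$max_epochs),
              pos_weight_mode = pos_weight_mode,
              pos_weight = as.numeric(pos_weight),
              input_size = as.integer(input_size %||% def$input_size),
              seed = as.integer(seed))
  if (cfg$batch_size < 1) stopf("train_config: batch_size must be >= 1")
  if (cfg$learning_rate <= 0) stopf("train_config: learning_rate must be > 0")
  if (cfg$max_epochs < 1) stopf("train_config: max_epochs must be >= 1")
  if (cfg$pos_weight <= 0) stopf("train_config: pos_weight must be > 0")
  structure(cfg, class = "train_config")
}

#' Class-balanced binary cross-entropy with logits
#'
#' Mean over pixels of
#' `pos_weight * y * softplus(-z) + (1 - y) * softplus(z)`, evaluated in the
#' overflow-safe softplus form (no explicit sigmoid).
#'
#' @param logits numeric matrix of logits.
#' @param target binary mask (logical or 0/1 numeric) of the same shape.
#' @param pos_weight positive scalar weight on foreground pixels.
#' @return scalar loss.
#' @export
bce_logit_loss <- function(logits, target, pos_weight = 1) {
  if (!identical(dim(logits), dim(target))) {
    stopf("bce_logit_loss: logits %s and target %s shapes differ",
          paste(dim(logits), collapse = "x"), paste(dim(target), collapse = "x"))
  }
  if (pos_weight <= 0) stopf("bce_logit_loss: pos_weight must be > 0")
  z <- as.vector(logits)
  y <- as.numeric(as.vector(target))
  mean(pos_weight * y * softplus(-z) + (1 - y) * softplus(z))
}

## d loss / d z (same weighting, mean reduction)
bce_logit_grad <- function(logits, target, pos_weight = 1) {
  z <- as.vector(logits)
  y <- as.numeric(as.vector(target))
  s <- 1 / (1 + exp(-z))
  (-pos_weight * y * (1 - s) + (1 - y) * s) / length(z)
}

## ---- trainable-parameter bookkeeping ----

## Enumerate trainable parameter slots as (environment, field) refs with a
## unique id per environment (shared adapter layers appear once).
collect_trainable <- function(model) {
  refs <- list()
  envs <- list()
  add <- function(e, field) {
    for (k in seq_along(envs)) {
      if (identical(envs[[k]], e)) {
        refs[[length(refs) + 1]] <<- list(env = e, field = field,
                                          key = paste0(k, ".", field))
        return(invisible(NULL))
      }
    }
    envs[[length(envs) + 1]] <<- e
    refs[[length(refs) + 1]] <<- list(env = e, field = field,
                                      key = paste0(length(envs), ".", field))
  }
  seen_shared <- list()
  for (st in model$adapters$stages) {
    for (blk in st$blocks) { add(blk, "W"); add(blk, "b") }
  }
  for (st in model$adapters$stages) {
    already <- any(vapply(seen_shared, identical, logical(1), st$shared))
    if (!already) {
      seen_shared[[length(seen_shared) + 1]] <- st$shared
      add(st$shared, "W"); add(st$shared, "b")
    }
  }
  if (isTRUE(model$decoder$trainable)) {
    add(model$decoder$params, "w"); add(model$decoder$params, "b")
  }
  refs
}

new_grad_store <- function(refs) {
  g <- new.env(parent = emptyenv())
  for (r in refs) g[[r$key]] <- r$env[[r$field]] * 0
  g
}

grad_add <- function(grads, env_key, delta) {
  grads[[env_key]] <- grads[[env_key]] + delta
}

## ---- reverse-mode pass for one image ----

## fw: encoder_forward(..., keep_cache = TRUE); dec: decoder_forward output;
## dlz: d loss / d logit (vector, model pixels). Accumulates into `grads`
## using the key map built by the trainer.
backward_image <- function(model, fw, dec, dlz, grads, keys) {
  decoder <- model$decoder
  specs <- model$backbone$specs
  p <- model$backbone$params
  gain <- model$backbone$block_gain
  X <- dec$design$X
  if (decoder$trainable) {
    grad_add(grads, keys$dec_w, as.vector(crossprod(X, dlz)))
    grad_add(grads, keys$dec_b, sum(dlz))
  }
  w <- decoder$params$w
  dims <- spec_dims(specs)
  S <- length(specs)
  ## decoder gradient reaching each stage's output (column blocks of X;
  ## column 1 is the raw image, which receives no gradient)
  col_at <- 1L
  G_dec <- vector("list", S)
  for (s in seq_len(S)) {
    idx <- (col_at + 1):(col_at + dims[s])
    dU <- tcrossprod(dlz, w[idx])            # npix_model x c_s
    G_dec[[s]] <- rowsum(dU, group = dec$design$maps[[s]], reorder = TRUE)
    col_at <- col_at + dims[s]
  }
  G <- G_dec[[S]]
  for (s in S:1) {
    stc <- fw$cache$stages[[s]]
    ad_stage <- model$adapters$stages[[s]]
    for (j in rev(seq_along(stc$blocks))) {
      bc <- stc$blocks[[j]]
      bp <- p$blocks[[s]][[j]]
      ## block: out = u + gain * tanh(u W + b)
      dtan <- (G * (1 - bc$tb^2)) * gain
      d_feat_ad <- G + tcrossprod(dtan, bp$W)
      ## adapter: u = a + gelu(a Wd + bd) Ws + bs
      sh <- ad_stage$shared
      un <- ad_stage$blocks[[j]]
      grad_add(grads, keys$shared_W[[s]], crossprod(bc$g, d_feat_ad))
      grad_add(grads, keys$shared_b[[s]], colSums(d_feat_ad))
      dg <- tcrossprod(d_feat_ad, sh$W)
      dh <- dg * gelu_grad(bc$hpre)
      grad_add(grads, keys$unshared_W[[s]][[j]], crossprod(bc$a_in, dh))
      grad_add(grads, keys$unshared_b[[s]][[j]], colSums(dh))
      G <- d_feat_ad + tcrossprod(dh, un$W)
    }
    if (s > 1) {
      f <- specs[[s]]$spatial_scale %/% specs[[s - 1]]$spatial_scale
      tr <- p$transitions[[s - 1]]
      dpooled <- tcrossprod(G, tr$W)
      G <- G_dec[[s - 1]] + pool_mean_grad(dpooled, stc$h, stc$w, f)
    }
  }
  invisible(NULL)
}

## Map every (stage, block) parameter to its grad-store key once.
build_key_map <- function(model, refs) {
  key_of <- function(e, field) {
    for (r in refs) if (identical(r$env, e) && r$field == field) return(r$key)
    NULL
  }
  S <- length(model$adapters$stages)
  keys <- list(
    shared_W = lapply(model$adapters$stages, function(st) key_of(st$shared, "W")),
    shared_b = lapply(model$adapters$stages, function(st) key_of(st$shared, "b")),
    unshared_W = lapply(model$adapters$stages, function(st)
      lapply(st$blocks, function(b) key_of(b, "W"))),
    unshared_b = lapply(model$adapters$stages, function(st)
      lapply(st$blocks, function(b) key_of(b, "b")))
  )
  if (isTRUE(model$decoder$trainable)) {
    keys$dec_w <- key_of(model$decoder$params, "w")
    keys$dec_b <- key_of(model$decoder$params, "b")
  }
  keys
}

#' Train a few-shot segmentation model
#'
#' Runs Adam on the adapter and decoder parameters only; the backbone is
#' left untouched (and is asserted frozen). Deterministic given
#' `config$seed`. The model's parameter environments are updated in place
#' and the trained model is also returned.
#'
#' @param pairs list of training shots; each element is a list with elements
#'   `micrograph` (a [micrograph()] or matrix) and `mask` (binary matrix),
#'   as produced by [make_fewshot_dataset()] (`ground_truth$mask`).
#' @param model a [fewshot_model()].
#' @param config a [train_config()].
#' @return an object of class `fewpick_fit`: list with `model`, `loss_trace`
#'   (per-epoch mean loss), `pos_weight_last`, `epochs`.
#' @export
train_few_shot <- function(pairs, model, config = train_config("toy")) {
  if (length(pairs) < 1) stopf("train_few_shot: need at least one training pair")
  if (!isTRUE(model$backbone$frozen)) {
    warning("backbone is not flagged frozen; it will still not be updated")
  }
  n_in <- model$input_size
  if (config$input_size != n_in) {
    warning(sprintf("config input_size (%d) differs from model (%d); using the model's",
                    config$input_size, n_in))
  }
  prep <- lapply(pairs, function(pr) {
    mic <- pr$micrograph %||% pr[[1]]
    msk <- pr$mask %||% pr$ground_truth$mask %||% pr[[2]]
    xm <- resize_bilinear(normalize_intensity(as_image_matrix(mic)), n_in, n_in)
    ym <- resize_nearest(msk * 1, n_in, n_in) > 0.5
    list(x = xm, y = ym)
  })
  refs <- collect_trainable(model)
  keys <- build_key_map(model, refs)
  adam_m <- new_grad_store(refs)
  adam_v <- new_grad_store(refs)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n <- length(prep)
  loss_trace <- numeric(config$max_epochs)
  pw_last <- NA_real_

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_losses <- numeric(0)
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        pw <- switch(config$pos_weight_mode,
          auto = {
            fg <- sum(vapply(idx, function(i) sum(prep[[i]]$y), numeric(1)))
            bg <- sum(vapply(idx, function(i) sum(!prep[[i]]$y), numeric(1)))
            if (fg > 0) bg / fg else 1
          },
          fixed = config$pos_weight,
          none = 1)
        pw_last <- pw
        grads <- new_grad_store(refs)
        for (i in idx) {
          fw <- encoder_forward(prep[[i]]$x, model$backbone, model$adapters,
                                keep_cache = TRUE)
          dec <- decoder_forward(model$decoder, fw$stage_outputs, fw$image_model)
          l <- bce_logit_loss(dec$logits, prep[[i]]$y, pw)
          if (!is.finite(l)) {
            stopf("train_few_shot: non-finite loss (%g) at epoch %d; reduce the learning rate",
                  l, epoch)
          }
          epoch_losses <- c(epoch_losses, l)
          dlz <- bce_logit_grad(dec$logits, prep[[i]]$y, pw)
          backward_image(model, fw, dec, dlz, grads, keys)
        }
        ## Adam step on the batch-mean gradient
        t_step <- t_step + 1L
        bs <- length(idx)
        for (r in refs) {
          g <- grads[[r$key]] / bs
          adam_m[[r$key]] <- b1 * adam_m[[r$key]] + (1 - b1) * g
          adam_v[[r$key]] <- b2 * adam_v[[r$key]] + (1 - b2) * g^2
          mhat <- adam_m[[r$key]] / (1 - b1^t_step)
          vhat <- adam_v[[r$key]] / (1 - b2^t_step)
          r$env[[r$field]] <- r$env[[r$field]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_trace[epoch] <- mean(epoch_losses)
    }
  })
  structure(list(model = model, loss_trace = loss_trace,
                 pos_weight_last = pw_last, epochs = config$max_epochs),
            class = "fewpick_fit")
}

#' @export
print.fewpick_fit <- function(x, ...) {
  cat(sprintf("<fewpick_fit> %d epochs; loss %.4f -> %.4f\n", x$epochs,
              x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
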