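test_that("balanced BCE-with-logits matches closed forms and a brute-force oracle", {
  expect_equal(bce_logit_loss(matrix(0), matrix(1), 1), log(2), tolerance = 1e-12)
  ## saturated logits drive the loss to ~0
  y <- matrix(c(1, 1, 0, 0), 2, 2)
  z <- ifelse(y == 1, 40, -40)
  expect_lt(bce_logit_loss(z, y, 3), 1e-10)
  ## random 8x8 case vs direct per-pixel summation
  set.seed(1)
  z <- matrix(rnorm(64, sd = 3), 8, 8)
  y <- matrix(runif(64) > 0.6, 8, 8)
  pw <- 2.5
  direct <- mean(ifelse(y, -pw * log(1 / (1 + exp(-z))),
                        -log(1 - 1 / (1 + exp(-z)))))
  expect_equal(bce_logit_loss(z, y, pw), direct, tolerance = 1e-9)
  expect_error(bce_logit_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("analytic gradients match finite differences through every layer", {
  set.seed(4)
  model <- tiny_model(input_size = 32, seed = 2)
  for (st in model$adapters$stages) {
    st$shared$W[] <- rnorm(length(st$shared$W), sd = 0.05)
  }
  model$decoder$params$w[] <- rnorm(model$decoder$in_dim, sd = 0.05)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- matrix(runif(32 * 32) > 0.7, 32, 32)
  loss_fn <- function() {
    fw <- fewpick:::encoder_forward(x, model$backbone, model$adapters, TRUE)
    dc <- fewpick:::decoder_forward(model$decoder, fw$stage_outputs, fw$image_model)
    list(l = bce_logit_loss(dc$logits, y, 2), fw = fw, dec = dc)
  }
  r0 <- loss_fn()
  refs <- fewpick:::collect_trainable(model)
  keys <- fewpick:::build_key_map(model, refs)
  grads <- fewpick:::new_grad_store(refs)
  dlz <- fewpick:::bce_logit_grad(r0$dec$logits, y, 2)
  fewpick:::backward_image(model, r0$fw, r0$dec, dlz, grads, keys)
  eps <- 1e-6
  for (r in refs) {
    v <- r$env[[r$field]]
    idx <- sample(length(v), min(3, length(v)))
    for (ii in idx) {
      orig <- v[ii]
      r$env[[r$field]][ii] <- orig + eps; lp <- loss_fn()$l
      r$env[[r$field]][ii] <- orig - eps; lm <- loss_fn()$l
      r$env[[r$field]][ii] <- orig
      fd <- (lp - lm) / (2 * eps)
      expect_equal(grads[[r$key]][ii], fd, tolerance = 1e-4)
    }
  }
})

test_that("few-shot training reduces the loss, is deterministic, and never touches the backbone", {
  set.seed(6)
  p <- sim_params(image_size = 32, n_particles = 4, particle_diameter = 6,
                  snr = 8, overlap_fraction = 0, n_ice_blobs = 0, seed = 21)
  shots <- make_fewshot_dataset(3, p)
  pairs <- lapply(shots, function(s) list(micrograph = s$micrograph,
                                          mask = s$ground_truth$mask))
  cfg <- train_config("toy", max_epochs = 40, input_size = 32, seed = 5)

  model <- tiny_model(input_size = 32, seed = 3)
  before <- backbone_state(model$backbone)
  fit <- train_few_shot(pairs, model, cfg)
  expect_lt(fit$loss_trace[length(fit$loss_trace)], fit$loss_trace[1])
  expect_identical(backbone_state(model$backbone), before)

  ## adapters did move (gradient reaches them through the shared layers)
  moved <- max(abs(model$adapters$stages[[1]]$shared$W))
  expect_gt(moved, 0)

  ## same seed => identical trace and identical trained weights
  model2 <- tiny_model(input_size = 32, seed = 3)
  fit2 <- train_few_shot(pairs, model2, cfg)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  expect_identical(model$decoder$params$w, model2$decoder$params$w)
  expect_identical(model$adapters$stages[[2]]$blocks[[1]]$W,
                   model2$adapters$stages[[2]]$blocks[[1]]$W)

  expect_error(train_few_shot(list(), model, cfg), "pair")
})

test_that("auto pos_weight equals the batch background/foreground ratio", {
  mask <- matrix(FALSE, 32, 32); mask[10:17, 10:17] <- TRUE   # 64 fg, 960 bg
  pairs <- list(list(micrograph = matrix(runif(32 * 32), 32, 32), mask = mask))
  model <- tiny_model(input_size = 32, seed = 4)
  cfg <- train_config("toy", max_epochs = 1, batch_size = 1, input_size = 32, seed = 1)
  fit <- train_few_shot(pairs, model, cfg)
  expect_equal(fit$pos_weight_last, 960 / 64)
})

test_that("prediction maps have the configured size and zero weights give zero logits", {
  model <- tiny_model(input_size = 32, seed = 7)  # zero-init decoder head
  mic <- micrograph(matrix(runif(50 * 70), 50, 70))
  lg <- predict_mask(mic, model)
  expect_equal(dim(lg), c(32L, 32L))
  expect_true(all(lg == 0))
  expect_equal(attr(lg, "native_size"), c(50L, 70L))
  expect_warning(predict_mask(micrograph(matrix(1, 40, 40)), model), "constant")
})

test_that("loss trends downward on a high-SNR toy problem (10-epoch windows)", {
  p <- sim_params(image_size = 32, n_particles = 5, particle_diameter = 6,
                  snr = 10, overlap_fraction = 0, n_ice_blobs = 0, seed = 31)
  shots <- make_fewshot_dataset(2, p)
  pairs <- lapply(shots, function(s) list(micrograph = s$micrograph,
                                          mask = s$ground_truth$mask))
  model <- tiny_model(input_size = 32, seed = 9)
  fit <- train_few_shot(pairs, model,
                        train_config("toy", max_epochs = 60, input_size = 32,
                                     seed = 2))
  win <- colMeans(matrix(fit$loss_trace, nrow = 10))
  expect_true(all(diff(win) < 0))
})
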