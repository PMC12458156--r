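test_that("stage presets reproduce the published layout", {
  specs <- make_stage_specs("paper_large")
  expect_equal(spec_dims <- vapply(specs, `[[`, integer(1), "embed_dim"),
               c(144L, 288L, 576L, 1152L))
  expect_equal(vapply(specs, `[[`, integer(1), "depth"), c(2L, 6L, 36L, 4L))
  expect_equal(specs[[3]]$embed_dim, 576L)
  expect_equal(specs[[3]]$depth, 36L)
  expect_equal(sum(vapply(specs, `[[`, integer(1), "depth")), 2L + 6L + 36L + 4L)

  toy <- make_stage_specs("toy", toy_scale = 8)
  expect_equal(vapply(toy, `[[`, integer(1), "embed_dim"), c(18L, 36L, 72L, 144L))
  expect_equal(vapply(toy, `[[`, integer(1), "depth"), c(2L, 6L, 36L, 4L))
  expect_error(make_stage_specs("toy", toy_scale = 7), "divide")
})

test_that("adapter initialization matches the layout and is deterministic", {
  specs <- make_stage_specs("paper_large")
  ad <- init_adapters(specs, bottleneck_ratio = 0.25, seed = 9)
  n_unshared <- sum(vapply(ad$stages, function(s) length(s$blocks), integer(1)))
  expect_equal(n_unshared, 48L)              # 2 + 6 + 36 + 4
  shared <- lapply(ad$stages, `[[`, "shared")
  expect_equal(length(unique(vapply(shared, function(e)
    format(nrow(e$W) * 1e6 + ncol(e$W)), ""))), 4L)  # 4 distinct shapes
  expect_equal(dim(ad$stages[[3]]$blocks[[1]]$W), c(576L, 144L))

  ad2 <- init_adapters(specs, bottleneck_ratio = 0.25, seed = 9)
  expect_identical(ad$stages[[3]]$blocks[[10]]$W, ad2$stages[[3]]$blocks[[10]]$W)

  ## square unshared layers at ratio 1
  toy <- make_stage_specs("toy", 8)
  adt <- init_adapters(toy, bottleneck_ratio = 1, seed = 1)
  expect_equal(dim(adt$stages[[1]]$blocks[[1]]$W), c(18L, 18L))

  ## global sharing rejected for heterogeneous stage dims
  expect_error(init_adapters(specs, sharing = "global"), "residual")
  ## ...but allowed when all stages agree
  eq <- list(stage_spec(1, 8, 2, 4), stage_spec(2, 8, 2, 8))
  adg <- init_adapters(eq, bottleneck_ratio = 0.5, sharing = "global", seed = 2)
  expect_identical(adg$stages[[1]]$shared, adg$stages[[2]]$shared)
})

test_that("adapter application follows the residual bottleneck formula", {
  ## zero shared layer => exact identity
  specs <- tiny_specs()
  ad <- init_adapters(specs, seed = 3)
  x <- array(rnorm(2 * 8 * 8 * 4), c(2, 8, 8, 4))
  a <- list(unshared = ad$stages[[1]]$blocks[[1]], shared = ad$stages[[1]]$shared)
  expect_identical(adapter_apply(a, x), x)

  ## scalar closed form: 1 + 0.5 * gelu(2), gelu(z) = z * pnorm(z)
  one <- list(stage_spec(1, 1, 1, 4))
  a1 <- init_adapters(one, bottleneck_ratio = 1, seed = 1)
  a1$stages[[1]]$blocks[[1]]$W[] <- 2
  a1$stages[[1]]$shared$W[] <- 0.5
  got <- adapter_apply(list(unshared = a1$stages[[1]]$blocks[[1]],
                            shared = a1$stages[[1]]$shared), matrix(1, 1, 1))
  expect_equal(as.numeric(got), 1 + 0.5 * 2 * pnorm(2), tolerance = 1e-12)

  ## shape preservation with a non-trivial shared layer
  ad$stages[[1]]$shared$W[] <- rnorm(length(ad$stages[[1]]$shared$W), sd = 0.1)
  y <- adapter_apply(a, x)
  expect_equal(dim(y), dim(x))
  expect_gt(max(abs(y - x)), 0)

  ## dimension mismatch rejected
  expect_error(adapter_apply(a, array(0, c(2, 2, 5))), "channels")
})

test_that("shared layers alias across all adapters of their group", {
  specs <- tiny_specs()
  ad <- init_adapters(specs, seed = 5)
  x <- matrix(rnorm(12 * 8), 12, 8)
  a1 <- list(unshared = ad$stages[[2]]$blocks[[1]], shared = ad$stages[[2]]$shared)
  a2 <- list(unshared = ad$stages[[2]]$blocks[[2]], shared = ad$stages[[2]]$shared)
  before1 <- adapter_apply(a1, x); before2 <- adapter_apply(a2, x)
  ad$stages[[2]]$shared$W[1, 1] <- 5   # one mutation...
  after1 <- adapter_apply(a1, x); after2 <- adapter_apply(a2, x)
  expect_gt(max(abs(after1 - before1)), 0)   # ...visible in every block
  expect_gt(max(abs(after2 - before2)), 0)
})

test_that("encode reduces to the backbone-only pass with zero adapters", {
  specs <- tiny_specs()
  bb <- toy_backbone(specs, input_size = 32, seed = 8)
  ad <- init_adapters(specs, seed = 9)
  img <- matrix(runif(32 * 32), 32, 32)
  plain <- encode(img, bb, NULL)
  with_ad <- encode(img, bb, ad)
  expect_identical(plain, with_ad)

  ## deterministic
  expect_identical(encode(img, bb, ad), with_ad)

  ## per-stage spatial dims follow the configured scales
  for (s in seq_along(specs)) {
    expect_equal(dim(with_ad[[s]])[1:2],
                 rep(32L %/% specs[[s]]$spatial_scale, 2))
    expect_equal(dim(with_ad[[s]])[3], specs[[s]]$embed_dim)
  }

  ## mismatched adapters rejected
  other <- init_adapters(make_stage_specs("toy", 8), seed = 1)
  expect_error(encode(img, bb, other), "match")
})

test_that("trainable-parameter count follows closed-form dim arithmetic", {
  specs <- tiny_specs()     # dims (4, 8), depths (1, 2), ratio 0.5 -> b = (2, 4)
  bb <- toy_backbone(specs, input_size = 32, seed = 1)
  ad <- init_adapters(specs, bottleneck_ratio = 0.5, seed = 1)
  model <- fewshot_model(bb, ad)
  expected <- (4 * 2 + 2) + 2 * (8 * 4 + 4) +        # unshared W + b per block
              (2 * 4 + 4) + (4 * 8 + 8) +            # shared per stage
              (1 + 4 + 8) + 1                        # decoder w + b
  expect_equal(count_trainable_params(model), expected)

  ## frozen decoder drops its parameters from the count
  model2 <- fewshot_model(bb, ad, toy_decoder(specs, 32, trainable = FALSE))
  expect_equal(count_trainable_params(model2), expected - (1 + 4 + 8) - 1)

  ## unfreezing the backbone strictly increases the count
  bb2 <- toy_backbone(specs, input_size = 32, seed = 1)
  bb2$frozen <- FALSE
  expect_gt(count_trainable_params(fewshot_model(bb2, ad)),
            count_trainable_params(model))
})
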