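## Shared fixtures and independent oracles for the test suite. Oracles are
## deliberately naive (brute force / enumeration) and never call the code
## paths they check.

## brute-force disk-union rasterizer: loops over every pixel
oracle_rasterize <- function(xs, ys, image_size, diameter) {
  r2 <- (diameter / 2)^2
  m <- matrix(FALSE, image_size, image_size)
  for (i in seq_len(image_size)) {
    for (j in seq_len(image_size)) {
      x <- j - 1; y <- i - 1
      for (k in seq_along(xs)) {
        if ((x - xs[k])^2 + (y - ys[k])^2 <= r2) { m[i, j] <- TRUE; break }
      }
    }
  }
  m
}

## exhaustive Euclidean distance transform: nearest background by all-pairs
oracle_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0) return(matrix(Inf, H, W) * (mask * 1))
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (mask[i, j]) {
        out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
      }
    }
  }
  out
}

## optimal one-to-one assignment TP count by exhaustive enumeration
## (feasible for <= 6 particles per side)
oracle_optimal_tp <- function(pred, gt, threshold) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(0L)
  dd <- sqrt(outer(pred$x, gt$x, "-")^2 + outer(pred$y, gt$y, "-")^2)
  feas <- dd <= threshold
  k <- min(np, ng)
  best <- 0L
  ## enumerate injections from the smaller side into the larger
  if (np <= ng) {
    perms <- all_injections(ng, np)
    for (p in perms) best <- max(best, sum(feas[cbind(seq_len(np), p)]))
  } else {
    perms <- all_injections(np, ng)
    for (p in perms) best <- max(best, sum(feas[cbind(p, seq_len(ng))]))
  }
  best
}

## all ordered selections of `k` distinct values from 1..n
all_injections <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix) {
    if (length(prefix) == k) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in setdiff(seq_len(n), prefix)) rec(c(prefix, v))
  }
  rec(integer(0))
  out
}

## exact two-sided signed-rank p by literal enumeration of all sign patterns
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  all_W <- vapply(0:(2^n - 1), function(m) {
    pos <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))
    sum(r[pos])
  }, numeric(1))
  min(1, 2 * min(mean(all_W <= W_obs), mean(all_W >= W_obs)))
}

## small two-stage layout for fast trainer tests
tiny_specs <- function() list(stage_spec(1, 4, 1, 4), stage_spec(2, 8, 2, 8))

tiny_model <- function(input_size = 32, seed = 2) {
  specs <- tiny_specs()
  bb <- toy_backbone(specs, input_size = input_size, seed = seed)
  ad <- init_adapters(specs, bottleneck_ratio = 0.5, seed = seed + 1)
  fewshot_model(bb, ad)
}

## binary mask -> surrogate logit map
mask_logits <- function(mask) ifelse(mask, 10, -10)
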