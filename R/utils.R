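## Shared numeric helpers.

#' Gaussian-error linear unit
#'
#' Exact GELU, `x * pnorm(x)` (the Gaussian CDF form, not the tanh
#' approximation).
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape.
#' @export
gelu <- function(x) x * pnorm(x)

## d/dx [x * Phi(x)] = Phi(x) + x * phi(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

## log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic child seed for the i-th member of a multi-simulation dataset.
## Linear-congruential mix of (parent seed, index); stays below 2^31.
derive_seed <- function(parent, index) {
  p <- as.double(parent) %% 2147483647
  s <- (p * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(s)
}

## Bilinear resize of a plain numeric matrix (rows = y, cols = x).
resize_bilinear <- function(x, out_h, out_w) {
  if (nrow(x) == out_h && ncol(x) == out_w) return(x)
  as.matrix(EBImage::resize(x, w = out_h, h = out_w, filter = "bilinear"))
}

## Nearest-neighbour resize (used for masks; keeps values binary).
resize_nearest <- function(x, out_h, out_w) {
  if (nrow(x) == out_h && ncol(x) == out_w) return(x)
  as.matrix(EBImage::resize(x, w = out_h, h = out_w, filter = "none"))
}

## Percentile clip (1st-99th) then min-max to [0, 1]. Constant images come
## back as all 0.5 with a warning (degenerate but usable).
normalize_intensity <- function(x, probs = c(0.01, 0.99)) {
  q <- quantile(x, probs = probs, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant-intensity image; normalization is degenerate")
    return(matrix(0.5, nrow(x), ncol(x)))
  }
  x <- pmin(pmax(x, q[1]), q[2])
  (x - q[1]) / (q[2] - q[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
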