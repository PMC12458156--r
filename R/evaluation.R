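## Matching-based detection metrics: greedy one-to-one center matching,
## precision / recall / F1, rasterized particle IoU, and report aggregation.

#' Match predicted to ground-truth particles
#'
#' Greedy one-to-one matching by ascending center distance (deterministic
#' tie-break by prediction index, then ground-truth index); only pairs
#' within `threshold` pixels are eligible. Greedy matching is near-optimal
#' at realistic particle densities; an exhaustive optimal matcher is kept as
#' a test oracle, not used here.
#'
#' @param pred,gt [particle_set()]s in the same coordinate frame.
#' @param threshold maximum center distance for a match, in pixels;
#'   conventionally half the particle diameter.
#' @return an object of class `match_result`: counts `tp`, `fp`, `fn` and a
#'   data frame `pairs` with `pred`, `gt`, `dist`.
#' @export
match_particles <- function(pred, gt, threshold) {
  if (threshold < 0) stopf("match_particles: threshold must be >= 0")
  np <- nrow(pred); ng <- nrow(gt)
  pairs <- data.frame(pred = integer(0), gt = integer(0), dist = numeric(0))
  if (np > 0 && ng > 0) {
    dx <- outer(pred$x, gt$x, "-")
    dy <- outer(pred$y, gt$y, "-")
    dd <- sqrt(dx^2 + dy^2)
    cand <- which(dd <= threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dd[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_p <- logical(np); used_g <- logical(ng)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_g[j]) {
          used_p[i] <- TRUE; used_g[j] <- TRUE
          pairs <- rbind(pairs, data.frame(pred = i, gt = j, dist = dd[i, j]))
        }
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = ng - tp,
                 n_pred = np, n_gt = ng, pairs = pairs,
                 threshold = threshold),
            class = "match_result")
}

degenerate_zero <- function() {
  structure(0, degenerate = TRUE)
}

#' Precision of a match result
#'
#' `TP / (TP + FP)`. With no predictions the result is 0 carrying a
#' `degenerate` attribute (flagged, not an error), so dataset means stay
#' defined.
#'
#' @param match a [match_particles()] result.
#' @return scalar in `[0, 1]`.
#' @export
precision <- function(match) {
  if (match$tp + match$fp == 0) return(degenerate_zero())
  match$tp / (match$tp + match$fp)
}

#' Recall of a match result
#'
#' `TP / (TP + FN)`; 0 with a `degenerate` attribute when there is no ground
#' truth.
#'
#' @param match a [match_particles()] result.
#' @return scalar in `[0, 1]`.
#' @export
recall <- function(match) {
  if (match$tp + match$fn == 0) return(degenerate_zero())
  match$tp / (match$tp + match$fn)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param p,r precision and recall.
#' @return `2 p r / (p + r)`; 0 with a `degenerate` attribute when both are 0.
#' @export
f1 <- function(p, r) {
  p <- as.numeric(p); r <- as.numeric(r)
  if (p + r == 0) return(degenerate_zero())
  2 * p * r / (p + r)
}

## Disk-union rasterizer that clips out-of-bounds disks (unlike the strict
## ground-truth renderer).
rasterize_disks <- function(x, y, image_size, diameter) {
  sz <- as.integer(image_size)
  mask <- matrix(FALSE, sz, sz)
  r <- diameter / 2
  for (k in seq_along(x)) {
    i0 <- max(1, floor(y[k] + 1 - r)); i1 <- min(sz, ceiling(y[k] + 1 + r))
    j0 <- max(1, floor(x[k] + 1 - r)); j1 <- min(sz, ceiling(x[k] + 1 + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    rho2 <- outer(((ii - 1) - y[k])^2, ((jj - 1) - x[k])^2, "+")
    mask[ii, jj] <- mask[ii, jj] | (rho2 <= r^2)
  }
  mask
}

#' Particle-level intersection over union
#'
#' Rasterizes both particle sets as unions of disks of the given diameter
#' and returns `|intersection| / |union|` of the foreground pixels. With an
#' empty union the result is 0 carrying a `degenerate` attribute.
#'
#' @param pred,gt [particle_set()]s in the same frame.
#' @param image_size square image side in pixels.
#' @param diameter disk diameter used for both sets (ground-truth diameter
#'   by convention).
#' @return scalar in `[0, 1]`.
#' @export
particle_iou <- function(pred, gt, image_size, diameter = NULL) {
  diameter <- diameter %||% attr(gt, "diameter")
  mp <- rasterize_disks(pred$x, pred$y, image_size, diameter)
  mg <- rasterize_disks(gt$x, gt$y, image_size, diameter)
  uni <- sum(mp | mg)
  if (uni == 0) return(degenerate_zero())
  sum(mp & mg) / uni
}

#' Per-micrograph detection metrics
#'
#' Convenience wrapper: match, then precision, recall, F1 and particle IoU
#' as a one-row data frame.
#'
#' @param pred,gt [particle_set()]s in the same frame.
#' @param image_size square image side in pixels (for the IoU rasterization).
#' @param diameter particle diameter; defaults to the ground truth's.
#' @param threshold match distance; defaults to `diameter / 2`.
#' @return data frame with columns `precision`, `recall`, `f1`, `iou`,
#'   `tp`, `fp`, `fn`.
#' @export
evaluate_picks <- function(pred, gt, image_size, diameter = NULL,
                           threshold = NULL) {
  diameter <- diameter %||% attr(gt, "diameter")
  threshold <- threshold %||% (diameter / 2)
  m <- match_particles(pred, gt, threshold)
  p <- precision(m); r <- recall(m)
  data.frame(precision = as.numeric(p), recall = as.numeric(r),
             f1 = as.numeric(f1(p, r)),
             iou = as.numeric(particle_iou(pred, gt, image_size, diameter)),
             tp = m$tp, fp = m$fp, fn = m$fn)
}

#' Aggregate per-micrograph metric rows
#'
#' Unweighted arithmetic means of every numeric metric column across rows
#' (micrographs, or per-dataset rows for a grand average).
#'
#' @param rows data frame of per-micrograph metrics.
#' @param columns metric columns to average; defaults to all numeric columns.
#' @return one-row data frame of means.
#' @export
aggregate_report <- function(rows, columns = NULL) {
  if (is.null(rows) || nrow(rows) == 0) {
    stopf("aggregate_report: no rows to aggregate")
  }
  columns <- columns %||% names(rows)[vapply(rows, is.numeric, logical(1))]
  out <- lapply(rows[columns], mean)
  as.data.frame(out)
}
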