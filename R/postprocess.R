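## Mask-to-coordinate post-processing: threshold, Euclidean distance
## transform, multi-scale peak detection, marker-controlled watershed,
## geometric filtering, and a dual-pass recovery strategy for crowded fields.
##
## All defaults here are this package's own; they are exposed in
## postproc_params and discussed in the methods vignette.

#' Post-processing parameters
#'
#' @param expected_diameter expected particle diameter `d` in pixels of the
#'   logit map's space.
#' @param logit_threshold foreground where logit exceeds this value.
#' @param peak_scales minimum peak separations for multi-scale peak
#'   detection, as fractions of `d`.
#' @param area_bounds `(min, max)` region area, as multiples of the nominal
#'   particle area `pi (d/2)^2`.
#' @param circularity_min_pass1 strict circularity (`4 pi A / P^2`) cutoff of
#'   the first pass.
#' @param circularity_min_pass2 relaxed cutoff of the recovery pass; must not
#'   exceed the first-pass cutoff.
#' @param dedup_dist minimum distance between reported centers, as a
#'   fraction of `d`.
#' @return an object of class `postproc_params`.
#' @export
postproc_params <- function(expected_diameter,
                            logit_threshold = 0,
                            peak_scales = c(0.5, 0.75),
                            area_bounds = c(0.3, 2.5),
                            circularity_min_pass1 = 0.6,
                            circularity_min_pass2 = 0.4,
                            dedup_dist = 0.5) {
  if (expected_diameter <= 0) stopf("postproc_params: expected_diameter must be > 0")
  if (length(peak_scales) < 1) stopf("postproc_params: peak_scales must be non-empty")
  if (area_bounds[1] >= area_bounds[2]) {
    stopf("postproc_params: area_bounds min (%g) must be < max (%g)",
          area_bounds[1], area_bounds[2])
  }
  for (cm in c(circularity_min_pass1, circularity_min_pass2)) {
    if (cm <= 0 || cm > 1) stopf("postproc_params: circularity thresholds must lie in (0, 1]")
  }
  if (circularity_min_pass2 > circularity_min_pass1) {
    stopf("postproc_params: pass-2 circularity cutoff must be <= pass-1 cutoff")
  }
  structure(list(expected_diameter = as.numeric(expected_diameter),
                 logit_threshold = as.numeric(logit_threshold),
                 peak_scales = as.numeric(peak_scales),
                 area_bounds = as.numeric(area_bounds),
                 circularity_min_pass1 = as.numeric(circularity_min_pass1),
                 circularity_min_pass2 = as.numeric(circularity_min_pass2),
                 dedup_dist = as.numeric(dedup_dist)),
            class = "postproc_params")
}

#' Threshold a logit map into a binary mask
#'
#' @param logits numeric matrix.
#' @param threshold foreground where `logits > threshold`.
#' @return logical matrix.
#' @export
binarize <- function(logits, threshold = 0) {
  m <- unclass(logits) > threshold
  attributes(m) <- list(dim = dim(logits))
  m
}

#' Euclidean distance transform of a binary mask
#'
#' Per-pixel distance to the nearest background pixel: zero on background,
#' positive on foreground.
#'
#' @param mask logical matrix.
#' @return numeric matrix of distances.
#' @export
distance_map <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(m)
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

#' Multi-scale peak detection on a distance map
#'
#' Finds local maxima of the distance map at each minimum-separation scale
#' (grayscale max-filter with a disc window of radius `scale * d`), takes
#' the union over scales, and collapses seeds closer than
#' `dedup_dist * d` to the highest-valued one (ties: first found).
#'
#' @param dist distance map from [distance_map()].
#' @param params a [postproc_params()].
#' @return data frame of seed points: `row`, `col` (1-based pixels), `value`.
#' @export
detect_peaks_multiscale <- function(dist, params) {
  d <- params$expected_diameter
  seeds <- NULL
  for (sc in params$peak_scales) {
    m <- max(1L, as.integer(round(sc * d)))
    brush <- EBImage::makeBrush(2 * m + 1, "disc")
    mx <- as.matrix(EBImage::dilate(dist, brush))
    pk <- which(dist > 0 & dist >= mx, arr.ind = TRUE)
    seeds <- unique(rbind(seeds, pk))
  }
  if (is.null(seeds) || nrow(seeds) == 0) {
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  }
  df <- data.frame(row = seeds[, 1], col = seeds[, 2],
                   value = dist[seeds])
  keep <- dedup_centers(data.frame(x = df$col - 1, y = df$row - 1,
                                   priority = df$value),
                        min_dist = params$dedup_dist * d)
  df[keep, , drop = FALSE]
}

#' Greedy deduplication of centers
#'
#' Orders candidates by decreasing `priority` (ties: input order) and keeps
#' each candidate only if it lies at least `min_dist` from every already-kept
#' one. Idempotent: applying it to its own output changes nothing.
#'
#' @param centers data frame with columns `x`, `y` and optionally `priority`.
#' @param min_dist minimum pairwise distance in pixels.
#' @return integer indices (into `centers`) of the kept rows, in input order.
#' @export
dedup_centers <- function(centers, min_dist) {
  n <- nrow(centers)
  if (n == 0) return(integer(0))
  pr <- centers$priority %||% rep(0, n)
  ord <- order(-pr, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        min((centers$x[kept] - centers$x[i])^2 +
            (centers$y[kept] - centers$y[i])^2) >= min_dist^2) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Marker-controlled watershed split of a mask
#'
#' Partitions the foreground into one region per seed by watershed on the
#' negated Euclidean distance map (priority flood, 8-connected). Seeds on
#' background are dropped with a warning.
#'
#' @param mask logical matrix.
#' @param seeds data frame or matrix with 1-based `row`, `col` seed
#'   positions (e.g. from [detect_peaks_multiscale()]).
#' @return an object of class `labeled_regions`: `labels` integer matrix
#'   (0 = background) and `table`, a data frame of per-region area,
#'   perimeter, centroid and circularity.
#' @export
watershed_split <- function(mask, seeds) {
  seeds <- as.matrix(as.data.frame(seeds)[, c("row", "col"), drop = FALSE])
  storage.mode(seeds) <- "integer"
  if (nrow(seeds) > 0) {
    on_fg <- mask[seeds]
    if (any(!on_fg)) {
      warning(sprintf("watershed_split: dropped %d seed(s) on background",
                      sum(!on_fg)))
      seeds <- seeds[on_fg, , drop = FALSE]
    }
  }
  if (nrow(seeds) == 0) {
    return(new_labeled_regions(matrix(0L, nrow(mask), ncol(mask))))
  }
  dist <- distance_map(mask)
  lab <- .ws_flood(dist, mask, seeds)
  new_labeled_regions(lab)
}

new_labeled_regions <- function(lab) {
  structure(list(labels = lab, table = region_stats(lab)),
            class = "labeled_regions")
}

## Per-region area, centroid, Crofton-corrected perimeter and circularity.
## Perimeter counts exposed 4-neighbour pixel edges (a boundary between a
## region pixel and anything else, including the image border) scaled by
## pi/4, the isotropic Cauchy-Crofton correction; a rasterized disk then
## measures close to its true circumference and circularity ~ 1 (capped
## at 1).
region_stats <- function(lab) {
  k <- max(lab)
  if (k == 0) {
    return(data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), x = numeric(0), y = numeric(0),
                      circularity = numeric(0)))
  }
  area <- tabulate(lab, nbins = k)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[idx]
  cx <- rowsum(idx[, 2] - 1, l)[, 1] / area[sort(unique(l))]
  cy <- rowsum(idx[, 1] - 1, l)[, 1] / area[sort(unique(l))]
  xs <- numeric(k); ys <- numeric(k)
  xs[sort(unique(l))] <- cx
  ys[sort(unique(l))] <- cy
  H <- nrow(lab); W <- ncol(lab)
  edges <- numeric(k)
  pad <- function(m, side) {
    switch(side,
           up = rbind(0L, m[-H, , drop = FALSE]),
           down = rbind(m[-1, , drop = FALSE], 0L),
           left = cbind(0L, m[, -W, drop = FALSE]),
           right = cbind(m[, -1, drop = FALSE], 0L))
  }
  for (side in c("up", "down", "left", "right")) {
    nb <- pad(lab, side)
    mism <- lab > 0 & nb != lab
    edges <- edges + tabulate(lab[mism], nbins = k)
  }
  per <- edges * pi / 4
  circ <- pmin(1, 4 * pi * area / pmax(per, .Machine$double.eps)^2)
  data.frame(label = seq_len(k), area = as.numeric(area), perimeter = per,
             x = xs, y = ys, circularity = circ)
}

#' Geometric filtering of labeled regions
#'
#' Keeps regions whose area lies within `area_bounds * pi (d/2)^2` and whose
#' circularity `4 pi A / P^2` reaches `circularity_min`. Surviving regions
#' are relabeled contiguously from 1.
#'
#' @param regions a `labeled_regions` object.
#' @param params a [postproc_params()].
#' @param circularity_min circularity cutoff; defaults to the strict pass-1
#'   value in `params`.
#' @return a filtered `labeled_regions` object.
#' @export
region_filter <- function(regions, params,
                          circularity_min = params$circularity_min_pass1) {
  tb <- regions$table
  a0 <- pi * (params$expected_diameter / 2)^2
  keep <- tb$area >= params$area_bounds[1] * a0 &
          tb$area <= params$area_bounds[2] * a0 &
          tb$circularity >= circularity_min
  kept_labels <- tb$label[keep]
  lab <- regions$labels
  remap <- integer(max(lab, 1L))
  remap[kept_labels] <- seq_along(kept_labels)
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  new_lab[nz] <- remap[lab[nz]]
  new_labeled_regions(new_lab)
}

#' Extract particle coordinates from a segmentation logit map
#'
#' The dual-pass pipeline: (1) binarize, distance transform, multi-scale
#' peaks, watershed, strict geometric filter; (2) remove accepted regions
#' from the mask and repeat with the relaxed circularity cutoff to recover
#' touching or partially occluded particles; finally deduplicate centers at
#' `dedup_dist * d` (keeping the larger region on conflicts). Centers are
#' region centroids.
#'
#' @param logits numeric logit matrix (e.g. from [predict_mask()]), or a
#'   binary mask disguised as logits (use large +/- values).
#' @param params a [postproc_params()].
#' @return a [particle_set()] in the logit map's pixel frame (0-based x/y),
#'   with the expected diameter attached.
#' @export
extract_particles <- function(logits, params) {
  d <- params$expected_diameter
  frame <- attr(logits, "frame_model") %||%
    coord_frame("model", ncol(logits), nrow(logits))
  mask <- binarize(logits, params$logit_threshold)

  run_pass <- function(mask, cmin) {
    if (!any(mask)) return(NULL)
    dist <- distance_map(mask)
    seeds <- detect_peaks_multiscale(dist, params)
    if (nrow(seeds) == 0) return(NULL)
    regions <- watershed_split(mask, seeds)
    region_filter(regions, params, cmin)
  }

  pass1 <- run_pass(mask, params$circularity_min_pass1)
  found <- if (!is.null(pass1)) pass1$table else NULL
  mask2 <- mask
  if (!is.null(pass1)) mask2 <- mask & (pass1$labels == 0L)
  pass2 <- run_pass(mask2, params$circularity_min_pass2)
  if (!is.null(pass2)) found <- rbind(found, pass2$table)

  if (is.null(found) || nrow(found) == 0) {
    return(particle_set(diameter = d, frame = frame))
  }
  keep <- dedup_centers(data.frame(x = found$x, y = found$y,
                                   priority = found$area),
                        min_dist = params$dedup_dist * d)
  found <- found[keep, , drop = FALSE]
  particle_set(found$x, found$y, diameter = d, frame = frame)
}
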