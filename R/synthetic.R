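## Synthetic micrograph simulator with exact ground truth.
##
## Emulates the conditions that make cryo-EM picking hard -- low SNR,
## crowded/overlapping particles, contrast heterogeneity and high-contrast
## ice-like contamination -- while recording exact particle centers and
## rasterized masks, so every downstream stage can be tested without
## external data. It does not model physical image formation (no CTF,
## defocus or radiation damage).

#' Simulation parameters
#'
#' @param image_size square image side in pixels; must be at least twice the
#'   particle diameter.
#' @param n_particles number of particles to place.
#' @param particle_diameter particle diameter in pixels. Particles are
#'   rendered as radially symmetric Gaussian bumps (sd = diameter/4)
#'   truncated at this diameter, giving the soft low-contrast edge typical of
#'   projection images.
#' @param snr ratio of nominal particle amplitude (1.0) to the standard
#'   deviation of the additive Gaussian background noise; must be positive.
#' @param overlap_fraction fraction in `[0, 1]` of particles deliberately
#'   placed within one diameter of an existing particle (center distance
#'   uniform in 0.5-1.0 diameters), to exercise instance splitting.
#' @param n_ice_blobs number of high-contrast contaminant blobs (amplitude
#'   2-5x the particle amplitude, radius 0.5-3x the particle radius). Blobs
#'   are excluded from the ground-truth mask.
#' @param contrast_jitter multiplicative amplitude spread: per-particle
#'   amplitude is `1 + contrast_jitter * U(-1, 1)`.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(image_size = 256, n_particles = 40,
                       particle_diameter = 20, snr = 2,
                       overlap_fraction = 0.1, n_ice_blobs = 2,
                       contrast_jitter = 0.2, seed = 1L) {
  p <- list(image_size = as.integer(image_size),
            n_particles = as.integer(n_particles),
            particle_diameter = as.numeric(particle_diameter),
            snr = as.numeric(snr),
            overlap_fraction = as.numeric(overlap_fraction),
            n_ice_blobs = as.integer(n_ice_blobs),
            contrast_jitter = as.numeric(contrast_jitter),
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$image_size < 2 * p$particle_diameter) {
    stopf("sim_params: image_size (%d) must be >= 2 * particle_diameter (%g)",
          p$image_size, p$particle_diameter)
  }
  if (p$overlap_fraction < 0 || p$overlap_fraction > 1) {
    stopf("sim_params: overlap_fraction must lie in [0, 1], got %g",
          p$overlap_fraction)
  }
  if (p$snr <= 0) stopf("sim_params: snr must be > 0, got %g", p$snr)
  if (p$n_particles < 0) stopf("sim_params: n_particles must be >= 0")
  if (p$n_ice_blobs < 0) stopf("sim_params: n_ice_blobs must be >= 0")
  if (p$contrast_jitter < 0) stopf("sim_params: contrast_jitter must be >= 0")
  invisible(p)
}

#' Simulate a micrograph with exact ground truth
#'
#' Places particles (a configurable fraction overlapping), renders them as
#' truncated Gaussian disks with per-particle amplitude jitter, adds
#' ice-like contaminant blobs and white Gaussian noise of sd =
#' `amplitude / snr`. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return a list with components `micrograph` (a [micrograph()]) and
#'   `ground_truth` (class `ground_truth`: `particles` as [particle_set()],
#'   `mask` logical matrix of the particle-disk union, `contaminants` data
#'   frame).
#' @export
simulate_micrograph <- function(params) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  validate_sim_params(params)
  with_seed(params$seed, {
    sz <- params$image_size
    d <- params$particle_diameter
    r <- d / 2
    centers <- place_particles(params$n_particles, sz, d,
                               params$overlap_fraction)
    n <- nrow(centers)
    amps <- if (n > 0) {
      pmax(0.05, 1 + params$contrast_jitter * runif(n, -1, 1))
    } else numeric(0)

    img <- matrix(0, sz, sz)
    sigma <- d / 4
    for (k in seq_len(n)) {
      img <- add_soft_disk(img, centers$x[k], centers$y[k], r, sigma, amps[k])
    }

    blobs <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                        amplitude = numeric(0))
    for (k in seq_len(params$n_ice_blobs)) {
      bx <- runif(1, 0, sz - 1)
      by <- runif(1, 0, sz - 1)
      br <- runif(1, 0.5, 3) * r
      ba <- runif(1, 2, 5)
      img <- add_soft_disk(img, bx, by, br, br / 2, ba)
      blobs <- rbind(blobs, data.frame(x = bx, y = by, radius = br,
                                       amplitude = ba))
    }

    img <- img + matrix(rnorm(sz * sz, sd = 1 / params$snr), sz, sz)

    frame <- coord_frame("native", sz, sz)
    particles <- particle_set(centers$x, centers$y, diameter = d, frame = frame)
    mask <- render_gt_mask(particles, sz, d)
    gt <- structure(list(particles = particles, mask = mask,
                         contaminants = blobs, amplitudes = amps),
                    class = "ground_truth")
    list(micrograph = micrograph(img, pixel_size = 1), ground_truth = gt)
  })
}

## Rejection-sampled placement. "Base" particles keep >= 1 diameter between
## centers; "overlap" particles are dropped at 0.5-1.0 diameters from a
## randomly chosen anchor. All centers stay a radius inside the borders.
place_particles <- function(n, image_size, diameter, overlap_fraction) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  r <- diameter / 2
  lo <- r
  hi <- image_size - 1 - r
  if (hi <= lo) stopf("image too small to place particles of diameter %g", diameter)
  n_overlap <- min(n - 1, round(overlap_fraction * n))
  n_base <- n - n_overlap
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_base) {
    tries <- tries + 1
    if (tries > 400 * n) {
      stopf("could not place %d non-overlapping particles of diameter %g in a %d px image",
            n_base, diameter, image_size)
    }
    cx <- runif(1, lo, hi); cy <- runif(1, lo, hi)
    if (length(xs) == 0 ||
        min((xs - cx)^2 + (ys - cy)^2) >= diameter^2) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  for (k in seq_len(n_overlap)) {
    repeat {
      a <- sample.int(length(xs), 1)
      ang <- runif(1, 0, 2 * pi)
      dist <- runif(1, 0.5, 1.0) * diameter
      cx <- xs[a] + dist * cos(ang); cy <- ys[a] + dist * sin(ang)
      if (cx >= lo && cx <= hi && cy >= lo && cy <= hi) break
    }
    xs <- c(xs, cx); ys <- c(ys, cy)
  }
  data.frame(x = xs, y = ys)
}

## Add a truncated Gaussian bump at (cx, cy): amp * exp(-rho^2 / (2 sigma^2))
## for rho <= radius, zero outside. Operates on a local window only.
add_soft_disk <- function(img, cx, cy, radius, sigma, amp) {
  sz_r <- nrow(img); sz_c <- ncol(img)
  i0 <- max(1, floor(cy + 1 - radius)); i1 <- min(sz_r, ceiling(cy + 1 + radius))
  j0 <- max(1, floor(cx + 1 - radius)); j1 <- min(sz_c, ceiling(cx + 1 + radius))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  dy2 <- ((ii - 1) - cy)^2
  dx2 <- ((jj - 1) - cx)^2
  rho2 <- outer(dy2, dx2, "+")
  bump <- amp * exp(-rho2 / (2 * sigma^2))
  bump[rho2 > radius^2] <- 0
  img[ii, jj] <- img[ii, jj] + bump
  img
}

#' Rasterize a ground-truth mask from particle centers
#'
#' Foreground is the union of disks of the given diameter centered at each
#' particle: pixel (x, y) is foreground when
#' `(x - cx)^2 + (y - cy)^2 <= (diameter/2)^2` for some particle.
#'
#' @param particles a [particle_set()]; all centers must lie inside the image.
#' @param image_size square image side in pixels.
#' @param diameter disk diameter in pixels; defaults to the particle set's.
#' @return logical matrix (`TRUE` = foreground).
#' @export
render_gt_mask <- function(particles, image_size, diameter = NULL) {
  diameter <- diameter %||% attr(particles, "diameter")
  if (is.null(diameter) || is.na(diameter)) stopf("render_gt_mask: diameter required")
  sz <- as.integer(image_size)
  mask <- matrix(FALSE, sz, sz)
  if (nrow(particles) == 0) return(mask)
  oob <- particles$x < 0 | particles$x > sz - 1 |
         particles$y < 0 | particles$y > sz - 1
  if (any(oob)) {
    stopf("render_gt_mask: %d particle center(s) outside image bounds", sum(oob))
  }
  r2 <- (diameter / 2)^2
  r <- diameter / 2
  for (k in seq_len(nrow(particles))) {
    cx <- particles$x[k]; cy <- particles$y[k]
    i0 <- max(1, floor(cy + 1 - r)); i1 <- min(sz, ceiling(cy + 1 + r))
    j0 <- max(1, floor(cx + 1 - r)); j1 <- min(sz, ceiling(cx + 1 + r))
    ii <- i0:i1; jj <- j0:j1
    rho2 <- outer(((ii - 1) - cy)^2, ((jj - 1) - cx)^2, "+")
    mask[ii, jj] <- mask[ii, jj] | (rho2 <= r2)
  }
  mask
}

#' Generate a k-shot synthetic dataset
#'
#' Runs `k` independent simulations with child seeds derived
#' deterministically from `params$seed`, so the dataset is reproducible yet
#' the micrographs are pairwise distinct.
#'
#' @param k number of shots (annotated micrographs); must be >= 1.
#' @param params a [sim_params()] template; its `seed` seeds the sequence.
#' @return list of `k` results of [simulate_micrograph()].
#' @export
make_fewshot_dataset <- function(k, params) {
  if (k < 1) stopf("make_fewshot_dataset: k must be >= 1, got %s", format(k))
  lapply(seq_len(k), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    simulate_micrograph(p)
  })
}

#' Estimate the realized SNR of a simulated micrograph
#'
#' Amplitude is estimated by a matched filter (the known truncated-Gaussian
#' profile) at each ground-truth center; noise sd is the standard deviation
#' over pixels at least one diameter away from every particle and
#' contaminant.
#'
#' @param mic a [micrograph()].
#' @param gt the `ground_truth` from [simulate_micrograph()].
#' @return list with `amplitude`, `noise_sd`, `snr`.
#' @export
estimate_snr <- function(mic, gt) {
  img <- as_image_matrix(mic)
  sz <- nrow(img)
  d <- attr(gt$particles, "diameter")
  r <- d / 2
  sigma <- d / 4
  ## matched-filter amplitude per particle
  amps <- vapply(seq_len(nrow(gt$particles)), function(k) {
    cx <- gt$particles$x[k]; cy <- gt$particles$y[k]
    i0 <- max(1, floor(cy + 1 - r)); i1 <- min(sz, ceiling(cy + 1 + r))
    j0 <- max(1, floor(cx + 1 - r)); j1 <- min(sz, ceiling(cx + 1 + r))
    ii <- i0:i1; jj <- j0:j1
    rho2 <- outer(((ii - 1) - cy)^2, ((jj - 1) - cx)^2, "+")
    g <- exp(-rho2 / (2 * sigma^2))
    g[rho2 > r^2] <- 0
    sum(img[ii, jj] * g) / sum(g^2)
  }, numeric(1))
  ## background pixels: > 1 diameter from everything rendered
  yy <- matrix(0:(sz - 1), sz, sz)
  xx <- t(yy)
  clear <- matrix(TRUE, sz, sz)
  for (k in seq_len(nrow(gt$particles))) {
    clear <- clear & ((xx - gt$particles$x[k])^2 +
                      (yy - gt$particles$y[k])^2 > d^2)
  }
  for (k in seq_len(nrow(gt$contaminants))) {
    md <- gt$contaminants$radius[k] + d
    clear <- clear & ((xx - gt$contaminants$x[k])^2 +
                      (yy - gt$contaminants$y[k])^2 > md^2)
  }
  noise_sd <- sd(img[clear])
  amp <- if (length(amps)) mean(amps) else NA_real_
  list(amplitude = amp, noise_sd = noise_sd, snr = amp / noise_sd)
}
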