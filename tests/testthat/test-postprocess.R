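test_that("binarize thresholds logits exactly", {
  expect_false(any(binarize(matrix(-10, 4, 4), 0)))
  expect_true(all(binarize(matrix(rnorm(16), 4, 4), -Inf)))
  set.seed(2)
  z <- matrix(rnorm(100), 10, 10)
  expect_equal(sum(binarize(z, 0.3)), sum(z > 0.3))
})

test_that("distance map equals the exhaustive nearest-background oracle", {
  expect_true(all(distance_map(matrix(FALSE, 8, 8)) == 0))
  ## single disk: maximum within 1 px of the radius
  ps <- particle_set(16, 16, diameter = 14, frame = coord_frame("native", 32, 32))
  m <- render_gt_mask(ps, 32, 14)
  dm <- distance_map(m)
  expect_lt(abs(max(dm) - 7), 1.01)
  ## exhaustive check on random 32x32 masks and on the disk
  set.seed(5)
  for (rep in 1:6) {
    mk <- matrix(runif(32 * 32) > runif(1, 0.3, 0.7), 32, 32)
    expect_equal(distance_map(mk), oracle_edt(mk), tolerance = 1e-10)
  }
  expect_equal(dm, oracle_edt(m), tolerance = 1e-10)
})

test_that("multi-scale peak detection seeds isolated and paired disks correctly", {
  pp <- postproc_params(expected_diameter = 14)
  ## empty map
  expect_equal(nrow(detect_peaks_multiscale(matrix(0, 16, 16), pp)), 0)
  ## single disk: exactly one seed within 1 px of center
  ps <- particle_set(20, 20, diameter = 14, frame = coord_frame("native", 40, 40))
  m <- render_gt_mask(ps, 40, 14)
  seeds <- detect_peaks_multiscale(distance_map(m), pp)
  expect_equal(nrow(seeds), 1)
  expect_lte(max(abs(c(seeds$col - 1, seeds$row - 1) - 20)), 1)
  ## two disks at distance 2d: two seeds
  ps2 <- particle_set(c(20, 48), c(20, 20), diameter = 14,
                      frame = coord_frame("native", 68, 68))
  m2 <- render_gt_mask(ps2, 68, 14)
  seeds2 <- detect_peaks_multiscale(distance_map(m2), pp)
  expect_equal(nrow(seeds2), 2)
})

test_that("marker-controlled watershed partitions the foreground per seed", {
  pp <- postproc_params(expected_diameter = 16)
  ## one seed on one blob -> one region equal to the blob
  ps <- particle_set(16, 16, diameter = 16, frame = coord_frame("native", 32, 32))
  m <- render_gt_mask(ps, 32, 16)
  ws <- watershed_split(m, data.frame(row = 17, col = 17))
  expect_equal(nrow(ws$table), 1)
  expect_equal(sum(ws$labels == 1), sum(m))
  ## zero seeds -> zero regions
  ws0 <- watershed_split(m, data.frame(row = integer(0), col = integer(0)))
  expect_equal(nrow(ws0$table), 0)
  ## background seed dropped with warning
  expect_warning(watershed_split(m, data.frame(row = c(17, 1), col = c(17, 1))),
                 "background")
  ## dumbbell of two equal overlapping disks: two regions, equal areas (10%)
  d <- 20
  ps2 <- particle_set(c(40, 40 + 0.8 * d), c(40, 40), diameter = d,
                      frame = coord_frame("native", 96, 96))
  m2 <- render_gt_mask(ps2, 96, d)
  seeds <- detect_peaks_multiscale(distance_map(m2), postproc_params(d))
  ws2 <- watershed_split(m2, seeds)
  expect_equal(nrow(ws2$table), 2)
  expect_lt(abs(diff(ws2$table$area)) / mean(ws2$table$area), 0.1)
})

test_that("geometric filter keeps disks and rejects elongated or tiny regions", {
  d <- 20
  pp <- postproc_params(expected_diameter = d)
  ps <- particle_set(48, 48, diameter = d, frame = coord_frame("native", 96, 96))
  lab <- matrix(as.integer(render_gt_mask(ps, 96, d)), 96, 96)
  regions <- fewpick:::new_labeled_regions(lab)
  expect_gte(regions$table$circularity, 0.85)
  kept <- region_filter(regions, pp)
  expect_equal(nrow(kept$table), 1)
  ## 3-px-wide line of length 5d: circularity 4 pi A / P^2 far below 0.6
  line <- matrix(0L, 120, 120); line[60:62, 10:(10 + 5 * d)] <- 1L
  lr <- fewpick:::new_labeled_regions(line)
  expect_lt(lr$table$circularity, 0.3)
  expect_equal(nrow(region_filter(lr, pp)$table), 0)
  ## area below 0.1 nominal: rejected by the lower bound
  tiny <- matrix(0L, 40, 40); tiny[20:22, 20:24] <- 1L
  expect_equal(nrow(region_filter(fewpick:::new_labeled_regions(tiny), pp)$table), 0)
})

test_that("extraction recovers disjoint disks exactly and splits overlapping pairs", {
  d <- 16
  pp <- postproc_params(expected_diameter = d)
  ## 10 disjoint disks, centers recovered within 1 px
  p <- sim_params(image_size = 200, n_particles = 10, particle_diameter = d,
                  snr = 5, overlap_fraction = 0, n_ice_blobs = 0, seed = 13)
  sim <- simulate_micrograph(p)
  got <- extract_particles(mask_logits(sim$ground_truth$mask), pp)
  expect_equal(nrow(got), 10)
  m <- match_particles(got, sim$ground_truth$particles, threshold = 1.5)
  expect_equal(m$tp, 10)
  expect_lt(max(m$pairs$dist), 1.01)
  ## two overlapping disks at 0.8 d
  ps2 <- particle_set(c(40, 40 + 0.8 * d), c(40, 40), diameter = d,
                      frame = coord_frame("native", 80, 80))
  m2 <- render_gt_mask(ps2, 80, d)
  got2 <- extract_particles(mask_logits(m2), postproc_params(d))
  expect_equal(nrow(got2), 2)
  ## all-background logits
  expect_equal(nrow(extract_particles(matrix(-5, 64, 64), pp)), 0)
})

test_that("deduplication is idempotent and enforces the minimum spacing", {
  set.seed(8)
  pts <- data.frame(x = runif(60, 0, 50), y = runif(60, 0, 50),
                    priority = runif(60))
  keep <- dedup_centers(pts, min_dist = 8)
  kept <- pts[keep, ]
  dd <- as.matrix(dist(kept[, c("x", "y")]))
  diag(dd) <- Inf
  expect_gte(min(dd), 8)
  keep2 <- dedup_centers(kept, min_dist = 8)
  expect_equal(keep2, seq_len(nrow(kept)))
})

test_that("raising the circularity cutoff never increases the particle count", {
  p <- sim_params(image_size = 220, n_particles = 25, particle_diameter = 14,
                  snr = 4, overlap_fraction = 0.3, n_ice_blobs = 0, seed = 17)
  sim <- simulate_micrograph(p)
  lg <- mask_logits(sim$ground_truth$mask)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(cm) {
    pp <- postproc_params(14, circularity_min_pass1 = cm,
                          circularity_min_pass2 = min(cm, 0.3))
    nrow(extract_particles(lg, pp))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
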