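test_that("roi parameters are validated at construction", {
  expect_error(roi_params(block_size = 10), "odd")
  expect_error(roi_params(block_size = 1), "odd")
  expect_error(roi_params(occupancy_min = 1.5), "occupancy_min")
  expect_error(roi_params(min_area = 0), "min_area")
  expect_error(roi_params(connectivity = 6), "connectivity")
})

test_that("adaptive binarization matches the exhaustive local-mean oracle", {
  p <- roi_params(block_size = 5, offset = 0)
  # constant frame with positive offset: nothing active
  expect_false(any(binarize_frame(matrix(1, 6, 6),
                                  roi_params(block_size = 3, offset = 0.5))))
  # single bright pixel on a zero background
  fr <- matrix(0, 5, 5); fr[3, 3] <- 50
  b <- binarize_frame(fr, roi_params(block_size = 3, offset = 1))
  expect_identical(b, oracle_binarize(fr, roi_params(block_size = 3,
                                                     offset = 1)))
  expect_true(b[3, 3])
  expect_equal(sum(b), 1)
  # ramp image at offset 0 vs the O(N b^2) oracle
  ramp <- outer(1:7, 1:9, function(i, j) i + 0.5 * j)
  expect_identical(binarize_frame(ramp, p), oracle_binarize(ramp, p))
  # random frames, including NA pixels
  set.seed(31)
  for (i in 1:5) {
    fr <- matrix(rnorm(8 * 11), 8, 11)
    fr[sample(88, 4)] <- NA
    prm <- roi_params(block_size = sample(c(3, 5, 7), 1),
                      offset = runif(1, -0.5, 0.5))
    expect_identical(binarize_frame(fr, prm), oracle_binarize(fr, prm))
  }
  expect_error(binarize_frame(matrix(0, 4, 4),
                              roi_params(block_size = 5)), "extent")
})

test_that("morphological cleaning removes speckle, fills holes, idempotent", {
  p <- roi_params(open_radius = 1, close_radius = 1)
  empty <- matrix(FALSE, 6, 6)
  expect_identical(morph_clean(empty, p), empty)
  # isolated active pixel is removed by opening
  single <- empty; single[3, 3] <- TRUE
  expect_false(any(morph_clean(single, p)))
  # interior hole in a solid square is filled by closing (no opening)
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  holed <- sq; holed[5, 5] <- FALSE
  cleaned <- morph_clean(holed, roi_params(open_radius = 0,
                                           close_radius = 1))
  expect_identical(cleaned, sq)
  # idempotence and oracle agreement on random masks
  set.seed(17)
  for (i in 1:6) {
    m <- matrix(runif(10 * 12) < 0.4, 10, 12)
    prm <- roi_params(open_radius = sample(0:2, 1),
                      close_radius = sample(0:2, 1))
    once <- morph_clean(m, prm)
    expect_identical(morph_clean(once, prm), once)
    expect_identical(once, oracle_clean(m, prm))
  }
})

test_that("detect_rois matches the from-definition oracle on small stacks", {
  set.seed(41)
  for (i in 1:4) {
    nr <- sample(6:12, 1); nc <- sample(6:12, 1); nf <- 6
    vals <- array(rnorm(nf * nr * nc, sd = 2), dim = c(nf, nr, nc))
    # add a persistent bright blob so something real is present
    r0 <- sample(2:(nr - 1), 1); c0 <- sample(2:(nc - 1), 1)
    vals[, r0 + (-1:1), c0 + (-1:1)] <-
      vals[, r0 + (-1:1), c0 + (-1:1)] + 10
    dff <- make_dff(vals, seq_len(nf) - 0.5)
    prm <- roi_params(block_size = 5, offset = 0.5, occupancy_min = 0.3,
                      min_area = 2, connectivity = sample(c(4, 8), 1))
    got <- detect_rois(dff, prm)
    want <- oracle_detect_rois(dff, prm)
    expect_equal(length(got$rois), length(want))
    for (k in seq_along(want)) {
      expect_identical(got$rois[[k]]$pixels[order(got$rois[[k]]$pixels[, 1],
                                                  got$rois[[k]]$pixels[, 2]), ,
                                            drop = FALSE],
                       want[[k]]$pixels[order(want[[k]]$pixels[, 1],
                                              want[[k]]$pixels[, 2]), ,
                                        drop = FALSE])
      expect_equal(got$rois[[k]]$centroid, want[[k]]$centroid)
      expect_equal(got$rois[[k]]$area, want[[k]]$area)
      expect_equal(got$rois[[k]]$id, want[[k]]$id)
    }
  }
})

test_that("planted sites become ROIs with raster-ordered ids", {
  # all-zero stack: nothing detected
  dff0 <- make_dff(array(0, dim = c(5, 10, 12)), 1:5 - 0.5)
  expect_length(detect_rois(dff0, roi_params(block_size = 5))$rois, 0)
  # one noiseless planted site -> exactly one ROI at the right place
  s <- quick_session(seed = 12, post_min = 30, sim_fps = 0.05,
                     read_noise_sd = 0, shot_noise_gain = 0, n_sites = 1,
                     site_gain_range = c(1, 1))
  rs <- detect_rois(s$dff)
  expect_length(rs$rois, 1)
  truth_site <- s$sim$truth$sites[[1]]
  expect_lt(max(abs(rs$rois[[1]]$centroid -
                    c(truth_site$center_row, truth_site$center_col))), 1)
  # two separated sites -> two disjoint ROIs in raster order
  vals <- array(0, dim = c(6, 20, 40))
  vals[, 4:6, 5:7] <- 12
  vals[, 14:16, 30:32] <- 12
  dff2 <- make_dff(vals, 1:6 - 0.5)
  rs2 <- detect_rois(dff2, roi_params(block_size = 7, min_area = 4))
  expect_length(rs2$rois, 2)
  expect_lt(rs2$rois[[1]]$centroid[1], rs2$rois[[2]]$centroid[1])
  px <- rbind(rs2$rois[[1]]$pixels, rs2$rois[[2]]$pixels)
  expect_equal(nrow(px), nrow(unique(px)))
})

test_that("stricter thresholds never add ROIs on a fixed fixture", {
  s <- quick_session(seed = 23, post_min = 30, sim_fps = 0.05)
  counts_off <- sapply(c(0.5, 1, 2, 4), function(o)
    length(detect_rois(s$dff, roi_params(offset = o))$rois))
  expect_true(all(diff(counts_off) <= 0))
  counts_occ <- sapply(c(0.02, 0.05, 0.2, 0.5, 0.9), function(o)
    length(detect_rois(s$dff, roi_params(occupancy_min = o))$rois))
  expect_true(all(diff(counts_occ) <= 0))
})

test_that("ROI traces average mask pixels and append the whole-image row", {
  set.seed(7)
  vals <- array(rnorm(40 * 6 * 8), dim = c(40, 6, 8))
  dff <- make_dff(vals, -5 + (1:40 - 0.5) * 0.5)
  one_px <- structure(list(
    rois = list(list(id = 1L, pixels = cbind(3L, 4L),
                     centroid = c(row = 3, col = 4), area = 1L)),
    occupancy = matrix(0, 6, 8), dim = c(6L, 8L), params = roi_params()),
    class = "roi_set")
  tm <- extract_traces(dff, one_px, interval_width = 5)
  expect_equal(rownames(tm$values), c("1", "W"))
  manual <- bin_series_ref(vals[, 3, 4], dff$timestamps, 5)
  expect_equal(unname(tm$values["1", ]), manual)
  # an ROI covering every pixel reproduces the whole-image trace
  allpx <- which(matrix(TRUE, 6, 8), arr.ind = TRUE)
  all_roi <- structure(list(
    rois = list(list(id = 1L, pixels = unname(allpx),
                     centroid = c(row = 3.5, col = 4.5), area = 48L)),
    occupancy = matrix(1, 6, 8), dim = c(6L, 8L), params = roi_params()),
    class = "roi_set")
  tm2 <- extract_traces(dff, all_roi, interval_width = 5)
  expect_equal(unname(tm2$values["1", ]), unname(tm2$values["W", ]))
})

test_that("planted-site ROI trace tracks the kinetic curve exactly when noiseless", {
  s <- quick_session(seed = 12, post_min = 60, sim_fps = 0.05,
                     read_noise_sd = 0, shot_noise_gain = 0, n_sites = 1,
                     site_gain_range = c(1, 1))
  rs <- detect_rois(s$dff)
  tm <- extract_traces(s$dff, rs, interval_width = 5)
  truth_binned <- bin_series_ref(s$sim$truth$kinetic_curve,
                                 s$dff$timestamps, 5)
  expect_gt(stats::cor(tm$values[1, ], truth_binned), 1 - 1e-9)
})

test_that("profile metrics summarise a trace per the definitions", {
  m <- profile_metrics(c(2, 10, 6, -1), labels = c(15, 30, 45, 60))
  expect_equal(m$peak_label, 30)
  expect_equal(m$peak_value, 10)
  expect_equal(m$time_to_half_rise, 30)
  expect_equal(m$baseline_crossing, 60)
  expect_equal(m$undershoot_min, -1)
  # degenerate constant-zero trace
  z <- profile_metrics(c(0, 0, 0), labels = c(15, 30, 45))
  expect_equal(z$peak_value, 0)
  expect_equal(z$peak_label, 15)
  expect_equal(z$time_to_half_rise, 15)
  expect_equal(z$baseline_crossing, 30)
  # binned noiseless morphine defaults peak in the (30, 45] bin
  kp <- kinetic_profile("morphine_like", artifact_depth = 0)
  ts <- seq(0.25, 225, by = 0.5)
  binned <- bin_series_ref(kinetic_value(kp, ts), ts, 15)
  mm <- profile_metrics(binned, labels = seq(15, 225, by = 15))
  expect_equal(mm$peak_label, 45)
})
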