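# Preprocessing: windowing, isometric spline resampling, patch sampling,
# augmentation.

test_that("HU windowing maps the 50/250 window onto [0,1]", {
  expect_equal(window_hu(-75), 0)
  expect_equal(window_hu(175), 1)
  expect_equal(window_hu(50), 0.5)
  expect_equal(window_hu(-1000), 0)   # clipped below
  expect_equal(window_hu(3000), 1)    # clipped above
  expect_error(window_hu(0, width = 0), "width")
  # monotone non-decreasing in HU
  hu <- sort(runif(500, -500, 500))
  expect_true(all(diff(window_hu(hu)) >= 0))
})

test_that("isometric resampling follows the dimension rounding rule", {
  mk <- function(n, sp) ct_volume(array(0, c(n, n, 1)), sp, 3)
  expect_equal(dim(resample_isometric(mk(512, 0.5))$voxels)[1:2], c(256L, 256L))
  # 512 * 0.35 = 179.2 -> 179
  expect_equal(dim(resample_isometric(mk(512, 0.35))$voxels)[1:2], c(179L, 179L))
  expect_equal(resample_isometric(mk(64, 0.5))$pixel_spacing, c(1, 1))
  expect_error(resample_isometric(mk(8, 0.5), target_mm = 0), "> 0")
})

test_that("cubic spline resampling is exact on constants and linear ramps", {
  const <- ct_volume(array(17.5, c(40, 30, 2)), c(0.5, 0.4), 3)
  out <- resample_isometric(const)
  expect_equal(max(abs(out$voxels - 17.5)), 0, tolerance = 1e-8)
  # linear ramp in physical coordinates is reproduced away from the border
  n <- 60
  ramp <- outer((seq_len(n) - 0.5) * 0.5, rep(1, n))
  vol <- ct_volume(array(ramp, c(n, n, 1)), 0.5, 3)
  res <- resample_isometric(vol)
  m <- dim(res$voxels)[1]
  expected <- (seq_len(m) - 0.5) * 1.0
  interior <- 6:(m - 6)
  expect_equal(res$voxels[interior, 15, 1], expected[interior], tolerance = 1e-4)
})

test_that("resampling to 1 mm and back preserves in-plane dimensions within 1 px", {
  for (sp in c(0.31, 0.4, 0.47)) {
    n <- 120
    vol <- ct_volume(array(rnorm(n * n), c(n, n, 1)), sp, 3)
    iso <- resample_isometric(vol, 1)
    back <- resample_isometric(iso, sp)
    expect_lte(max(abs(dim(back$voxels)[1:2] - n)), 1)
  }
})

test_that("label resampling is nearest-neighbour and never invents labels", {
  lab <- array(0L, c(50, 50, 2))
  lab[10:20, 10:20, 1] <- 3L
  lab[30:40, 30:40, 2] <- 7L
  lv <- label_volume(lab, 0.5, 3)
  out <- resample_labels(lv, 1)
  expect_true(all(unique(as.vector(out$labels)) %in% c(0L, 3L, 7L)))
  single <- label_volume(array(5L, c(20, 20, 1)), 0.5, 3)
  expect_true(all(resample_labels(single, 1)$labels == 5L))
})

test_that("binary mask area scales by the squared spacing ratio under resampling", {
  disk <- raster_ellipse(60, c(30, 30), 14, 14, 0)
  lv <- label_volume(array(as.integer(disk), c(60, 60, 1)), 0.5, 3)
  out <- resample_labels(lv, 1)   # 0.5 mm -> 1 mm: counts shrink ~4x
  n_in <- sum(disk); n_out <- sum(out$labels > 0)
  perimeter_px <- 2 * pi * 14 / 2   # circumference on the coarse grid
  expect_lt(abs(n_out - n_in / 4), perimeter_px)
})

test_that("patch sampling balances orbit and background patches", {
  ph <- fixture_phantom()
  st <- prepare_study(ph$ct, ph$labels)
  ps <- sample_patches(st$vol, st$lab, 20, seed = 9)
  expect_length(ps$images, 20)
  expect_equal(sum(ps$provenance$orbit), 10)
  # orbit patches contain muscle; background patches none
  for (i in seq_len(20)) {
    has <- any(ps$labels[[i]] > 0)
    expect_identical(has, ps$provenance$orbit[i])
  }
  # provenance offsets keep patches inside the volume
  d <- dim(st$vol$voxels)
  expect_true(all(ps$provenance$row_off + 128 <= d[1]))
  expect_true(all(ps$provenance$col_off + 128 <= d[2]))
  # determinism
  ps2 <- sample_patches(st$vol, st$lab, 20, seed = 9)
  expect_identical(ps$provenance, ps2$provenance)
  # odd counts put the extra patch on the orbit side
  expect_equal(sum(sample_patches(st$vol, st$lab, 7, seed = 1)$provenance$orbit), 4)
  tiny <- ct_volume(array(0, c(64, 64, 1)), 1, 3)
  tl <- label_volume(array(0L, c(64, 64, 1)), 1, 3)
  expect_error(sample_patches(tiny, tl, 2, 128, 1), "smaller than patch")
})

test_that("augmentation without rotation/scale/noise is the identity", {
  ph <- fixture_phantom()
  st <- prepare_study(ph$ct, ph$labels)
  ps <- sample_patches(st$vol, st$lab, 4, seed = 2)
  aug <- augment(ps, seed = 3, rotation_deg_range = c(0, 0),
                 scale_range = c(1, 1), noise_sd_hu = 0)
  expect_equal(aug$images, ps$images)
  expect_identical(aug$labels, ps$labels)
})

test_that("augmented label patches never gain new labels", {
  ph <- fixture_phantom()
  st <- prepare_study(ph$ct, ph$labels)
  ps <- sample_patches(st$vol, st$lab, 6, seed = 4)
  aug <- augment(ps, seed = 5)
  for (i in seq_along(aug$labels)) {
    expect_true(all(unique(as.vector(aug$labels[[i]])) %in%
                      unique(as.vector(ps$labels[[i]]))))
    # rotation+scale only: orientation is preserved (no flips exist)
    expect_true(all(dim(aug$images[[i]]) == dim(ps$images[[i]])))
  }
})

test_that("HU noise injection has the configured standard deviation", {
  # constant mid-window patch: unwindowed difference recovers the HU noise
  img <- matrix(0.5, 128, 128)
  lab <- matrix(0L, 128, 128)
  ps <- structure(list(images = list(img), labels = list(lab),
                       provenance = data.frame(source_id = "x", slice = 1L,
                                               row_off = 0L, col_off = 0L,
                                               orbit = FALSE),
                       patch = 128L), class = "patch_set")
  aug <- augment(ps, seed = 11, rotation_deg_range = c(0, 0),
                 scale_range = c(1, 1), noise_sd_hu = 10)
  d_hu <- (aug$images[[1]] - img) * 250
  # chi-distribution bound for n = 16384 (window clipping is negligible at
  # mid-window): sample sd within [8.5, 11.5]
  expect_gt(sd(as.numeric(d_hu)), 8.5)
  expect_lt(sd(as.numeric(d_hu)), 11.5)
})
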