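# Minimum-area rotated-rectangle thickness and pixel-count area.

test_that("axis-aligned rectangles measure their exact sides", {
  m <- matrix(0, 20, 20); m[5:14, 5:8] <- 1   # 10 x 4 block
  r <- slice_thickness(m, 1)
  expect_equal(r$thickness_mm, 4)
  expect_equal(r$rect$long, 10)
  # at 0.5 mm the same block halves its physical size
  expect_equal(slice_thickness(m, 0.5)$thickness_mm, 2)
})

test_that("thickness is recovered for rotated rasterised rectangles", {
  n <- 60
  # 24 x 10 px rectangle rotated 30 degrees, rasterised
  th <- 30 * pi / 180
  g <- expand.grid(r = seq_len(n) - 0.5, c = seq_len(n) - 0.5)
  u <- (g$r - 30) * cos(th) + (g$c - 30) * sin(th)
  v <- -(g$r - 30) * sin(th) + (g$c - 30) * cos(th)
  m <- matrix(abs(u) <= 12 & abs(v) <= 5, n, n)
  r <- slice_thickness(m, 1)
  # pixel-corner convention: an oblique footprint widens by up to
  # (|cos| + |sin|) px, well inside the 2-pixel rasterisation bound
  expect_lt(abs(r$thickness_mm - 10), 2)
  # the min-AREA orientation can differ marginally from the min-width one
  expect_lt(abs(r$thickness_mm - caliper_width_oracle(m)), 0.1)
})

test_that("disk width equals its diameter", {
  disk <- raster_ellipse(40, c(20, 20), 7, 7, 0)
  r <- slice_thickness(disk, 0.5)
  expect_equal(r$thickness_mm, 7, tolerance = 0.5)
  expect_equal(r$thickness_mm, caliper_width_oracle(disk, c(0.5, 0.5)),
               tolerance = 1e-6)
})

test_that("min-area rectangle agrees with the caliper oracle across rotations", {
  set.seed(3)
  for (ang in seq(0, 175, by = 35)) {
    m <- raster_ellipse(50, c(25, 25), 11, 4.5, ang)
    got <- slice_thickness(m, 1)$thickness_mm
    oracle <- caliper_width_oracle(m)
    expect_lt(abs(got - oracle), 0.3)
    expect_lt(abs(got - 9), 2)   # 2-pixel rasterisation bound on 2b = 9
  }
})

test_that("area is exactly linear in pixel count and spacing", {
  m <- matrix(0, 10, 10); m[1:5, 1:5] <- 1
  expect_equal(slice_area(m, 1), 25)
  expect_equal(slice_area(m, 0.5), 6.25)
  expect_equal(slice_area(matrix(0, 5, 5), 1), 0)
  expect_equal(slice_area(m, c(0.4, 0.45)), 25 * 0.4 * 0.45)
})

test_that("empty masks signal an absent muscle rather than erroring", {
  r <- slice_thickness(matrix(0, 8, 8), 1)
  expect_true(is.na(r$thickness_mm))
  expect_null(r$rect)
})

test_that("thickness is translation invariant and monotone under dilation", {
  m <- matrix(0, 40, 40); m[10:19, 10:13] <- 1
  m_shift <- matrix(0, 40, 40); m_shift[20:29, 25:28] <- 1
  expect_equal(slice_thickness(m, 1)$thickness_mm,
               slice_thickness(m_shift, 1)$thickness_mm)
  dil <- matrix(0, 40, 40); dil[9:20, 9:14] <- 1   # superset of m
  expect_gte(slice_thickness(dil, 1)$thickness_mm,
             slice_thickness(m, 1)$thickness_mm)
  # short side never exceeds the long side
  set.seed(8)
  for (rep in 1:5) {
    mm <- matrix(0, 30, 30); mm[sample(900, 60)] <- 1
    r <- slice_thickness(mm, 1)$rect
    expect_lte(r$short, r$long + 1e-12)
  }
})

test_that("multiple components: the largest is measured", {
  m <- matrix(0, 30, 30)
  m[5:14, 5:8] <- 1       # 40 px, 10 x 4
  m[25:26, 25:26] <- 1    # 4 px speck
  expect_equal(slice_thickness(m, 1)$thickness_mm, 4)
})

test_that("measure_volume reports per-slice maxima and their slices", {
  lab <- array(0L, c(40, 40, 3))
  lab[10:19, 10:12, 1] <- 1L   # 10 x 3
  lab[10:19, 10:14, 2] <- 1L   # 10 x 5  <- belly
  lab[10:19, 10:13, 3] <- 1L   # 10 x 4
  lv <- label_volume(lab, 1, 3)
  rep <- measure_volume(lv)
  row <- rep$table[rep$table$class == 1, ]
  expect_equal(row$thickness_mm, 5)
  expect_equal(row$thickness_slice, 2L)
  expect_equal(row$area_mm2, 50)
  expect_equal(row$area_slice, 2L)
  # classes absent everywhere are absent, not zero
  row8 <- rep$table[rep$table$class == 8, ]
  expect_false(row8$present)
  expect_true(is.na(row8$thickness_mm))
})

test_that("phantom ground truth is recovered within rasterisation error", {
  ph <- fixture_phantom()
  rep <- measure_volume(ph$labels)
  sp <- ph$labels$pixel_spacing
  px_diag <- sqrt(sum(sp^2))
  for (cls in muscle_classes()) {
    row <- rep$table[rep$table$class == cls, ]
    tru <- ph$truth[ph$truth$class == cls, ]
    expect_lt(abs(row$thickness_mm - tru$thickness_mm), px_diag)
    # rasterised area differs from the ellipse by at most one pixel band
    # around the perimeter
    perim <- pi * (3 * (tru$long_axis_mm + tru$thickness_mm) / 4)
    expect_lt(abs(row$area_mm2 - tru$area_mm2), perim * px_diag)
  }
})

test_that("size reports export to CSV and JSON", {
  ph <- fixture_phantom()
  rep <- measure_volume(ph$labels)
  td <- withr::local_tempdir()
  write_size_report(rep, csv = file.path(td, "sizes.csv"),
                    json = file.path(td, "sizes.json"))
  back <- utils::read.csv(file.path(td, "sizes.csv"))
  expect_equal(nrow(back), 8)
  expect_equal(back$thickness_mm, rep$table$thickness_mm)
  js <- jsonlite::fromJSON(file.path(td, "sizes.json"))
  expect_equal(length(js$profiles), 8)
})
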