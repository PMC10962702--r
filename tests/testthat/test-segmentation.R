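test_that("segment_nuclei handles blank and single-nucleus images", {
  expect_warning(m0 <- segment_nuclei(gray_image(matrix(5, 64, 64))),
                 "constant")
  expect_true(all(m0$labels == 0L))

  # one rendered disk nucleus: a single label with area within 5% of pi R^2
  set.seed(7)
  sim <- sim_small(7, n_nuclei = 1L, nucleus_shape = "disk",
                   image_size = 200L, nucleus_radius_range = c(40, 40))
  mask <- segment_nuclei(acq_channel(sim$acquisitions[[1]], "dapi"))
  expect_identical(max(mask$labels), 1L)
  expect_lt(abs(sum(mask$labels == 1L) - pi * 40^2) / (pi * 40^2), 0.05)
})

test_that("segmentation recovers the simulated nucleus count", {
  for (s in 1:3) {
    sim <- sim_small(100 + s, image_size = 768L, n_nuclei = 12L)
    mask <- segment_nuclei(acq_channel(sim$acquisitions[[1]], "dapi"))
    expect_identical(max(mask$labels), 12L)
  }
})

test_that("nucleus geometry matches analytic shapes", {
  # axis-aligned square: circularity ~ pi/4
  sq <- measure_nucleus(mk_square_mask(100L), 1L)
  expect_lt(abs(sq$circularity - pi / 4), 0.03)
  # disk R = 50 passes the shape filter
  d50 <- measure_nucleus(mk_disk_mask(50L), 1L)
  expect_gte(d50$circularity, 0.95)
  # equivalent diameter of a disk R = 30 at 0.108 um/px: ~ 2 * 30 * 0.108
  d30 <- measure_nucleus(mk_disk_mask(30L, pixel_size = 0.108), 1L)
  expect_lt(abs(d30$equivalent_diameter_um - 6.48), 0.05)
  # absent label errors
  expect_error(measure_nucleus(mk_disk_mask(20L), 9L), "not present")
})

test_that("disk circularity stays near 1 across radii", {
  circ <- vapply(c(10L, 20L, 40L, 80L), function(R)
    measure_nucleus(mk_disk_mask(R), 1L)$circularity, numeric(1))
  expect_true(all(circ > 0.95 & circ < 1.05))
  expect_lt(max(abs(circ - 1)), 0.05)
})

test_that("qc_filter applies the diameter-OR-circularity rule", {
  rec <- data.frame(
    label = 1:10,
    area_um2 = NA_real_, perimeter_um = NA_real_,
    equivalent_diameter_um = c(8, 15, 15, 9.99, 10.01, 20, 5, 12, 30, 10),
    circularity = c(0.99, 0.99, 0.50, 0.99, 0.99, 0.94, 0.20, 0.95, 1.01, 0.96),
    centroid_x = 0, centroid_y = 0,
    touches_border = c(rep(FALSE, 9), TRUE),
    qc_pass = NA)
  out <- qc_filter(rec)
  # hand count: pass iff diameter >= 10 AND circularity >= 0.95
  expect_identical(out$qc_pass,
                   c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                     TRUE, TRUE))
  # idempotent and order-independent
  expect_identical(qc_filter(out)$qc_pass, out$qc_pass)
  shuf <- sample(nrow(rec))
  expect_identical(qc_filter(rec[shuf, ])$qc_pass, out$qc_pass[shuf])
  # border flag only drops when requested
  expect_false(qc_filter(rec, drop_border = TRUE)$qc_pass[10])
})

test_that("label masks round-trip through 16-bit TIFF", {
  mask <- mk_disk_mask(15L, label = 3L)
  p <- file.path(withr::local_tempdir(), "mask.tif")
  write_gray_tiff(mask$labels, p)
  back <- read_label_mask(p, mask$pixel_size)
  expect_identical(back$labels, mask$labels)
})
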