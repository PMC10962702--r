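test_that("raw cross-correlation matches the direct-sum oracle and its trivial cases", {
  set.seed(11)
  # autocorrelation of a nonzero image peaks at zero lag
  a <- matrix(runif(32 * 32), 32)
  surf <- cross_correlate(a, a, max_shift = 5)
  peak <- which(surf$values == max(surf$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(6L, 6L))  # center = (0, 0)

  # all-zero image correlates to zero everywhere
  z <- matrix(0, 20, 20)
  expect_true(all(cross_correlate(z, a[1:20, 1:20], 4)$values == 0))

  # FFT surface equals the literal double loop on random images
  for (i in 1:5) {
    h <- sample(8:16, 1); w <- sample(8:16, 1)
    A <- matrix(rnorm(h * w), h); B <- matrix(rnorm(h * w), h)
    fast <- cross_correlate(A, B, 3)$values
    direct <- xcorr_direct(A, B, 3)
    expect_lt(max(abs(fast - direct)) / max(abs(direct)), 1e-9)
  }
})

test_that("cross_correlate validates its inputs", {
  a <- matrix(1, 10, 10); b <- matrix(1, 10, 12)
  expect_error(cross_correlate(a, b, 2), "10x10 vs 10x12")
  expect_error(cross_correlate(a, a, 10), "max_shift")
})

test_that("translation estimation recovers known shifts", {
  sim <- sim_small(21, image_size = 256L, n_nuclei = 3L,
                   nucleus_radius_range = c(28, 34))
  dapi <- acq_channel(sim$acquisitions[[1]], "dapi")
  # identity
  v0 <- estimate_translation(dapi, dapi, max_shift = 10)
  expect_identical(c(v0$dx, v0$dy), c(0L, 0L))
  expect_gte(v0$confidence, 1)
  # pure shift with zero fill
  v <- estimate_translation(dapi, apply_translation(dapi,
                                                    translation_vector(5, -3)),
                            max_shift = 10)
  expect_identical(c(v$dx, v$dy), c(5L, -3L))
  # constant image is rejected
  expect_error(estimate_translation(gray_image(matrix(3, 32, 32)),
                                    gray_image(matrix(runif(1024), 32))),
               "no registration content")
})

test_that("shift recovery is exact under noise up to 20% of the foreground level", {
  set.seed(33)
  sim <- sim_small(33, image_size = 256L, n_nuclei = 3L,
                   nucleus_radius_range = c(28, 34))
  dapi <- acq_channel(sim$acquisitions[[1]], "dapi")
  for (i in 1:6) {
    v_in <- translation_vector(sample(-10:10, 1), sample(-10:10, 1))
    shifted <- apply_translation(dapi, v_in)
    noisy <- gray_image(pmax(shifted$pixels +
                               matrix(rnorm(length(shifted$pixels), 0, 80),
                                      nrow(shifted$pixels)), 0),
                        dapi$pixel_size)
    v <- estimate_translation(dapi, noisy, max_shift = 12)
    expect_identical(c(v$dx, v$dy), c(v_in$dx, v_in$dy))
  }
})

test_that("apply_translation moves pixels exactly and zero-fills the border", {
  img <- gray_image(matrix(runif(900), 30))
  expect_identical(apply_translation(img, translation_vector(0, 0))$pixels,
                   img$pixels)
  # single bright pixel moves as documented (0-based (10,10) -> (12,14))
  m <- matrix(0, 30, 30); m[11, 11] <- 7
  out <- apply_translation(m, translation_vector(2, 4))
  expect_equal(out[15, 13], 7)
  expect_equal(sum(out), 7)
  # forward then inverse restores everything but a zeroed border band
  fwd <- apply_translation(img, translation_vector(5, -3))
  back <- apply_translation(fwd, translation_vector(-5, 3))
  inner_r <- 4:30; inner_c <- 1:25
  expect_equal(back$pixels[inner_r, inner_c], img$pixels[inner_r, inner_c])
  # intensity is conserved up to the zeroed border
  expect_lte(sum(fwd$pixels), sum(img$pixels))
})

test_that("estimate after apply recovers the vector (round-trip property)", {
  sim <- sim_small(44, image_size = 200L, n_nuclei = 2L,
                   nucleus_radius_range = c(25, 30))
  dapi <- acq_channel(sim$acquisitions[[1]], "dapi")
  for (v in list(c(3L, 4L), c(-6L, 0L), c(0L, -5L), c(-4L, -4L))) {
    est <- estimate_translation(
      dapi, apply_translation(dapi, translation_vector(v[1], v[2])),
      max_shift = 14)
    expect_identical(c(est$dx, est$dy), v)
  }
})

test_that("register_acquisition aligns a sequential field to its ground truth", {
  sim <- sim_small(55, sequential_shift = c(4L, 4L), mode = "sequential")
  merged <- register_acquisition(sim$acquisitions[[1]], sim$acquisitions[[2]],
                                 max_shift = 10)
  reg <- merged$meta$registration
  expect_identical(c(reg$estimated_dx, reg$estimated_dy), c(4L, 4L))
  # detected RNA spots in the merged frame coincide with truth within 1 px
  spots <- detect_spots(acq_channel(merged, "rna"), channel = "RNA")
  tr <- sim$truth$alleles[sim$truth$alleles$active, ]
  expect_gte(nrow(spots), nrow(tr))
  m <- match_spots(spots$x, spots$y, tr$rna_x_px, tr$rna_y_px, tol_px = 1)
  expect_equal(m$fn, 0)

  # missing DAPI channel is a contract error
  no_dapi <- acquisition(list(rna = matrix(1, 8, 8)), tag = "rna_pass")
  expect_error(register_acquisition(sim$acquisitions[[1]], no_dapi),
               "missing the DAPI channel")
})
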