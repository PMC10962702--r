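test_that("LoG response behaves like a blob detector", {
  expect_error(log_filter(matrix(1, 5, 5), 0), "sigma")
  # constant image: zero response everywhere
  expect_lt(max(abs(log_filter(matrix(7, 50, 50), 2))), 1e-10)
  # isotropic Gaussian blob of scale s: response maximal at the center +/- 1
  s <- 3
  blob <- 500 * outer(dnorm(-40:40, sd = s), dnorm(-40:40, sd = s)) /
    dnorm(0, sd = s)^2
  resp <- log_filter(blob, s)
  peak <- which(resp == max(resp), arr.ind = TRUE)
  expect_lte(max(abs(peak - 41)), 1)
  # response integrates to ~0 for an interior blob (Laplacian telescoping)
  expect_lt(abs(sum(resp)) / sum(abs(resp)), 1e-6)
})

test_that("detect_spots finds well-separated spots at the right positions", {
  expect_error(detect_spots(matrix(0, 10, 10), threshold = -1), "threshold")
  expect_identical(nrow(detect_spots(matrix(0, 64, 64))), 0L)

  set.seed(5)
  img <- matrix(100, 96, 96)
  # two spots 20 px apart (0-based truth (30,40) and (50,40))
  for (ctr in list(c(30, 40), c(50, 40))) {
    xs <- ctr[1]; ys <- ctr[2]
    dy2 <- ((1:96) - 1 - ys)^2; dx2 <- ((1:96) - 1 - xs)^2
    img <- img + 600 * exp(-outer(dy2, dx2, "+") / (2 * 2^2))
  }
  noisy <- img + matrix(rnorm(96 * 96, 0, 10), 96)
  s <- detect_spots(noisy, sigma = 2, threshold = 100)
  expect_identical(nrow(s), 2L)
  m <- match_spots(s$x, s$y, c(30, 50), c(40, 40), tol_px = 1)
  expect_identical(m$tp, 2L)

  # detection count is invariant to a constant offset (LoG kills DC)
  s2 <- detect_spots(noisy + 500, sigma = 2, threshold = 100)
  expect_identical(nrow(s2), nrow(s))
})

test_that("maxima closer than 2 sigma merge into the stronger one", {
  img <- matrix(0, 64, 64)
  dy2 <- ((1:64) - 31)^2
  img <- img + 600 * exp(-outer(dy2, ((1:64) - 31)^2, "+") / 8) +
    500 * exp(-outer(dy2, ((1:64) - 34)^2, "+") / 8)
  s <- detect_spots(img, sigma = 2, threshold = 50)
  expect_identical(nrow(s), 1L)        # one site, not two
  expect_lte(abs(s$x - 30), 1)         # at/next to the stronger component
  expect_identical(s$y, 30L)
})

test_that("spots are assigned to nuclei and orphans are removed", {
  mask <- mk_disk_mask(10L, pad = 10, label = 7L)
  spots <- data.frame(well = "A01", field = 1L, channel = "DNA",
                      x = c(20L, 1L), y = c(20L, 1L),
                      x_um = c(20, 1) * 0.108, y_um = c(20, 1) * 0.108,
                      intensity = c(10, 10), log_response = c(5, 5),
                      nucleus_label = NA_integer_)
  out <- assign_spots_to_nuclei(spots, mask)
  expect_identical(nrow(out), 1L)       # background spot dropped
  expect_identical(out$nucleus_label, 7L)
  expect_error(assign_spots_to_nuclei(transform(spots, x = c(500L, 1L)), mask),
               "outside")
})

test_that("detection is deterministic and the output ordering is canonical", {
  sim <- sim_small(61)
  img <- acq_channel(sim$acquisitions[[1]], "dna")
  s1 <- detect_spots(img, channel = "DNA", well = "A01", field = 1L)
  s2 <- detect_spots(img, channel = "DNA", well = "A01", field = 1L)
  expect_identical(s1, s2)
  expect_identical(order(s1$y, s1$x), seq_len(nrow(s1)))
})
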