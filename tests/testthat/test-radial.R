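test_that("distance transform matches a brute-force nearest-background search", {
  mask <- mk_disk_mask(12L, pad = 4)
  dt <- distance_transform(mask, 1L)
  expect_equal(dt, dt_brute(mask$labels, 1L), tolerance = 1e-6)
  # maximal at the disk center
  ctr <- which(dt == max(dt), arr.ind = TRUE)
  expect_lte(max(abs(ctr - (12 + 4 + 1))), 1)
  expect_error(distance_transform(mask, 5L), "not present")
})

test_that("radial map is 0 at the deepest pixel and exactly 1 at the rim", {
  R <- 50L
  mask <- mk_disk_mask(R)
  rmap <- radial_map(mask)
  c0 <- R + 6 + 1
  expect_identical(rmap$values[c0, c0], 0)
  # boundary-adjacent pixels clamp to exactly 1
  expect_identical(rmap$values[c0, c0 + R], 1)
  # interior follows d / R within the discretization tolerance
  for (d in c(10, 25, 40)) {
    expect_lt(abs(rmap$values[c0, c0 + d] - d / R), 2 / R + 1e-9)
  }
  # values span [0, 1] inside, NA outside
  v <- rmap$values[mask$labels == 1L]
  expect_true(all(v >= 0 & v <= 1))
  expect_true(is.na(rmap$values[1, 1]))
})

test_that("degenerate one-pixel nuclei map to radial 0", {
  lab <- matrix(0L, 9, 9); lab[5, 5] <- 1L
  rmap <- radial_map(label_mask(lab))
  expect_identical(rmap$values[5, 5], 0)
})

test_that("radial increases monotonically outward in convex nuclei", {
  for (mask in list(mk_disk_mask(30L),
                    {  # ellipse 40 x 28
                      n <- 101L; xx <- matrix(rep(1:n, each = n), n)
                      yy <- matrix(rep(1:n, n), n)
                      label_mask((((xx - 51) / 40)^2 + ((yy - 51) / 28)^2 <= 1) * 1L)
                    })) {
    rmap <- radial_map(mask)
    ctr <- which(rmap$values == 0, arr.ind = TRUE)[1, ]
    ray <- rmap$values[ctr[1], ctr[2]:ncol(rmap$values)]
    ray <- ray[!is.na(ray)]
    expect_true(all(diff(ray) >= -1e-9))
  }
})

test_that("spot radial lookup works and rejects outside-nucleus spots", {
  mask <- mk_disk_mask(20L)
  rmap <- radial_map(mask)
  deepest <- which(rmap$values == 0, arr.ind = TRUE)[1, ]
  s <- data.frame(x = deepest[2] - 1L, y = deepest[1] - 1L)
  expect_identical(radial_of_spot(s, rmap), 0)
  expect_error(radial_of_spot(data.frame(x = 0L, y = 0L), rmap), "outside")
})

test_that("shell binning partitions [0,1] with a closed top shell", {
  expect_identical(shell_bin(c(0, 0.2, 0.39, 0.4, 0.99, 1.0)),
                   c(1L, 2L, 2L, 3L, 5L, 5L))
  expect_error(shell_bin(1.2), "\\[0, 1\\]")
  expect_error(shell_bin(-0.1), "\\[0, 1\\]")
  # conservation: histogram counts sum to the number of binned values
  set.seed(9); r <- runif(500)
  expect_identical(sum(tabulate(shell_bin(r), 5L)), 500L)
})

test_that("uniformly placed in-disk spots have mean radial 2/3", {
  mask <- mk_disk_mask(60L)
  rmap <- radial_map(mask)
  px <- which(mask$labels == 1L)
  set.seed(12)
  v <- rmap$values[sample(px, 10000, replace = TRUE)]
  expect_lt(abs(mean(v) - 2 / 3), 0.02)
})
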