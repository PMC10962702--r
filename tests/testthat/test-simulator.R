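test_that("the simulator is deterministic under a fixed seed", {
  s1 <- sim_small(9)
  s2 <- sim_small(9)
  expect_identical(s1$acquisitions[[1]]$channels, s2$acquisitions[[1]]$channels)
  expect_identical(s1$truth$alleles, s2$truth$alleles)
  # and the global RNG stream is left untouched
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(sim_small(9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("activity extremes behave by construction", {
  s0 <- sim_small(10, p_active = 0)
  expect_false(any(s0$truth$alleles$active))
  expect_identical(nrow(detect_spots(acq_channel(s0$acquisitions[[1]], "rna"),
                                     channel = "RNA")), 0L)
  s1 <- sim_small(11, p_active = 1)
  tr <- s1$truth$alleles
  expect_true(all(tr$active))
  d_um <- sqrt((tr$rna_x_px - tr$x_px)^2 + (tr$rna_y_px - tr$y_px)^2) * 0.108
  expect_true(all(d_um <= 0.5 + 1e-9))
})

test_that("simulation_config validates its contract", {
  expect_error(simulation_config(p_active = 1.5), "p_active")
  expect_error(simulation_config(rna_offset_max_um = 1.2), "rna_offset")
  expect_error(simulation_config(radial_model = list(type = "beta")),
               "radial_model")
  expect_error(simulate_field(simulation_config(n_nuclei = 80L,
                                                image_size = 256L)),
               "placed")
})

test_that("place_spot_at_radius hits its target ring", {
  mask <- mk_disk_mask(50L)
  rmap <- radial_map(mask)
  set.seed(3)
  p0 <- place_spot_at_radius(mask, 1L, 0, rmap = rmap)
  expect_identical(rmap$values[p0["y"] + 1L, p0["x"] + 1L], 0)
  p1 <- place_spot_at_radius(mask, 1L, 1, rmap = rmap)
  expect_identical(rmap$values[p1["y"] + 1L, p1["x"] + 1L], 1)
  # target 0.5 in a disk of radius 50 -> ~25 px from the center
  ctr <- which(rmap$values == 0, arr.ind = TRUE)[1, ]
  p5 <- place_spot_at_radius(mask, 1L, 0.5, rmap = rmap)
  d <- sqrt((p5["x"] + 1 - ctr[2])^2 + (p5["y"] + 1 - ctr[1])^2)
  expect_lt(abs(d - 25), 4)
  expect_error(place_spot_at_radius(mask, 1L, 1.4), "target_radial")
})

test_that("beta-distributed placement emulates peripheral bias", {
  tr <- list()
  for (s in 1:4) {
    sim <- sim_small(400 + s, image_size = 768L, n_nuclei = 12L,
                     radial_model = list(type = "beta", alpha = 5, beta = 2))
    tr[[s]] <- sim$truth$alleles$radial_true
  }
  m <- mean(unlist(tr))
  expect_lt(abs(m - 5 / 7), 0.04)
})

test_that("ground-truth activity fractions are binomially distributed", {
  hits <- 0L; n_tot <- 0L; x_tot <- 0L
  for (s in 1:6) {
    sim <- sim_small(600 + s, p_active = 0.3)
    x_tot <- x_tot + sum(sim$truth$alleles$active)
    n_tot <- n_tot + nrow(sim$truth$alleles)
  }
  ci <- stats::binom.test(x_tot, n_tot)$conf.int
  expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
})

test_that("simulate_plate writes the documented tree and refuses overwrites", {
  out <- file.path(withr::local_tempdir(), "plate")
  cfg <- simulation_config(seed = 2, n_wells = 2L, n_fields = 2L,
                           image_size = 256L, n_nuclei = 2L,
                           nucleus_radius_range = c(30, 36))
  res <- simulate_plate(cfg, out, mode = "simultaneous")
  expect_identical(nrow(res$layout), 2L * 2L * 3L)   # wells x fields x channels
  expect_true(all(file.exists(res$layout$path)))
  expect_true(file.exists(file.path(out, "simulation_config.yaml")))
  gt <- utils::read.csv(list.files(out, "ground_truth", recursive = TRUE,
                                   full.names = TRUE)[1])
  expect_true(all(c("nucleus", "allele", "active", "radial_true") %in%
                    names(gt)))
  expect_error(simulate_plate(cfg, out, mode = "simultaneous"), "not empty")
  # sequential plates carry two tagged acquisitions per field
  out2 <- file.path(withr::local_tempdir(), "plate2")
  res2 <- simulate_plate(simulation_config(seed = 3, image_size = 256L,
                                           n_nuclei = 2L,
                                           nucleus_radius_range = c(30, 36),
                                           sequential_shift = c(3L, -2L)),
                         out2, mode = "sequential")
  expect_setequal(unique(res2$layout$tag), c("dna_pass", "rna_pass"))
})
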