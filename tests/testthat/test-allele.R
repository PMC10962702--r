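mk_nuclei <- function(labels, pass = TRUE) {
  data.frame(label = labels, area_um2 = 100, equivalent_diameter_um = 12,
             perimeter_um = 35, circularity = 0.99, centroid_x = 0,
             centroid_y = 0, touches_border = FALSE,
             qc_pass = rep_len(pass, length(labels)))
}

mk_spot <- function(label, channel, x, y, ps = 0.108) {
  data.frame(well = "A01", field = 1L, channel = channel, x = x, y = y,
             x_um = x * ps, y_um = y * ps, intensity = 100,
             log_response = 50, nucleus_label = label, radial = 0.5)
}

test_that("spot counts bin as printed and gate the analyzable flag", {
  spots <- rbind(mk_spot(1L, "DNA", c(10, 20, 30), 10),
                 mk_spot(2L, "DNA", c(40, 50), 40),
                 mk_spot(2L, "RNA", 41, 41))
  cells <- count_and_bin(spots, mk_nuclei(1:3))
  expect_identical(cells$dna_bin, c(">=3", "2", "0"))
  expect_identical(cells$rna_bin, c("0", "1", "0"))
  expect_identical(cells$analyzable, c(FALSE, TRUE, FALSE))
  # cells in QC-failed nuclei are not reported
  cells2 <- count_and_bin(spots, mk_nuclei(1:3, pass = c(TRUE, FALSE, TRUE)))
  expect_identical(cells2$nucleus_label, c(1L, 3L))
  # >2 RNA spots excludes the cell entirely
  spots3 <- rbind(mk_spot(1L, "DNA", c(10, 20), 10),
                  mk_spot(1L, "RNA", c(30, 40, 50), 30))
  expect_false(count_and_bin(spots3, mk_nuclei(1L))$analyzable)
})

test_that("minimum DNA-RNA distances follow the per-DNA-spot rule", {
  cell <- data.frame(analyzable = TRUE)
  dna <- mk_spot(1L, "DNA", c(0, 10), c(0, 0))
  # 3-4-5 triangle: DNA at (0,0), RNA at (3,4) -> 5 px = 0.54 um
  rna <- mk_spot(1L, "RNA", 3, 4)
  d <- min_dna_rna_distance(cell, dna, rna)
  expect_equal(d[1], 0.54, tolerance = 1e-12)
  # no RNA: both distances NA
  expect_identical(min_dna_rna_distance(cell, dna, rna[0, ]),
                   rep(NA_real_, 2))
  # random 2 x 2 configuration equals the brute-force all-pairs minimum
  set.seed(77)
  for (i in 1:10) {
    dna <- mk_spot(1L, "DNA", runif(2, 0, 50), runif(2, 0, 50))
    rna <- mk_spot(1L, "RNA", runif(2, 0, 50), runif(2, 0, 50))
    d <- min_dna_rna_distance(cell, dna, rna)
    brute <- vapply(1:2, function(k)
      min(sqrt((dna$x_um[k] - rna$x_um)^2 + (dna$y_um[k] - rna$y_um)^2)),
      numeric(1))
    expect_equal(d, brute)
  }
  expect_error(min_dna_rna_distance(data.frame(analyzable = FALSE), dna, rna),
               "analyzable")
})

test_that("allele classification applies the strict 1-micron rule", {
  expect_identical(classify_allele(c(0.54, NA, 1.0, 0.999, 2.3)),
                   c("Active", "NoTranscription", "Inactive", "Active",
                     "Inactive"))
  expect_error(classify_allele(-0.1), "non-negative")
})

test_that("every analyzable cell yields exactly two alleles partitioned by status", {
  sim <- sim_small(88)
  res <- run_pipeline(sim$acquisitions, mode = "simultaneous",
                      config = run_config())
  expect_identical(nrow(res$alleles), 2L * sum(res$cells$analyzable))
  expect_identical(sum(res$summaries$n_alleles), nrow(res$alleles))
  expect_true(all(table(res$alleles$nucleus_label) == 2L))
  expect_true(all(res$alleles$status %in%
                    c("Active", "Inactive", "NoTranscription")))
})

test_that("radial summaries aggregate means, sds and shell histograms", {
  al <- data.frame(well = "A01", field = 1L, nucleus_label = c(1L, 1L, 2L),
                   allele = c(1L, 2L, 1L), x_um = 0, y_um = 0,
                   min_rna_distance_um = c(0.5, NA, NA),
                   status = c("Active", "NoTranscription", "NoTranscription"),
                   radial = c(0.6, 0.1, 0.9),
                   shell = c(3L, 1L, 5L))
  s <- summarize_radial(al)
  act <- s[s$status == "Active", ]
  expect_identical(act$n_alleles, 1L)
  expect_identical(act$mean_radial, 0.6)
  expect_identical(act$sd_radial, 0)       # single allele: sd reported as 0
  expect_true(act$single_allele)
  nt <- s[s$status == "NoTranscription", ]
  expect_identical(nt$shell_1 + nt$shell_5, 2L)
  expect_identical(sum(s$n_alleles), 3L)
  # boundary-forced alleles average exactly 1
  al$radial <- 1; al$shell <- 5L
  expect_true(all(summarize_radial(al)$mean_radial == 1))
})
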