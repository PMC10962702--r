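#' @title Allele-level accounting and classification
#' @description The diploid analysis unit is one DNA FISH spot (one allele).
#' Per-cell spot counts are binned into "0"/"1"/"2"/">=3"; only cells with
#' exactly 2 DNA spots and at most 2 RNA spots are analyzable. Each DNA spot
#' receives the minimum Euclidean distance (in microns, 2D on maximum
#' projections) to any RNA spot of its cell, NA when the cell has no RNA.
#' NA distances classify as "NoTranscription", distances strictly below the
#' 1 um threshold as "Active", and the remainder as "Inactive". One RNA spot
#' may validate both DNA spots; no one-to-one matching is enforced.
#' @name allele_pipeline
NULL

.bin_count <- function(n) {
  ifelse(n >= 3L, ">=3", as.character(n))
}

#' Per-cell spot counts, bins and the analyzable flag
#'
#' One record per QC-passing nucleus. `analyzable` is TRUE iff the cell has
#' exactly 2 DNA spots and 2 or fewer RNA spots.
#'
#' @param spots Spot data frame, already nucleus-assigned (see
#'   [assign_spots_to_nuclei()]); spots in QC-failed nuclei are ignored.
#' @param nuclei Nucleus data frame with `qc_pass` set (see [qc_filter()]).
#' @param well,field Identifiers for the records (taken from the spots when
#'   present).
#' @return Cell data frame: `well`, `field`, `nucleus_label`, `n_dna`,
#'   `n_rna`, `dna_bin`, `rna_bin`, `analyzable`.
#' @export
count_and_bin <- function(spots, nuclei, well = NA_character_,
                          field = NA_integer_) {
  keep <- nuclei[isTRUE_v(nuclei$qc_pass), , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(well = character(), field = integer(),
                      nucleus_label = integer(), n_dna = integer(),
                      n_rna = integer(), dna_bin = character(),
                      rna_bin = character(), analyzable = logical()))
  if (nrow(spots)) {
    if (!all(is.na(spots$well))) well <- spots$well[1]
    if (!all(is.na(spots$field))) field <- spots$field[1]
  }
  cnt <- function(ch) {
    s <- spots[spots$channel == ch & spots$nucleus_label %in% keep$label, ,
               drop = FALSE]
    tab <- table(factor(s$nucleus_label, levels = keep$label))
    as.integer(tab)
  }
  n_dna <- cnt("DNA"); n_rna <- cnt("RNA")
  data.frame(well = well, field = as.integer(field),
             nucleus_label = keep$label,
             n_dna = n_dna, n_rna = n_rna,
             dna_bin = .bin_count(n_dna), rna_bin = .bin_count(n_rna),
             analyzable = n_dna == 2L & n_rna <= 2L)
}

# treat NA as FALSE (vectorized)
isTRUE_v <- function(x) !is.na(x) & x

#' Minimum DNA-RNA distance per DNA spot of one analyzable cell
#'
#' All pairwise distances between the cell's 2 DNA spots and its RNA spots
#' (if any) are computed in microns; each DNA spot keeps its minimum. Cells
#' without RNA spots yield NA for both DNA spots.
#'
#' @param cell One row of the cell table; must be analyzable.
#' @param dna_spots,rna_spots Spot data frames restricted to this cell's
#'   nucleus (columns `x_um`, `y_um`).
#' @return Numeric vector, one minimum distance (um) per DNA spot, NA when
#'   there is no RNA spot.
#' @export
min_dna_rna_distance <- function(cell, dna_spots, rna_spots) {
  if (!isTRUE(cell$analyzable))
    stop("min_dna_rna_distance requires an analyzable cell (2 DNA, <=2 RNA spots)")
  if (nrow(dna_spots) != 2L)
    stop("analyzable cell must carry exactly 2 DNA spots")
  if (!nrow(rna_spots)) return(rep(NA_real_, 2L))
  vapply(seq_len(2L), function(i) {
    min(sqrt((dna_spots$x_um[i] - rna_spots$x_um)^2 +
               (dna_spots$y_um[i] - rna_spots$y_um)^2))
  }, numeric(1))
}

#' Classify alleles from their minimum DNA-RNA distance
#'
#' NA -> `"NoTranscription"`; `distance < threshold_um` -> `"Active"`;
#' otherwise `"Inactive"`. The threshold is strict: a distance of exactly
#' 1 um is Inactive.
#'
#' @param distance_um Numeric vector of distances (microns) or NA.
#' @param threshold_um Activity threshold in microns (default 1.0).
#' @return Character vector of statuses.
#' @export
classify_allele <- function(distance_um, threshold_um = 1.0) {
  if (any(!is.na(distance_um) & distance_um < 0))
    stop("distances must be non-negative")
  ifelse(is.na(distance_um), "NoTranscription",
         ifelse(distance_um < threshold_um, "Active", "Inactive"))
}

#' Build the allele table for one field
#'
#' Expands every analyzable cell into exactly 2 allele records with minimum
#' DNA-RNA distance, activity status, radial position and shell.
#'
#' @param cells Cell table from [count_and_bin()].
#' @param spots Nucleus-assigned spot table carrying a `radial` column for
#'   DNA spots (see [radial_of_spot()]).
#' @param activity_threshold_um Activity threshold (microns).
#' @param shell_width Radial shell width.
#' @return Allele data frame: `well`, `field`, `nucleus_label`, `allele`,
#'   `x_um`, `y_um`, `min_rna_distance_um`, `status`, `radial`, `shell`.
#' @export
allele_records <- function(cells, spots, activity_threshold_um = 1.0,
                           shell_width = 0.2) {
  ana <- cells[cells$analyzable, , drop = FALSE]
  if (!nrow(ana)) return(.empty_allele_table())
  out <- vector("list", nrow(ana))
  for (i in seq_len(nrow(ana))) {
    cell <- ana[i, ]
    sel <- spots$nucleus_label == cell$nucleus_label &
      spots$well %in% cell$well & spots$field %in% cell$field
    dna <- spots[sel & spots$channel == "DNA", , drop = FALSE]
    rna <- spots[sel & spots$channel == "RNA", , drop = FALSE]
    d <- min_dna_rna_distance(cell, dna, rna)
    rad <- dna$radial
    out[[i]] <- data.frame(well = cell$well, field = cell$field,
                           nucleus_label = cell$nucleus_label,
                           allele = 1:2,
                           x_um = dna$x_um, y_um = dna$y_um,
                           min_rna_distance_um = d,
                           status = classify_allele(d, activity_threshold_um),
                           radial = rad,
                           shell = shell_bin(rad, shell_width))
  }
  do.call(rbind, out)
}

.empty_allele_table <- function() {
  data.frame(well = character(), field = integer(), nucleus_label = integer(),
             allele = integer(), x_um = numeric(), y_um = numeric(),
             min_rna_distance_um = numeric(), status = character(),
             radial = numeric(), shell = integer())
}

#' Radial summaries per group
#'
#' Mean and standard deviation of the (un-binned) radial values plus the
#' shell histogram, per group. Groups with no alleles are omitted; groups of
#' size 1 report `sd_radial = 0` and are flagged.
#'
#' @param alleles Allele table from [allele_records()].
#' @param group_by Character vector of allele-table column names to group on
#'   (default `"status"`).
#' @param shell_width Shell width used for the histogram columns.
#' @return Data frame with the grouping columns, `n_alleles`, `mean_radial`,
#'   `sd_radial`, `single_allele` flag and `shell_1` .. `shell_k` counts.
#' @export
summarize_radial <- function(alleles, group_by = "status",
                             shell_width = 0.2) {
  n_shell <- as.integer(ceiling(1 / shell_width - 1e-9))
  if (!nrow(alleles)) {
    base <- stats::setNames(
      as.data.frame(matrix(character(), 0, length(group_by))), group_by)
    base$n_alleles <- integer(); base$mean_radial <- numeric()
    base$sd_radial <- numeric(); base$single_allele <- logical()
    for (s in seq_len(n_shell)) base[[paste0("shell_", s)]] <- integer()
    return(base)
  }
  key <- interaction(alleles[group_by], drop = TRUE, lex.order = TRUE)
  parts <- split(alleles, key)
  rows <- lapply(parts, function(p) {
    r <- data.frame(p[1, group_by, drop = FALSE],
                    n_alleles = nrow(p),
                    mean_radial = mean(p$radial),
                    sd_radial = if (nrow(p) > 1L) stats::sd(p$radial) else 0,
                    single_allele = nrow(p) == 1L,
                    row.names = NULL)
    h <- tabulate(p$shell, nbins = n_shell)
    for (s in seq_len(n_shell)) r[[paste0("shell_", s)]] <- h[s]
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare radial distributions of two allele groups
#'
#' Two-sided two-sample KS test on the un-binned radial values of two levels
#' of a grouping column (shells are for reporting only).
#'
#' @param alleles Allele table.
#' @param group_col Column name (default `"status"`).
#' @param g1,g2 The two group levels to compare.
#' @param exact_max Passed to [ks_two_sample()].
#' @return A `ks_result`.
#' @export
compare_radial <- function(alleles, group_col = "status", g1 = "Active",
                           g2 = "Inactive", exact_max = 100) {
  x <- alleles$radial[alleles[[group_col]] == g1]
  y <- alleles$radial[alleles[[group_col]] == g2]
  ks_two_sample(x, y, exact_max = exact_max)
}
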