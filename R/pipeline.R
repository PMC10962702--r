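#' @title End-to-end pipeline
#' @description One call from acquisitions to tables. The sequential mode
#' first registers each RNA acquisition onto its DNA acquisition via the
#' shared DAPI channel; both modes then share the same tail: nucleus
#' segmentation and QC, LoG spot detection and nucleus assignment, radial
#' positioning, per-cell accounting and allele classification.
#' @name pipeline
NULL

# Process one merged (single-tag) acquisition into per-field tables.
.process_field <- function(acq, config, mask = NULL) {
  dapi <- acq_channel(acq, "dapi")
  if (is.null(mask))
    mask <- segment_nuclei(dapi, smooth_sigma = config$seg_smooth_sigma,
                           min_area_px = config$seg_min_area_px)
  nuclei <- measure_nuclei(mask)
  nuclei <- qc_filter(nuclei, config$min_diameter_um, config$min_circularity,
                      config$drop_border)
  if (nrow(nuclei)) {
    nuclei$well <- acq$well; nuclei$field <- acq$field
    nuclei <- nuclei[, c("well", "field",
                         setdiff(names(nuclei), c("well", "field")))]
  } else {
    nuclei <- cbind(data.frame(well = character(), field = integer()),
                    nuclei)
  }

  spots <- list()
  for (ch in c("dna", "rna")) {
    if (!ch %in% names(acq$channels)) next
    s <- detect_spots(acq_channel(acq, ch), sigma = config$log_sigma,
                      threshold = config$log_threshold,
                      adaptive = config$adaptive_threshold,
                      k = config$adaptive_k,
                      channel = toupper(ch), well = acq$well,
                      field = acq$field)
    spots[[ch]] <- assign_spots_to_nuclei(s, mask)
  }
  spots <- if (length(spots)) do.call(rbind, spots) else .empty_spot_table()
  rownames(spots) <- NULL

  # drop spots whose nucleus failed QC, then annotate radial position
  pass <- nuclei$label[isTRUE_v(nuclei$qc_pass)]
  spots <- spots[spots$nucleus_label %in% pass, , drop = FALSE]
  spots$radial <- if (nrow(spots)) {
    rmap <- radial_map(mask)
    radial_of_spot(spots, rmap)
  } else numeric(0)
  spots <- sort_spots(spots)

  cells <- count_and_bin(spots, nuclei, well = acq$well, field = acq$field)
  alleles <- allele_records(cells, spots,
                            activity_threshold_um = config$activity_threshold_um,
                            shell_width = config$shell_width)
  reg <- acq$meta$registration
  reg_row <- data.frame(well = acq$well, field = acq$field,
                        dx = if (is.null(reg)) 0L else reg$estimated_dx,
                        dy = if (is.null(reg)) 0L else reg$estimated_dy,
                        confidence = if (is.null(reg)) NA_real_
                        else reg$confidence)
  list(nuclei = nuclei, spots = spots, cells = cells, alleles = alleles,
       registration = reg_row)
}

# Pair tagged sequential acquisitions by (well, field).
.pair_sequential <- function(acquisitions) {
  if (all(vapply(acquisitions,
                 function(a) is.list(a) && !inherits(a, "acquisition") &&
                   all(c("dna", "rna") %in% names(a)), logical(1))))
    return(acquisitions)
  tags <- vapply(acquisitions, `[[`, character(1), "tag")
  key <- vapply(acquisitions,
                function(a) sprintf("%s_f%03d", a$well, a$field), character(1))
  dna <- acquisitions[tags == "dna_pass"]; kd <- key[tags == "dna_pass"]
  rna <- acquisitions[tags == "rna_pass"]; kr <- key[tags == "rna_pass"]
  missing <- c(setdiff(kd, kr), setdiff(kr, kd))
  if (length(missing))
    stop(sprintf("unpaired sequential acquisitions: %s",
                 paste(sort(missing), collapse = ", ")))
  lapply(kd, function(k) list(dna = dna[[match(k, kd)]],
                              rna = rna[[match(k, kr)]]))
}

#' Run the full analysis pipeline
#'
#' @param acquisitions For `mode = "simultaneous"`: a list of `acquisition`
#'   objects with `dapi`, `dna` and `rna` channels. For
#'   `mode = "sequential"`: either a list of `list(dna =, rna =)` acquisition
#'   pairs or a flat list of acquisitions tagged `"dna_pass"` /
#'   `"rna_pass"`, paired by well and field (unpaired fields are an error).
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, all tables and a
#'   run manifest are written there.
#' @param masks Optional list of precomputed `label_mask` objects, one per
#'   field (positional), to bypass the built-in segmenter.
#' @return List of data frames: `nuclei`, `cells`, `spots`, `alleles`,
#'   `summaries` (radial summaries per status), `registration` (per-field
#'   vectors), plus the `config` used.
#' @export
run_pipeline <- function(acquisitions, mode = config$mode,
                         config = run_config(), out_dir = NULL,
                         masks = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (mode == "sequential") {
    pairs <- .pair_sequential(acquisitions)
    acquisitions <- lapply(pairs, function(p)
      register_acquisition(p$dna, p$rna, max_shift = config$max_shift))
  }
  res <- lapply(seq_along(acquisitions), function(i)
    .process_field(acquisitions[[i]], config,
                   mask = if (!is.null(masks)) masks[[i]] else NULL))
  bind <- function(part) {
    out <- do.call(rbind, lapply(res, `[[`, part))
    rownames(out) <- NULL
    out
  }
  nuclei <- bind("nuclei"); spots <- bind("spots")
  cells <- bind("cells"); alleles <- bind("alleles")
  summaries <- summarize_radial(alleles, group_by = "status",
                                shell_width = config$shell_width)
  out <- list(nuclei = nuclei, cells = cells, spots = spots,
              alleles = alleles, summaries = summaries,
              registration = bind("registration"), config = config)
  if (!is.null(out_dir)) {
    write_tables(out, out_dir)
    write_manifest(out_dir, config = config, seed = config$seed)
  }
  out
}
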