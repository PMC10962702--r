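#' @title Plate layout, tables and manifests
#' @description File-system conventions: per-field channel TIFFs named
#' `<well>_f<field>_<channel>_<tag>.tif` grouped in per-well directories;
#' result tables as flat CSVs, partitioned one file per well (cells, nuclei)
#' and per well and channel (spots) alongside concatenated master tables.
#' NA distances are serialized as the literal token `NA`. Every output
#' directory receives one JSON manifest recording the configuration, seed,
#' package version and input file hashes.
#' @name io
NULL

# The one place the image file naming convention is parsed.
.parse_image_name <- function(fn) {
  bn <- basename(fn)
  m <- regmatches(bn, regexec(
    "^([A-P][0-9]{2})_f([0-9]+)_([a-z]+)_(single|dna_pass|rna_pass)\\.tif{1,2}$",
    bn))[[1]]
  if (!length(m)) return(NULL)
  data.frame(well = m[2], field = as.integer(m[3]), channel = m[4],
             tag = m[5], path = fn)
}

#' Scan a plate directory
#'
#' Recursively finds channel TIFFs following the naming convention and
#' validates completeness: a `single` acquisition needs dapi, dna and rna;
#' a `dna_pass` needs dapi and dna; an `rna_pass` needs dapi and rna. All
#' gaps are reported in one aggregate error.
#'
#' @param root Plate directory.
#' @return An object of class `plate_layout`: list with `root` and `files`
#'   (data frame well/field/channel/tag/path). An empty directory yields an
#'   empty layout with a warning.
#' @export
load_plate <- function(root) {
  if (!dir.exists(root)) stop(sprintf("no such directory: %s", root))
  fns <- list.files(root, pattern = "\\.tiff?$", recursive = TRUE,
                    full.names = TRUE)
  rows <- Filter(Negate(is.null), lapply(fns, .parse_image_name))
  files <- if (length(rows)) do.call(rbind, rows)
  else data.frame(well = character(), field = integer(),
                  channel = character(), tag = character(),
                  path = character())
  if (!nrow(files)) warning(sprintf("empty plate layout under %s", root))
  need <- list(single = c("dapi", "dna", "rna"),
               dna_pass = c("dapi", "dna"), rna_pass = c("dapi", "rna"))
  gaps <- character()
  if (nrow(files)) {
    key <- interaction(files$well, files$field, files$tag, drop = TRUE)
    for (k in levels(key)) {
      grp <- files[key == k, ]
      missing <- setdiff(need[[grp$tag[1]]], grp$channel)
      if (length(missing))
        gaps <- c(gaps, sprintf("%s f%02d [%s]: missing %s", grp$well[1],
                                grp$field[1], grp$tag[1],
                                paste(missing, collapse = ", ")))
    }
  }
  if (length(gaps))
    stop(sprintf("incomplete plate layout:\n  %s",
                 paste(gaps, collapse = "\n  ")))
  structure(list(root = root, files = files), class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout %s: %d wells, %d files>\n", x$root,
              length(unique(x$files$well)), nrow(x$files)))
  invisible(x)
}

#' Load the acquisitions of a plate layout
#'
#' @param layout A `plate_layout`.
#' @param pixel_size Microns per pixel to attach.
#' @return A list of `acquisition` objects, one per (well, field, tag),
#'   sorted by well then field (suitable for [run_pipeline()]; sequential
#'   passes are returned tagged and are paired there).
#' @export
load_acquisitions <- function(layout, pixel_size = 0.108) {
  stopifnot(inherits(layout, "plate_layout"))
  f <- layout$files
  if (!nrow(f)) return(list())
  f <- f[order(f$well, f$field, f$tag), ]
  key <- interaction(f$well, f$field, f$tag, drop = TRUE)
  lapply(split(f, key), function(grp) {
    chans <- stats::setNames(
      lapply(grp$path, function(p) read_gray_tiff(p, pixel_size)$pixels),
      grp$channel)
    acquisition(chans, pixel_size = pixel_size, well = grp$well[1],
                field = grp$field[1], tag = grp$tag[1])
  })
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Write pipeline result tables
#'
#' Cells and nuclei are partitioned per well, spots per well and channel;
#' concatenated master tables (`cells.csv`, `nuclei.csv`, `spots.csv`,
#' `alleles.csv`, `summaries.csv`, `registration.csv`) are always written.
#'
#' @param result List of tables as returned by [run_pipeline()] (any subset
#'   of nuclei/cells/spots/alleles/summaries/registration).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the character vector of files written.
#' @export
write_tables <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in intersect(c("nuclei", "cells", "spots", "alleles", "summaries",
                         "registration"), names(result))) {
    df <- result[[nm]]
    if (is.null(df)) next
    written <- c(written, .write_csv(df, file.path(out_dir,
                                                   paste0(nm, ".csv"))))
    if (nm %in% c("nuclei", "cells") && nrow(df))
      for (w in unique(df$well))
        written <- c(written, .write_csv(
          df[df$well == w, , drop = FALSE],
          file.path(out_dir, sprintf("%s_%s.csv", nm, w))))
    if (nm == "spots" && nrow(df))
      for (w in unique(df$well)) for (ch in unique(df$channel)) {
        part <- df[df$well == w & df$channel == ch, , drop = FALSE]
        if (nrow(part))
          written <- c(written, .write_csv(
            part, file.path(out_dir, sprintf("spots_%s_%s.csv", w, ch))))
      }
  }
  invisible(written)
}

#' Read back master tables written by [write_tables()]
#'
#' @param out_dir Directory containing the CSVs.
#' @return Named list of data frames (only the tables present on disk).
#' @export
read_tables <- function(out_dir) {
  out <- list()
  for (nm in c("nuclei", "cells", "spots", "alleles", "summaries",
               "registration")) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(p))
      out[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  out
}

#' Write a run manifest
#'
#' @param out_dir Output directory.
#' @param config Configuration object (any list-like; serialized as-is).
#' @param seed Seed used by the run.
#' @param inputs Character vector of input file paths; their MD5 hashes are
#'   recorded.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(out_dir, config = NULL, seed = NA_integer_,
                           inputs = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(
    tool = "hifishr",
    version = as.character(utils::packageVersion("hifishr")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    inputs = if (length(inputs))
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    else NULL)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
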