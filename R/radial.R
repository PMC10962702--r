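#' @title Normalized radial position within the nucleus
#' @description Radial position is defined from the Euclidean distance
#' transform of the binary nucleus mask: each nucleus pixel carries its
#' distance to the nearest background pixel, the transform is normalized per
#' nucleus by its maximum and subtracted from 1. The deepest pixel(s) of a
#' nucleus thus map to 0 ("center") and the periphery maps to 1. Note the
#' "center" is the deepest point of the distance transform, not the
#' centroid; for non-convex nuclei these differ.
#' @name radial_geometry
NULL

# One pass over the mask: per-label pixel coordinates (matrix cbind(r, c)).
.label_pixels <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  h <- nrow(lab)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  vals <- lab[idx]
  lapply(split(seq_along(idx), vals), function(i) cbind(r = r[i], c = cc[i]))
}

# Bounding box of a label, padded; returns row/col ranges.
.label_bbox <- function(lab, label, pad = 1L) {
  idx <- which(lab == label, arr.ind = TRUE)
  if (!nrow(idx)) stop(sprintf("label %d not present in mask", label))
  list(r = max(1L, min(idx[, 1]) - pad):min(nrow(lab), max(idx[, 1]) + pad),
       c = max(1L, min(idx[, 2]) - pad):min(ncol(lab), max(idx[, 2]) + pad))
}

#' Euclidean distance transform of one nucleus
#'
#' Distance of each pixel of the given nucleus to the nearest non-nucleus
#' pixel (image borders count as background). Background pixels are 0.
#'
#' @param mask A `label_mask`.
#' @param label Positive label present in the mask.
#' @return A numeric matrix of the full mask dimensions: distances (in
#'   pixels) inside the chosen nucleus, 0 elsewhere.
#' @export
distance_transform <- function(mask, label) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  bb <- .label_bbox(lab, label)
  sub <- lab[bb$r, bb$c, drop = FALSE] == label
  # pad with one background row/col so that image borders act as background
  padded <- matrix(0, length(bb$r) + 2L, length(bb$c) + 2L)
  padded[2:(length(bb$r) + 1L), 2:(length(bb$c) + 1L)] <- sub
  dt <- as.matrix(EBImage::distmap(padded, metric = "euclidean"))
  out <- matrix(0, nrow(lab), ncol(lab))
  out[bb$r, bb$c] <- dt[2:(length(bb$r) + 1L), 2:(length(bb$c) + 1L)]
  out
}

#' Per-pixel normalized radial map
#'
#' For every nucleus separately: `radial = 1 - dt / max(dt)`, where `dt` is
#' the Euclidean distance transform. Pixels 8-adjacent to background are
#' clamped to exactly 1 so the periphery reads 1; the deepest pixel(s) read
#' exactly 0. Degenerate nuclei whose maximum depth is <= 1 px are assigned
#' 0 everywhere (such nuclei never survive QC). Background is NA.
#'
#' @param mask A `label_mask`.
#' @return An object of class `radial_map`: list with `values` (matrix in
#'   [0,1] inside nuclei, NA outside), `max_distance` (named per-label vector
#'   of maximum depths in pixels) and `pixel_size`.
#' @export
radial_map <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  h <- nrow(lab); w <- ncol(lab)
  values <- matrix(NA_real_, h, w)
  pixl <- .label_pixels(lab)
  if (!length(pixl))
    return(structure(list(values = values, max_distance = numeric(0),
                          pixel_size = mask$pixel_size),
                     class = "radial_map"))
  # nuclei are disjoint components, so one global transform (with a 1-px
  # background pad making image borders count as background) serves them all
  fg <- lab > 0L
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- fg
  dt <- as.matrix(EBImage::distmap(padded,
                                   metric = "euclidean"))[2:(h + 1L),
                                                          2:(w + 1L),
                                                          drop = FALSE]
  # a foreground pixel is 8-adjacent to background iff its distance <= sqrt(2)
  bnd <- fg & dt <= sqrt(2) + 1e-6
  labs <- as.integer(names(pixl))
  max_d <- stats::setNames(numeric(length(labs)), labs)
  for (l in names(pixl)) {
    px <- pixl[[l]]
    d <- dt[px]
    mx <- max(d)
    max_d[l] <- mx
    if (mx <= 1) {
      values[px] <- 0
    } else {
      v <- 1 - d / mx
      v[bnd[px]] <- 1
      values[px] <- v
    }
  }
  structure(list(values = values, max_distance = max_d,
                 pixel_size = mask$pixel_size),
            class = "radial_map")
}

#' @export
print.radial_map <- function(x, ...) {
  cat(sprintf("<radial_map %d x %d px, %d nuclei>\n",
              nrow(x$values), ncol(x$values), length(x$max_distance)))
  invisible(x)
}

#' Radial position of spots
#'
#' Looks up the normalized radial value at each spot's pixel. Spots must lie
#' inside a nucleus (assign and filter them first).
#'
#' @param spots Spot data frame with 0-based `x`, `y` columns (a single spot
#'   row works too).
#' @param rmap A `radial_map`.
#' @return Numeric vector of radial values in [0, 1].
#' @export
radial_of_spot <- function(spots, rmap) {
  stopifnot(inherits(rmap, "radial_map"))
  r <- rmap$values[cbind(spots$y + 1L, spots$x + 1L)]
  if (any(is.na(r)))
    stop("spot outside all nuclei: radial position undefined")
  r
}

#' Bin normalized radial values into shells
#'
#' Shells partition [0, 1] into equal-width, half-open intervals
#' `[0, w), [w, 2w), ...` with the last shell closed at 1.
#'
#' @param r Numeric vector of radial values in [0, 1].
#' @param width Shell width (default 0.2, i.e. 5 shells).
#' @return Integer shell indices in `1..ceiling(1/width)`.
#' @export
shell_bin <- function(r, width = 0.2) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("radial values must lie in [0, 1]")
  n <- as.integer(ceiling(1 / width - 1e-9))
  pmin(as.integer(floor(r / width)) + 1L, n)
}

#' Export a radial map as a 32-bit float TIFF for inspection
#'
#' Background (NA) pixels are written as 0 and nucleus pixels as
#' `(1 + radial) / 2`, i.e. the nucleus interior spans 0.5..1; this keeps the
#' file a valid [0,1] float TIFF while remaining unambiguous.
#'
#' @param rmap A `radial_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_radial_tiff <- function(rmap, path) {
  v <- rmap$values
  enc <- ifelse(is.na(v), 0, (1 + v) / 2)
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  invisible(path)
}
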