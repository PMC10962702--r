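#' @title FISH spot detection by Laplacian of Gaussian
#' @description Diffraction-limited FISH signals are detected as local maxima
#' of the scale-normalized, sign-flipped Laplacian-of-Gaussian response
#' `-sigma^2 * laplacian(G_sigma * img)`, so bright blobs of scale ~sigma
#' yield positive peaks. Detection is single-scale: FISH spots are
#' near-constant size, and sigma plus the response threshold are the per-run
#' tuning parameters. Each detected spot is then assigned to the nucleus
#' whose mask pixel it falls on; spots outside all nuclei are discarded.
#' @name spot_detection
NULL

# 4-neighbor discrete Laplacian with replicated edges (small matrices).
.laplacian <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- m[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  left  <- m[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- m[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  up + down + left + right - 4 * m
}

# -sigma^2 * (discrete Laplacian of a sampled Gaussian): convolving with
# this kernel equals smoothing followed by the discrete Laplacian, in one
# filtering pass.
.log_kernel <- function(sigma) {
  r <- ceiling(3.5 * sigma) + 1L
  g1 <- stats::dnorm(-r:r, sd = sigma); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  -sigma^2 * .laplacian(G)
}

#' Scale-normalized LoG response
#'
#' Computes `-sigma^2 * laplacian(G_sigma * img)` (Gaussian smoothing
#' followed by the discrete 4-neighbor Laplacian, sign-flipped and scale
#' normalized), implemented as a single convolution with the equivalent
#' kernel; image borders are replicated.
#'
#' @param img `gray_image` or matrix.
#' @param sigma Gaussian scale in pixels; must be positive.
#' @return Matrix of responses, same dimensions as the input; positive at
#'   bright blob centers.
#' @export
log_filter <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  px <- .as_pixels(img)
  k <- .log_kernel(sigma)
  if (min(dim(px)) <= nrow(k) + 2L)
    return(-sigma^2 * .laplacian(.gauss_smooth_small(px, sigma)))
  as.matrix(EBImage::filter2(px, k))
}

#' Detect FISH spots
#'
#' Local maxima of the LoG response above a threshold. A candidate must be
#' >= its 8-neighborhood; candidates closer than `2 * sigma` pixels are
#' merged keeping the stronger response (plateau ties resolved row-major),
#' which prevents double counting of one transcription site.
#'
#' @param img `gray_image` (or matrix; pixel size then defaults to 0.108).
#' @param sigma LoG scale in pixels (default 2, ~0.22 um objects at the
#'   default sampling).
#' @param threshold Absolute response threshold (must be >= 0). Ignored when
#'   `adaptive = TRUE`.
#' @param adaptive If TRUE the threshold is `mean(resp) + k * sd(resp)`,
#'   computed per image.
#' @param k Multiplier for the adaptive mode (default 5).
#' @param channel Channel name stored on the spots (`"DNA"` or `"RNA"`).
#' @param well,field Identifiers stored on the spots.
#' @return Spot data frame, sorted by (y, x): columns `well`, `field`,
#'   `channel`, `x`, `y` (0-based pixels), `x_um`, `y_um`, `intensity` (raw
#'   image value at the maximum), `log_response`, `nucleus_label` (NA until
#'   assigned).
#' @export
detect_spots <- function(img, sigma = 2, threshold = 100, adaptive = FALSE,
                         k = 5, channel = "DNA", well = NA_character_,
                         field = NA_integer_) {
  if (!adaptive && (!is.numeric(threshold) || threshold < 0))
    stop("threshold must be >= 0")
  px <- .as_pixels(img)
  ps <- if (inherits(img, "gray_image")) img$pixel_size else 0.108
  resp <- log_filter(px, sigma)
  thr <- if (adaptive) mean(resp) + k * stats::sd(resp) else threshold

  # sparse candidate check: only above-threshold pixels are compared with
  # their 8-neighborhood (>= so that plateaus survive to the merge step)
  h <- nrow(resp); w <- ncol(resp)
  cand <- which(resp > thr)
  if (!length(cand)) return(.empty_spot_table())
  cr <- ((cand - 1L) %% h) + 1L
  cc <- ((cand - 1L) %/% h) + 1L
  ok <- rep(TRUE, length(cand))
  v <- resp[cand]
  for (d in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                 c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    nr <- cr + d[1]; nc <- cc + d[2]
    inb <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    ok[inb] <- ok[inb] & v[inb] >= resp[cbind(nr[inb], nc[inb])]
  }
  idx <- cbind(cr[ok], cc[ok])
  if (!nrow(idx))
    return(.empty_spot_table())

  r <- resp[idx]
  ord <- order(-r, idx[, 1], idx[, 2])     # strongest first, ties row-major
  idx <- idx[ord, , drop = FALSE]; r <- r[ord]
  keep <- logical(nrow(idx))
  min_d2 <- (2 * sigma)^2
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_len(nrow(idx))) {
    if (length(ky) == 0L ||
        all((ky - idx[i, 1])^2 + (kx - idx[i, 2])^2 >= min_d2)) {
      keep[i] <- TRUE
      ky <- c(ky, idx[i, 1]); kx <- c(kx, idx[i, 2])
    }
  }
  idx <- idx[keep, , drop = FALSE]; r <- r[keep]

  out <- data.frame(well = well, field = as.integer(field), channel = channel,
                    x = idx[, 2] - 1L, y = idx[, 1] - 1L,
                    x_um = (idx[, 2] - 1L) * ps, y_um = (idx[, 1] - 1L) * ps,
                    intensity = px[idx], log_response = r,
                    nucleus_label = NA_integer_)
  out[order(out$y, out$x), , drop = FALSE]
}

.empty_spot_table <- function() {
  data.frame(well = character(), field = integer(), channel = character(),
             x = integer(), y = integer(), x_um = numeric(), y_um = numeric(),
             intensity = numeric(), log_response = numeric(),
             nucleus_label = integer())
}

#' Assign spots to nuclei and drop orphans
#'
#' Sets `nucleus_label` to the mask value at each spot's pixel and removes
#' spots that do not overlap any nucleus (label 0).
#'
#' @param spots Spot data frame from [detect_spots()].
#' @param mask A `label_mask` with the same image dimensions.
#' @return The annotated, filtered spot data frame.
#' @export
assign_spots_to_nuclei <- function(spots, mask) {
  stopifnot(inherits(mask, "label_mask"))
  if (!nrow(spots)) { spots$nucleus_label <- integer(0); return(spots) }
  if (any(spots$x < 0 | spots$x >= ncol(mask$labels) |
          spots$y < 0 | spots$y >= nrow(mask$labels)))
    stop("spot coordinates fall outside the mask dimensions")
  spots$nucleus_label <- mask$labels[cbind(spots$y + 1L, spots$x + 1L)]
  spots[spots$nucleus_label > 0L, , drop = FALSE]
}

#' Canonical sort order for spot tables
#' @param spots Spot data frame.
#' @return The data frame sorted by (well, field, channel, y, x).
#' @export
sort_spots <- function(spots) {
  spots[order(spots$well, spots$field, spots$channel, spots$y, spots$x),
        , drop = FALSE]
}
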