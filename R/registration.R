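#' @title Translation registration of sequential acquisitions
#' @description In the sequential protocol the RNA and DNA hybridizations are
#' imaged in two separate rounds; the shared DAPI channel is used to estimate
#' the integer stage translation between rounds, which is then undone on all
#' channels of the RNA acquisition. The estimator maximizes the zero-mean
#' (per-overlap mean-subtracted) cross-correlation over a bounded displacement
#' window; the raw sliding-sum correlation surface is also exposed.
#' @name registration
NULL

# Linear (non-circular) cross-correlation for lags -m..m via zero-padded FFT.
# Returns a (2m+1) x (2m+1) matrix S with
#   S[dy + m + 1, dx + m + 1] = sum_{y,x} A(y,x) * B(y+dy, x+dx)
# summed over the overlap. Padding by m on each axis prevents wrap-around.
.xcorr_sums <- function(A, B, m) {
  h <- nrow(A); w <- ncol(A)
  H <- h + m; W <- w + m
  Ap <- matrix(0, H, W); Ap[seq_len(h), seq_len(w)] <- A
  Bp <- matrix(0, H, W); Bp[seq_len(h), seq_len(w)] <- B
  R <- Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp), inverse = TRUE)) /
    (H * W)
  lag <- -m:m
  R[(lag %% H) + 1, (lag %% W) + 1, drop = FALSE]
}

.check_same_dim <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (any(da != db))
    stop(sprintf("image dimensions differ: %dx%d vs %dx%d",
                 da[1], da[2], db[1], db[2]))
}

#' Raw cross-correlation surface over a displacement window
#'
#' Computes, for every integer displacement `(dx, dy)` with
#' `|dx|, |dy| <= max_shift`, the sliding sum
#' `C(dx, dy) = sum over the overlap of a(x, y) * b(x + dx, y + dy)`.
#' The implementation is FFT-based but is exactly the direct sum (up to
#' floating-point rounding).
#'
#' @param a,b `gray_image` objects (or matrices) of identical dimensions.
#' @param max_shift Half-width of the displacement window, in pixels.
#' @return An object of class `correlation_surface`: list with `values`
#'   (a `(2*max_shift+1)` square matrix indexed by `[dy + max_shift + 1,
#'   dx + max_shift + 1]`) and `max_shift`.
#' @export
cross_correlate <- function(a, b, max_shift) {
  A <- .as_pixels(a); B <- .as_pixels(b)
  .check_same_dim(A, B)
  m <- as.integer(max_shift)
  if (m < 0L) stop("max_shift must be non-negative")
  if (m >= min(dim(A)))
    stop(sprintf("max_shift (%d) must be smaller than the smallest image dimension (%d)",
                 m, min(dim(A))))
  structure(list(values = .xcorr_sums(A, B, m), max_shift = m),
            class = "correlation_surface")
}

#' @export
print.correlation_surface <- function(x, ...) {
  cat(sprintf("<correlation_surface window +/-%d px, peak %.6g>\n",
              x$max_shift, max(x$values)))
  invisible(x)
}

#' Estimate the integer translation between two DAPI images
#'
#' Returns the displacement `(dx, dy)` of `dapi_rna` relative to `dapi_dna`,
#' i.e. the vector `v` such that `dapi_rna(x, y) ~ dapi_dna(x - dx, y - dy)`.
#' The score maximized is the zero-mean cross-correlation: for each candidate
#' displacement both images are mean-subtracted over their overlap before the
#' product sum, so the peak reflects pattern alignment rather than overall
#' brightness. Ties at the peak are resolved by smallest `|dx| + |dy|`, then
#' row-major order (dy, then dx), and confidence is set to 1.
#'
#' @param dapi_dna,dapi_rna `gray_image` objects of identical dimensions;
#'   both must be non-constant.
#' @param max_shift Search half-width in pixels; defaults to 10% of the
#'   smaller image dimension.
#' @return An object of class `translation_vector`: list with integer `dx`,
#'   `dy`, `peak_value` (zero-mean correlation at the peak) and `confidence`
#'   (ratio of the peak to the best non-neighboring score).
#' @export
estimate_translation <- function(dapi_dna, dapi_rna, max_shift = NULL) {
  A <- .as_pixels(dapi_dna); B <- .as_pixels(dapi_rna)
  .check_same_dim(A, B)
  if (stats::sd(A) == 0 || stats::sd(B) == 0)
    stop("no registration content: constant image")
  if (is.null(max_shift)) max_shift <- max(1L, floor(0.1 * min(dim(A))))
  m <- as.integer(max_shift)
  if (m < 1L) stop("max_shift must be at least 1")
  if (m >= min(dim(A)))
    stop(sprintf("max_shift (%d) must be smaller than the smallest image dimension (%d)",
                 m, min(dim(A))))

  ones <- matrix(1, nrow(A), ncol(A))
  s_ab <- .xcorr_sums(A, B, m)
  s_a  <- .xcorr_sums(A, ones, m)   # sum of A over each overlap
  s_b  <- .xcorr_sums(ones, B, m)   # sum of B over each overlap
  lag <- -m:m
  n_ov <- outer(nrow(A) - abs(lag), ncol(A) - abs(lag))
  score <- s_ab - s_a * s_b / n_ov

  peak <- max(score)
  tol <- 1e-9 * max(abs(score)) + 1e-12
  cand <- which(score >= peak - tol, arr.ind = TRUE)
  dy <- cand[, 1] - m - 1L; dx <- cand[, 2] - m - 1L
  ord <- order(abs(dx) + abs(dy), dy, dx)
  best <- ord[1]
  tied <- length(ord) > 1L

  # peak prominence: best score outside the 3x3 neighborhood of the peak
  iy <- dy[best] + m + 1L; ix <- dx[best] + m + 1L
  excl <- score
  excl[max(1, iy - 1):min(2 * m + 1, iy + 1),
       max(1, ix - 1):min(2 * m + 1, ix + 1)] <- -Inf
  second <- max(excl)
  confidence <- if (tied) 1
  else if (is.finite(second) && second > 0) peak / second
  else Inf

  structure(list(dx = as.integer(dx[best]), dy = as.integer(dy[best]),
                 peak_value = peak, confidence = confidence),
            class = "translation_vector")
}

#' Construct a translation vector
#' @param dx,dy Integer pixel offsets.
#' @param peak_value,confidence Optional diagnostics.
#' @return A `translation_vector`.
#' @export
translation_vector <- function(dx, dy, peak_value = NA_real_,
                               confidence = NA_real_) {
  structure(list(dx = as.integer(dx), dy = as.integer(dy),
                 peak_value = peak_value, confidence = confidence),
            class = "translation_vector")
}

#' @export
print.translation_vector <- function(x, ...) {
  cat(sprintf("<translation (dx=%+d, dy=%+d), peak %.6g, confidence %.3g>\n",
              x$dx, x$dy, x$peak_value, x$confidence))
  invisible(x)
}

#' Apply an integer translation to an image
#'
#' The output satisfies `out(x, y) = b(x - dx, y - dy)` wherever the source
#' pixel exists; pixels mapping outside the input are set exactly to zero.
#' Output dimensions equal input dimensions.
#'
#' @param b `gray_image` or matrix.
#' @param v `translation_vector` (or list with `dx`, `dy`).
#' @return Same type as `b` (a `gray_image` keeps its pixel size).
#' @export
apply_translation <- function(b, v) {
  px <- .as_pixels(b)
  h <- nrow(px); w <- ncol(px)
  dx <- as.integer(v$dx); dy <- as.integer(v$dy)
  out <- matrix(0, h, w)
  rows <- seq_len(h); cols <- seq_len(w)
  dst_r <- rows[rows - dy >= 1L & rows - dy <= h]
  dst_c <- cols[cols - dx >= 1L & cols - dx <= w]
  if (length(dst_r) && length(dst_c))
    out[dst_r, dst_c] <- px[dst_r - dy, dst_c - dx]
  if (inherits(b, "gray_image")) gray_image(out, b$pixel_size) else out
}

#' Register a sequential RNA acquisition onto its DNA acquisition
#'
#' Estimates the translation between the two rounds from their shared DAPI
#' channels, then shifts every channel of the RNA acquisition by the negated
#' estimate so its content lines up with the DNA round. Returns a merged
#' acquisition (DAPI and DNA from the DNA round, registered RNA channel) with
#' the estimated and applied vectors recorded in `meta$registration`.
#'
#' @param dna_acq,rna_acq `acquisition` objects; both must contain a
#'   `"dapi"` channel of equal dimensions.
#' @param max_shift Search half-width in pixels (default 10% of the smaller
#'   image dimension).
#' @return A merged `acquisition` with tag `"single"`.
#' @export
register_acquisition <- function(dna_acq, rna_acq, max_shift = NULL) {
  stopifnot(inherits(dna_acq, "acquisition"), inherits(rna_acq, "acquisition"))
  for (acq in list(dna_acq, rna_acq))
    if (!"dapi" %in% names(acq$channels))
      stop(sprintf("acquisition %s f%02d is missing the DAPI channel",
                   acq$well, acq$field))
  v <- estimate_translation(acq_channel(dna_acq, "dapi"),
                            acq_channel(rna_acq, "dapi"),
                            max_shift = max_shift)
  inv <- translation_vector(-v$dx, -v$dy, v$peak_value, v$confidence)
  shifted <- lapply(rna_acq$channels, function(ch) apply_translation(ch, inv))
  channels <- dna_acq$channels[names(dna_acq$channels) != "rna"]
  for (nm in setdiff(names(shifted), names(channels)))
    channels[[nm]] <- shifted[[nm]]
  acquisition(channels, pixel_size = dna_acq$pixel_size,
              well = dna_acq$well, field = dna_acq$field, tag = "single",
              meta = c(dna_acq$meta,
                       list(registration = list(
                         estimated_dx = v$dx, estimated_dy = v$dy,
                         applied_dx = -v$dx, applied_dy = -v$dy,
                         peak_value = v$peak_value,
                         confidence = v$confidence))))
}
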