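#' @title Validation against simulator ground truth
#' @description Helpers that join pipeline outputs back onto the simulator's
#' per-allele truth, used for end-to-end validation: detected spots are
#' matched to true positions by nearest neighbor within a tolerance, and
#' allele statuses are compared against the truth-implied classification.
#' @name validate
NULL

#' Truth-implied allele status
#'
#' An active allele is `"Active"`. An inactive allele is `"Inactive"` when
#' its cell contains at least one RNA spot (some other allele is active) and
#' `"NoTranscription"` when the cell has no RNA at all.
#'
#' @param truth_alleles Ground-truth allele data frame from the simulator.
#' @return Character vector of expected statuses, aligned with the rows.
#' @export
truth_status <- function(truth_alleles) {
  key <- interaction(truth_alleles$well, truth_alleles$field,
                     truth_alleles$nucleus, drop = TRUE)
  any_active <- stats::ave(truth_alleles$active, key,
                           FUN = function(a) any(a) + 0) > 0
  ifelse(truth_alleles$active, "Active",
         ifelse(any_active, "Inactive", "NoTranscription"))
}

#' Greedy nearest-neighbor matching of detected to true spot positions
#'
#' @param det_x,det_y Detected coordinates (pixels, 0-based).
#' @param true_x,true_y True coordinates (pixels, 0-based).
#' @param tol_px Maximum match distance in pixels.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `match` (index of the matched truth row per detection, NA if
#'   unmatched) and `dist` (match distances in pixels).
#' @export
match_spots <- function(det_x, det_y, true_x, true_y, tol_px = 2) {
  n_det <- length(det_x); n_true <- length(true_x)
  match_idx <- rep(NA_integer_, n_det)
  dist_px <- rep(NA_real_, n_det)
  taken <- logical(n_true)
  if (n_det && n_true) {
    dd <- outer(det_x, true_x, "-")^2 + outer(det_y, true_y, "-")^2
    ord <- order(dd)
    for (k in ord) {
      if (dd[k] > tol_px^2) break
      i <- (k - 1L) %% n_det + 1L
      j <- (k - 1L) %/% n_det + 1L
      if (is.na(match_idx[i]) && !taken[j]) {
        match_idx[i] <- j; taken[j] <- TRUE; dist_px[i] <- sqrt(dd[k])
      }
    }
  }
  tp <- sum(!is.na(match_idx)); fp <- n_det - tp; fn <- n_true - tp
  precision <- if (n_det) tp / n_det else NA_real_
  recall <- if (n_true) tp / n_true else NA_real_
  f1 <- if (tp + fp + fn == 0L) 1            # nothing to find, nothing found
  else if (tp) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, match = match_idx, dist = dist_px)
}

#' Join pipeline alleles onto the ground truth
#'
#' Matches each pipeline allele record (one DNA spot) to the nearest
#' ground-truth allele of the same well and field within `tol_px` pixels and
#' appends the truth columns plus the truth-implied status.
#'
#' @param alleles Pipeline allele table.
#' @param truth_alleles Simulator ground-truth allele table.
#' @param pixel_size Microns per pixel (to convert the allele `x_um` back to
#'   pixels).
#' @param tol_px Match tolerance in pixels.
#' @return The matched subset of `alleles` with extra columns
#'   `true_active`, `true_radial`, `true_status` and `match_dist_px`;
#'   unmatched alleles are dropped.
#' @export
match_alleles_to_truth <- function(alleles, truth_alleles, pixel_size,
                                   tol_px = 3) {
  if (!nrow(alleles)) {
    alleles$true_nucleus <- integer(0); alleles$true_allele <- integer(0)
    alleles$true_active <- logical(0); alleles$true_radial <- numeric(0)
    alleles$true_status <- character(0)
    alleles$match_dist_px <- numeric(0)
    return(alleles)
  }
  truth_alleles$.status <- truth_status(truth_alleles)
  out <- list()
  key_a <- interaction(alleles$well, alleles$field, drop = TRUE)
  for (k in levels(key_a)) {
    a <- alleles[key_a == k, , drop = FALSE]
    t <- truth_alleles[interaction(truth_alleles$well, truth_alleles$field,
                                   drop = TRUE) == k, , drop = FALSE]
    if (!nrow(t)) next
    m <- match_spots(a$x_um / pixel_size, a$y_um / pixel_size,
                     t$x_px, t$y_px, tol_px = tol_px)
    ok <- !is.na(m$match)
    if (!any(ok)) next
    a <- a[ok, , drop = FALSE]
    tm <- t[m$match[ok], , drop = FALSE]
    a$true_nucleus <- tm$nucleus
    a$true_allele <- tm$allele
    a$true_active <- tm$active
    a$true_radial <- tm$radial_true
    a$true_status <- tm$.status
    a$match_dist_px <- m$dist[ok]
    out[[length(out) + 1L]] <- a
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
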