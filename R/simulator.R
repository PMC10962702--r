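#' @title Synthetic plate simulator
#' @description Generates maximum-projection-like fields with known ground
#' truth: textured DAPI nuclei (disks or mild ellipses placed without
#' overlap), two DNA FISH spots per nucleus (the two alleles of a diploid
#' locus), and one RNA spot within a configurable radius of each active
#' allele. Activity is Bernoulli per allele. Spots are rendered as 2D
#' Gaussians on a constant background, followed by Poisson and Gaussian read
#' noise. The sequential mode emits two acquisitions whose RNA pass is
#' translated by a configurable stage shift and independently re-noised.
#' @name simulator
NULL

# Evaluate code with a local, restored RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults mirror the target acquisition: 0.108 um pixels, nuclei of 50-60
#' px radius (>= 10.8 um equivalent diameter, i.e. QC-passing), a 0.5 um
#' maximum RNA offset (safely below the 1 um activity radius), and an
#' allele-activity probability of 0.3.
#'
#' @param seed Master seed; per-field seeds are derived as
#'   `seed + 7919 * field_index` (7919 is just a fixed prime stride).
#' @param image_size Field size in pixels (square).
#' @param pixel_size Microns per pixel.
#' @param n_nuclei Nuclei per field.
#' @param nucleus_radius_range Min/max nucleus semi-axis in pixels.
#' @param nucleus_shape `"disk"` or `"ellipse"` (mild eccentricity 0.85-1).
#' @param p_active Per-allele probability of being transcriptionally active.
#' @param rna_offset_max_um Maximum DNA-RNA offset of an active allele
#'   (microns); must stay below 1 so truth-active alleles classify Active.
#' @param radial_model `"uniform_in_nucleus"`, or `list(type = "beta",
#'   alpha =, beta =)` for a Beta-distributed target radial position.
#' @param psf_sigma Gaussian spot sigma in pixels.
#' @param spot_amplitude,background_level,noise_sigma Intensity model.
#' @param dapi_level,dapi_texture_amp,dapi_texture_sigma DAPI rendering: the
#'   nucleus interior is `dapi_level` plus a smooth random field (so
#'   registration has structure to lock onto).
#' @param poisson_noise Apply Poisson noise before Gaussian read noise.
#' @param sequential_shift Integer `(dx, dy)` translation injected into the
#'   RNA acquisition of sequential fields.
#' @param max_dna_radial Maximum normalized radial position at which a DNA
#'   allele is placed (default 0.92): gene loci sit interior to the DAPI
#'   mask, so the allele and an RNA signal within `rna_offset_max_um` of it
#'   remain inside the segmented nucleus.
#' @param min_spot_separation_um Minimum distance between the two DNA spots
#'   of a nucleus when `enforce_separation` is TRUE; never below
#'   `4 * psf_sigma` pixels. Keeps the homologous alleles far enough apart
#'   that an RNA signal is unambiguous.
#' @param enforce_separation Guarantee the DNA-DNA separation above.
#' @param stray_spot_rate Poisson rate of extra (false) spots per nucleus
#'   and channel, for negative-path testing (default 0).
#' @param n_fields,n_wells Plate extent.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              image_size = 512L,
                              pixel_size = 0.108,
                              n_nuclei = 6L,
                              nucleus_radius_range = c(50, 60),
                              nucleus_shape = c("ellipse", "disk"),
                              p_active = 0.3,
                              rna_offset_max_um = 0.5,
                              radial_model = "uniform_in_nucleus",
                              psf_sigma = 2,
                              spot_amplitude = 600,
                              background_level = 100,
                              noise_sigma = 10,
                              dapi_level = 400,
                              dapi_texture_amp = 120,
                              dapi_texture_sigma = 12,
                              poisson_noise = TRUE,
                              sequential_shift = c(0L, 0L),
                              min_spot_separation_um = 2.5,
                              enforce_separation = TRUE,
                              max_dna_radial = 0.92,
                              stray_spot_rate = 0,
                              n_fields = 1L,
                              n_wells = 1L) {
  nucleus_shape <- match.arg(nucleus_shape)
  if (p_active < 0 || p_active > 1) stop("p_active must lie in [0, 1]")
  if (rna_offset_max_um >= 1.0)
    stop("rna_offset_max_um must be < 1 um so ground-truth active alleles are classifiable as Active")
  if (is.character(radial_model)) {
    if (!radial_model %in% "uniform_in_nucleus")
      stop("unknown radial_model")
  } else if (!is.list(radial_model) || !identical(radial_model$type, "beta") ||
             is.null(radial_model$alpha) || is.null(radial_model$beta)) {
    stop("radial_model must be 'uniform_in_nucleus' or list(type='beta', alpha=, beta=)")
  }
  structure(list(seed = as.integer(seed), image_size = as.integer(image_size),
                 pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = nucleus_radius_range,
                 nucleus_shape = nucleus_shape, p_active = p_active,
                 rna_offset_max_um = rna_offset_max_um,
                 radial_model = radial_model, psf_sigma = psf_sigma,
                 spot_amplitude = spot_amplitude,
                 background_level = background_level,
                 noise_sigma = noise_sigma, dapi_level = dapi_level,
                 dapi_texture_amp = dapi_texture_amp,
                 dapi_texture_sigma = dapi_texture_sigma,
                 poisson_noise = poisson_noise,
                 sequential_shift = as.integer(sequential_shift),
                 min_spot_separation_um = min_spot_separation_um,
                 enforce_separation = enforce_separation,
                 max_dna_radial = max_dna_radial,
                 stray_spot_rate = stray_spot_rate,
                 n_fields = as.integer(n_fields),
                 n_wells = as.integer(n_wells)),
            class = "simulation_config")
}

# --- geometry -------------------------------------------------------------

# Place n non-overlapping ellipses by dart throwing (each nucleus retried
# against the already placed ones); errors after 1000 total failures.
.place_nuclei <- function(config) {
  sz <- config$image_size
  rr <- config$nucleus_radius_range
  margin_border <- max(abs(config$sequential_shift)) + 6
  n <- config$n_nuclei
  a <- b <- theta <- cx <- cy <- numeric(n)
  fails <- 0L
  i <- 1L
  while (i <= n) {
    a[i] <- stats::runif(1, rr[1], rr[2])
    ecc <- if (config$nucleus_shape == "disk") 1 else stats::runif(1, 0.85, 1)
    b[i] <- a[i] * ecc
    theta[i] <- stats::runif(1, 0, pi)
    rmax_i <- max(a[i], b[i])
    lo <- rmax_i + margin_border; hi <- sz - rmax_i - margin_border
    if (hi <= lo)
      stop("nuclei cannot be placed: radius too large for image size; use fewer or smaller nuclei")
    cx[i] <- stats::runif(1, lo, hi)
    cy[i] <- stats::runif(1, lo, hi)
    clash <- FALSE
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      need <- pmax(a[prev], b[prev]) + rmax_i + 10
      clash <- any((cx[prev] - cx[i])^2 + (cy[prev] - cy[i])^2 < need^2)
    }
    if (clash) {
      fails <- fails + 1L
      if (fails >= 1000L)
        stop("nuclei could not be placed without overlap in 1000 attempts; use fewer or smaller nuclei")
    } else i <- i + 1L
  }
  data.frame(nucleus = seq_len(n), cx = cx, cy = cy, a = a, b = b,
             theta = theta)
}

# Rasterize nuclei into a label mask (1-based matrix coordinates).
.rasterize_nuclei <- function(nuc, sz, pixel_size) {
  lab <- matrix(0L, sz, sz)
  for (i in seq_len(nrow(nuc))) {
    rmax <- ceiling(max(nuc$a[i], nuc$b[i])) + 1L
    rows <- max(1L, floor(nuc$cy[i] - rmax)):min(sz, ceiling(nuc$cy[i] + rmax))
    cols <- max(1L, floor(nuc$cx[i] - rmax)):min(sz, ceiling(nuc$cx[i] + rmax))
    dy <- outer(rows - 1 - nuc$cy[i], rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - 1 - nuc$cx[i])
    u <- (dx * cos(nuc$theta[i]) + dy * sin(nuc$theta[i])) / nuc$a[i]
    v <- (-dx * sin(nuc$theta[i]) + dy * cos(nuc$theta[i])) / nuc$b[i]
    inside <- u^2 + v^2 <= 1
    sub <- lab[rows, cols]
    sub[inside] <- nuc$nucleus[i]
    lab[rows, cols] <- sub
  }
  label_mask(lab, pixel_size)
}

#' Place a spot at a target normalized radial position
#'
#' Samples uniformly among the nucleus pixels whose normalized radial value
#' is within `tol` of the target (the admissible ring).
#'
#' @param mask A `label_mask`.
#' @param label Nucleus label.
#' @param target_radial Target radial value in [0, 1].
#' @param tol Ring half-width (default 0.05).
#' @param rmap Optional precomputed `radial_map` for the mask.
#' @return Integer vector `c(x, y)` (0-based pixel).
#' @export
place_spot_at_radius <- function(mask, label, target_radial, tol = 0.05,
                                 rmap = NULL) {
  if (target_radial < 0 || target_radial > 1)
    stop("target_radial must lie in [0, 1]")
  if (is.null(rmap)) rmap <- radial_map(mask)
  inlab <- mask$labels == label & !is.na(rmap$values)
  # the extremes are exact: the deepest pixel(s) for 0, the rim for 1
  hit <- if (target_radial <= 0) {
    inlab & rmap$values == min(rmap$values[inlab])
  } else if (target_radial >= 1) {
    inlab & rmap$values == max(rmap$values[inlab])
  } else {
    inlab & abs(rmap$values - target_radial) <= tol
  }
  sel <- which(hit, arr.ind = TRUE)
  if (!nrow(sel))
    stop(sprintf("no pixel of nucleus %d within %.3g of radial %.3g (nucleus too small?)",
                 label, tol, target_radial))
  i <- sel[sample.int(nrow(sel), 1L), ]
  c(x = unname(i[2]) - 1L, y = unname(i[1]) - 1L)
}

# Sample one allele position according to the configured radial model.
# Placement is capped at max_dna_radial so the allele (and an RNA signal
# within rna_offset_max_um of it) stays interior to the DAPI mask.
# `px` is the nucleus pixel table cbind(r, c), `rv` its radial values.
.sample_allele_pos <- function(config, px, rv) {
  cap <- config$max_dna_radial
  if (identical(config$radial_model, "uniform_in_nucleus")) {
    cand <- which(rv <= cap)
  } else {
    target <- min(stats::rbeta(1, config$radial_model$alpha,
                               config$radial_model$beta), cap)
    cand <- which(abs(rv - target) <= 0.05)
    if (!length(cand)) cand <- which(rv <= cap)
  }
  i <- px[cand[sample.int(length(cand), 1L)], ]
  c(x = unname(i[2]) - 1L, y = unname(i[1]) - 1L)
}

# --- rendering ------------------------------------------------------------

# Smooth random field: iid normal values on a coarse grid with the given
# spacing, bilinearly interpolated to sz x sz and scaled to amplitude `amp`.
.smooth_field <- function(sz, spacing, amp) {
  ng <- ceiling(sz / spacing) + 2L
  g <- matrix(stats::rnorm(ng * ng), ng, ng)
  pos <- (seq_len(sz) - 1) / spacing + 1
  i0 <- pmin(floor(pos), ng - 1L); fr <- pos - i0
  # interpolate rows then columns
  rows <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1L, , drop = FALSE] * fr
  out <- rows[, i0, drop = FALSE] * matrix(1 - fr, sz, sz, byrow = TRUE) +
    rows[, i0 + 1L, drop = FALSE] * matrix(fr, sz, sz, byrow = TRUE)
  out / stats::sd(out) * amp
}

.render_spots <- function(sz, xs, ys, amplitude, sigma) {
  img <- matrix(0, sz, sz)
  if (!length(xs)) return(img)
  rad <- ceiling(4 * sigma)
  for (i in seq_along(xs)) {
    rows <- max(1L, floor(ys[i] + 1 - rad)):min(sz, ceiling(ys[i] + 1 + rad))
    cols <- max(1L, floor(xs[i] + 1 - rad)):min(sz, ceiling(xs[i] + 1 + rad))
    dy2 <- (rows - 1 - ys[i])^2
    dx2 <- (cols - 1 - xs[i])^2
    img[rows, cols] <- img[rows, cols] +
      amplitude * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  }
  img
}

# Shot noise then Gaussian read noise. At the photon counts simulated here
# (background >= ~100) the Poisson component is indistinguishable from its
# Gaussian limit N(lambda, lambda), so both noises collapse into one draw;
# exact Poisson sampling is kept for low-count scenes.
.add_noise <- function(clean, config) {
  v <- as.vector(clean)
  if (config$poisson_noise) {
    lam <- pmax(v, 0)
    if (min(lam) >= 30) {
      v <- v + stats::rnorm(length(v), 0,
                            sqrt(lam + config$noise_sigma^2))
    } else {
      v <- stats::rpois(length(v), lam) +
        stats::rnorm(length(v), 0, config$noise_sigma)
    }
  } else {
    v <- v + stats::rnorm(length(v), 0, config$noise_sigma)
  }
  matrix(pmin(pmax(round(v), 0), 65535), nrow(clean), ncol(clean))
}

# --- field simulation -----------------------------------------------------

#' Simulate one field
#'
#' @param config A [simulation_config()].
#' @param field_seed Seed for this field (derive from the master seed for
#'   plates; any integer works).
#' @param well,field Identifiers stamped on outputs.
#' @param mode `"simultaneous"` (one acquisition) or `"sequential"` (two
#'   acquisitions sharing the DAPI scene, with the RNA pass translated by
#'   `config$sequential_shift` and independently re-noised).
#' @return List with `acquisitions` (list of `acquisition` objects),
#'   `truth` (list: `alleles` and `nuclei` data frames, plus the injected
#'   `shift`), and `mask` (the ground-truth `label_mask`).
#' @export
simulate_field <- function(config, field_seed = config$seed, well = "A01",
                           field = 1L,
                           mode = c("simultaneous", "sequential")) {
  stopifnot(inherits(config, "simulation_config"))
  mode <- match.arg(mode)
  .with_seed(field_seed, {
    sz <- config$image_size
    ps <- config$pixel_size
    nuc <- .place_nuclei(config)
    mask <- .rasterize_nuclei(nuc, sz, ps)
    rmap <- radial_map(mask)

    min_sep_px <- if (config$enforce_separation)
      max(config$min_spot_separation_um / ps, 4 * config$psf_sigma) else 0
    rmax_px <- config$rna_offset_max_um / ps

    pixl <- .label_pixels(mask$labels)
    n_nuc <- nrow(nuc); n_all <- 2L * n_nuc
    al_x <- al_y <- numeric(n_all)
    al_act <- logical(n_all)
    rna_xy <- matrix(NA_real_, n_all, 2)
    for (i in seq_len(n_nuc)) {
      lbl <- nuc$nucleus[i]
      px <- pixl[[as.character(lbl)]]
      rv <- rmap$values[px]
      p1 <- .sample_allele_pos(config, px, rv)
      for (try in seq_len(500L)) {
        p2 <- .sample_allele_pos(config, px, rv)
        if (sqrt(sum((p1 - p2)^2)) >= min_sep_px) break
        if (try == 500L)
          stop("could not separate the two alleles; nucleus too small for min_spot_separation_um")
      }
      act <- stats::runif(2) < config$p_active
      xy <- rbind(p1, p2)
      for (a in 1:2) {
        if (!act[a]) next
        pos <- xy[a, ]
        k <- 2L * (i - 1L) + a
        for (try in seq_len(200L)) {
          r <- rmax_px * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
          cand <- pos + c(r * cos(th), r * sin(th))
          ix <- round(cand) + 1L
          if (all(ix >= 1L) && all(ix <= sz) &&
              mask$labels[ix[2], ix[1]] == lbl) { rna_xy[k, ] <- cand; break }
          if (try == 200L) rna_xy[k, ] <- pos  # zero offset always valid
        }
      }
      sl <- 2L * (i - 1L) + (1:2)
      al_x[sl] <- xy[, 1]; al_y[sl] <- xy[, 2]; al_act[sl] <- act
    }
    alleles <- data.frame(
      well = well, field = as.integer(field),
      nucleus = rep(nuc$nucleus, each = 2L), allele = rep(1:2, n_nuc),
      x_px = al_x, y_px = al_y, x_um = al_x * ps, y_um = al_y * ps,
      radial_true = rmap$values[cbind(round(al_y) + 1L, round(al_x) + 1L)],
      active = al_act, rna_x_px = rna_xy[, 1], rna_y_px = rna_xy[, 2])

    # stray (false-positive) spots for negative-path testing
    stray <- list(DNA = NULL, RNA = NULL)
    if (config$stray_spot_rate > 0) {
      for (ch in c("DNA", "RNA")) {
        pts <- list()
        for (i in seq_len(nrow(nuc))) {
          k <- stats::rpois(1, config$stray_spot_rate)
          if (k > 0) for (j in seq_len(k)) {
            sel <- pixl[[as.character(nuc$nucleus[i])]]
            p <- sel[sample.int(nrow(sel), 1L), ]
            pts[[length(pts) + 1L]] <- c(p[2] - 1L, p[1] - 1L)
          }
        }
        if (length(pts)) stray[[ch]] <- do.call(rbind, pts)
      }
    }

    # clean scenes; chromatin-like texture: coarse Gaussian grid at spacing
    # dapi_texture_sigma, bilinearly upsampled (correlation length ~ spacing)
    texture <- .smooth_field(sz, config$dapi_texture_sigma,
                             config$dapi_texture_amp)
    # floor at half the nuclear level: chromatin texture modulates but never
    # extinguishes the DAPI signal, keeping nuclei segmentable by Otsu
    inside <- mask$labels > 0L
    dapi_clean <- config$background_level +
      inside * pmax(config$dapi_level + texture, 0.5 * config$dapi_level)
    scol <- function(m, j) if (is.null(m)) numeric(0) else m[, j]
    dna_x <- c(alleles$x_px, scol(stray$DNA, 1))
    dna_y <- c(alleles$y_px, scol(stray$DNA, 2))
    dna_clean <- config$background_level +
      .render_spots(sz, dna_x, dna_y, config$spot_amplitude, config$psf_sigma)
    act_sel <- alleles$active
    rna_x <- c(alleles$rna_x_px[act_sel], scol(stray$RNA, 1))
    rna_y <- c(alleles$rna_y_px[act_sel], scol(stray$RNA, 2))
    rna_clean <- config$background_level +
      .render_spots(sz, rna_x, rna_y, config$spot_amplitude, config$psf_sigma)

    shift <- config$sequential_shift
    if (mode == "simultaneous") {
      acqs <- list(acquisition(list(dapi = .add_noise(dapi_clean, config),
                                    dna = .add_noise(dna_clean, config),
                                    rna = .add_noise(rna_clean, config)),
                               pixel_size = ps, well = well, field = field,
                               tag = "single"))
      shift <- c(0L, 0L)
    } else {
      v <- translation_vector(shift[1], shift[2])
      acqs <- list(
        acquisition(list(dapi = .add_noise(dapi_clean, config),
                         dna = .add_noise(dna_clean, config)),
                    pixel_size = ps, well = well, field = field,
                    tag = "dna_pass"),
        acquisition(list(dapi = .add_noise(apply_translation(dapi_clean, v),
                                           config),
                         rna = .add_noise(apply_translation(rna_clean, v),
                                          config)),
                    pixel_size = ps, well = well, field = field,
                    tag = "rna_pass"))
    }
    alleles$shift_dx <- shift[1]; alleles$shift_dy <- shift[2]
    nuc$well <- well; nuc$field <- as.integer(field)
    list(acquisitions = acqs,
         truth = list(alleles = alleles, nuclei = nuc,
                      shift = shift),
         mask = mask)
  })
}

#' Simulate a plate and write it to disk
#'
#' One directory per well containing per-field channel TIFFs named
#' `<well>_f<field>_<channel>_<tag>.tif`, ground-truth CSVs in the same
#' per-well layout as pipeline outputs, and the configuration serialized as
#' YAML for provenance.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the plate `layout` data frame and the
#'   combined ground-truth `alleles` data frame.
#' @export
simulate_plate <- function(config, out_dir,
                           mode = c("simultaneous", "sequential"),
                           overwrite = FALSE) {
  mode <- match.arg(mode)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop(sprintf("output directory %s is not empty (use overwrite = TRUE)",
                 out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], length.out = config$n_wells),
                   (seq_len(config$n_wells) - 1L) %/% 8L + 1L)
  rows <- list(); truths <- list()
  fid <- 0L
  for (wi in seq_len(config$n_wells)) {
    wdir <- file.path(out_dir, wells[wi])
    dir.create(wdir, showWarnings = FALSE)
    wtruth <- list()
    for (fi in seq_len(config$n_fields)) {
      fid <- fid + 1L
      fseed <- config$seed + 7919L * fid
      sim <- simulate_field(config, field_seed = fseed, well = wells[wi],
                            field = fi, mode = mode)
      for (acq in sim$acquisitions) {
        for (ch in names(acq$channels)) {
          fn <- sprintf("%s_f%02d_%s_%s.tif", wells[wi], fi, ch, acq$tag)
          write_gray_tiff(acq$channels[[ch]], file.path(wdir, fn))
          rows[[length(rows) + 1L]] <- data.frame(
            well = wells[wi], field = fi, channel = ch, tag = acq$tag,
            path = file.path(wdir, fn))
        }
      }
      wtruth[[fi]] <- sim$truth$alleles
    }
    wtruth <- do.call(rbind, wtruth)
    utils::write.csv(wtruth,
                     file.path(wdir, sprintf("%s_ground_truth_alleles.csv",
                                             wells[wi])),
                     row.names = FALSE)
    truths[[wi]] <- wtruth
  }
  cfg <- unclass(config)
  cfg$mode <- mode
  yaml::write_yaml(cfg, file.path(out_dir, "simulation_config.yaml"))
  invisible(list(layout = do.call(rbind, rows),
                 alleles = do.call(rbind, truths)))
}
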