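# Shared fixtures and independent oracles, all built in code at test time.

# Rasterized disk label mask (pixel centers within R of the center).
mk_disk_mask <- function(R, pad = 6, pixel_size = 0.108, label = 1L) {
  n <- 2L * (R + pad) + 1L
  c0 <- R + pad + 1L
  xx <- matrix(rep(seq_len(n), each = n), n)
  yy <- matrix(rep(seq_len(n), n), n)
  m <- ((xx - c0)^2 + (yy - c0)^2 <= R^2) * label
  label_mask(m, pixel_size)
}

mk_square_mask <- function(s, pad = 6, pixel_size = 0.108) {
  n <- s + 2L * pad
  m <- matrix(0L, n, n)
  m[(pad + 1L):(pad + s), (pad + 1L):(pad + s)] <- 1L
  label_mask(m, pixel_size)
}

# Literal direct-sum cross-correlation: double loop over displacements,
# overlap sum per displacement. Oracle for the FFT implementation.
xcorr_direct <- function(A, B, m) {
  h <- nrow(A); w <- ncol(A)
  out <- matrix(0, 2 * m + 1, 2 * m + 1)
  for (dy in -m:m) for (dx in -m:m) {
    ys <- max(1, 1 - dy):min(h, h - dy)
    xs <- max(1, 1 - dx):min(w, w - dx)
    out[dy + m + 1, dx + m + 1] <- sum(A[ys, xs] * B[ys + dy, xs + dx])
  }
  out
}

# Brute-force Euclidean distance to the nearest background pixel.
dt_brute <- function(lab, label) {
  fg <- which(lab == label, arr.ind = TRUE)
  bg <- which(lab != label, arr.ind = TRUE)
  # image border also counts as background: add a virtual ring
  h <- nrow(lab); w <- ncol(lab)
  ring <- rbind(cbind(0, 0:(w + 1)), cbind(h + 1, 0:(w + 1)),
                cbind(1:h, 0), cbind(1:h, w + 1))
  bg <- rbind(bg, ring)
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Exhaustive two-sample KS permutation oracle over all C(n1+n2, n1) label
# assignments of the pooled sample (distinct values assumed). Returns the
# observed integer D numerator and the exact p-value.
ks_perm_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  z <- c(x, y)
  stopifnot(!anyDuplicated(z))
  ord_is_x <- rank(z)[seq_len(n1)]          # sorted positions of x
  U <- matrix(0, N, N); U[upper.tri(U, diag = TRUE)] <- 1
  combs <- utils::combn(N, n1)
  Z <- matrix(0, ncol(combs), N)
  Z[cbind(rep(seq_len(ncol(combs)), each = n1), as.vector(combs))] <- 1
  cs <- Z %*% U                              # cumulative x-count at each rank
  j <- matrix(seq_len(N), ncol(combs), N, byrow = TRUE)
  dn <- abs(cs * n2 - (j - cs) * n1)
  dmax <- do.call(pmax, as.data.frame(dn))
  obs_cs <- cumsum(seq_len(N) %in% ord_is_x)
  obs <- max(abs(obs_cs * n2 - (seq_len(N) - obs_cs) * n1))
  list(dnum = obs, p = mean(dmax >= obs))
}

# Small simulated field at the default acquisition scale.
sim_small <- function(seed, ..., mode = "simultaneous") {
  cfg <- simulation_config(seed = seed, ...)
  simulate_field(cfg, field_seed = seed, mode = mode)
}
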