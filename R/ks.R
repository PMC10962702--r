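#' @title Two-sample Kolmogorov-Smirnov test
#' @description Radial-position distributions of allele groups are compared
#' with the two-sided two-sample KS statistic
#' `D = sup |ECDF_x - ECDF_y|`. For small samples without ties the p-value
#' is exact, obtained by counting monotone lattice paths that stay strictly
#' inside the band `|i/n1 - j/n2| < D` (the classical distribution-free
#' permutation result, evaluated in integer arithmetic); otherwise the
#' asymptotic Kolmogorov distribution is used at the effective sample size
#' `n1 * n2 / (n1 + n2)`.
#' @name ks
NULL

# Integer numerator of D: max over pooled order of |i*n2 - j*n1|,
# evaluated at tie-group boundaries so ties are handled correctly.
.ks_dnum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  grp <- c(rep(1L, n1), rep(2L, n2))
  ord <- order(z)
  z <- z[ord]; grp <- grp[ord]
  i <- cumsum(grp == 1L); j <- cumsum(grp == 2L)
  at_end <- c(z[-1] != z[-length(z)], TRUE)  # evaluate after each tie group
  max(abs(i[at_end] * n2 - j[at_end] * n1))
}

# Exact P(D >= Dnum/(m*n)) by path counting: number of monotone lattice
# paths (0,0) -> (m,n) that ever reach |i*n - j*m| >= Dnum, over choose(m+n,m).
# Inner recurrence v[j] = v[j-1] + u[j] inside allowed states is a segmented
# cumulative sum, vectorized over j.
.ks_exact_p <- function(dnum, m, n) {
  if (dnum <= 0L) return(1)
  j <- 0:n
  u <- numeric(n + 1L)
  allowed0 <- abs(-j * m) < dnum
  u[1] <- 1
  if (n >= 1L) for (jj in seq_len(n)) u[jj + 1L] <-
      if (allowed0[jj + 1L]) u[jj] else 0
  for (i in seq_len(m)) {
    allowed <- abs(i * n - j * m) < dnum
    cu <- cumsum(u)
    blocked_at <- ifelse(allowed, 0L, seq_len(n + 1L))
    last_blocked <- cummax(blocked_at)
    base <- c(0, cu)[last_blocked + 1L]
    u <- ifelse(allowed, cu - base, 0)
  }
  p <- 1 - u[n + 1L] / choose(m + n, m)
  min(max(p, 0), 1)
}

# Asymptotic two-sided Kolmogorov tail Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2).
.ks_asym_p <- function(d, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(ne) * d
  if (lambda < 1e-3) return(1)
  k <- 1:100
  terms <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  min(max(sum(terms), 0), 1)
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' @param x,y Numeric samples, each with at least one observation.
#' @param exact_max Use the exact path-counting p-value when
#'   `length(x) * length(y) <= exact_max` and the pooled sample has no ties
#'   (default 100); the asymptotic approximation is used otherwise.
#' @return An object of class `ks_result`: list with `statistic` (D),
#'   `p_value`, `n1`, `n2` and `method` (`"exact"` or `"asymptotic"`).
#' @export
ks_two_sample <- function(x, y, exact_max = 100) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite")
  n1 <- length(x); n2 <- length(y)
  dnum <- .ks_dnum(x, y)
  d <- dnum / (n1 * n2)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 * n2 <= exact_max) {
    p <- .ks_exact_p(dnum, n1, n2)
    method <- "exact"
  } else {
    p <- .ks_asym_p(d, n1, n2)
    method <- "asymptotic"
  }
  structure(list(statistic = d, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test (%s): D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}
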