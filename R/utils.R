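# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Minimum-jerk smoothstep
#'
#' The quintic 6t^5 - 15t^4 + 10t^3 used for all scripted joint-angle and
#' load-transfer profiles: zero velocity and acceleration at both ends.
#' @param tau numeric in [0, 1]; values outside are clamped.
#' @return numeric of the same length in [0, 1].
#' @keywords internal
mjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 + tau * (-15 + 6 * tau))
}

# Piecewise minimum-jerk interpolation through (knot_t, knot_v). Constant
# before the first and after the last knot.
mjerk_profile <- function(t, knot_t, knot_v) {
  stopifnot(length(knot_t) == length(knot_v), !is.unsorted(knot_t))
  i <- findInterval(t, knot_t)
  v <- numeric(length(t))
  v[i == 0] <- knot_v[1]
  n <- length(knot_t)
  v[i >= n] <- knot_v[n]
  inside <- i >= 1 & i < n
  ii <- i[inside]
  tau <- (t[inside] - knot_t[ii]) / (knot_t[ii + 1] - knot_t[ii])
  v[inside] <- knot_v[ii] + (knot_v[ii + 1] - knot_v[ii]) * mjerk(tau)
  v
}

# 31-bit avalanche mix (murmur-style finalizer adapted to 31 bits). All
# arithmetic stays exact in doubles; the multiply is split into 16-bit
# halves so no intermediate exceeds 2^53.
.sg_mix31 <- function(h) {
  M <- 2147483648
  mul <- function(a, b) {
    a_hi <- a %/% 65536
    a_lo <- a %% 65536
    (((a_hi * b) %% 32768) * 65536 + a_lo * b) %% M
  }
  xshift <- function(h, s) {
    bitwXor(as.integer(h %% M), as.integer((h %/% 2^s) %% M))
  }
  h <- h %% M
  h <- mul(xshift(h, 16), 2654435761)
  h <- mul(xshift(h, 13), 2246822519)
  abs(xshift(h, 16))
}

# Deterministic seed splitting: one master seed, hierarchically combined with
# small integer labels through an avalanche mix, so that stream k of
# participant p is independent of how many other participants exist and
# nearby master seeds or labels yield decorrelated streams.
sub_seed <- function(seed, ...) {
  h <- .sg_mix31(as.numeric(seed))
  for (k in c(...)) {
    h <- .sg_mix31(h + (as.numeric(k) + 1) * 2654435761)
  }
  as.integer(h %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_sub_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gamma draws moment-matched to a target mean and sd; degenerate sd -> constant.
rgamma_ms <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Gamma quantile for a moment-matched mean/sd (copula marginals).
qgamma_ms <- function(p, mean, sd) {
  if (mean <= 0) return(rep(0, length(p)))
  if (sd <= 0) return(rep(mean, length(p)))
  shape <- (mean / sd)^2
  stats::qgamma(p, shape = shape, rate = shape / mean)
}

# One correlated pair of gamma draws (Gaussian copula, correlation rho) with
# exact moment-matched marginals. Dwell time and fixation count on an AOI
# are tightly coupled (dwell = count x mean fixation duration, and the
# latter varies far less than either), so the default correlation is high;
# the copula keeps that dependence without touching the marginal mean/sd.
rgamma_pair <- function(mean1, sd1, mean2, sd2, rho = 0.95) {
  z1 <- stats::rnorm(1)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
  c(qgamma_ms(stats::pnorm(z1), mean1, sd1),
    qgamma_ms(stats::pnorm(z2), mean2, sd2))
}

abort_if <- function(cond, msg, class = "standgaze_error") {
  if (cond) rlang::abort(msg, class = class)
  invisible(NULL)
}

# 3-vector cross product.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

normalize_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}
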