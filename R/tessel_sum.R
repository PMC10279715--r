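# Bessel-form path-length densities for sums of alternating exponential chords.
#
# All closed forms are assembled in log space and evaluated through the even
# entire function h_nu(t) = I_nu(t) / t^nu, which is well-defined for every
# sign of the rate contrast mu = r_b - r_a (t = s * mu / 2) and has the
# finite limit 2^(-nu) / Gamma(nu + 1) as t -> 0, so the equal-rate (gamma)
# degeneracy needs no special-casing.

# Exponentially scaled modified Bessel I_nu(x) * exp(-x). base::besselI
# underflows to 0 for x beyond ~1e5, so for larger arguments the exact
# finite Hankel sum for half-integer orders is used (all orders arising
# from the alternating-chord densities are half-integers, and for x > 1e4
# with moderate nu the alternating sum is strictly decreasing, so there is
# no cancellation).
ive <- function(nu, x) {
  if (all(x <= 1e4) || abs(nu %% 1) != 0.5) {
    return(besselI(x, nu, expon.scaled = TRUE))
  }
  out <- numeric(length(x))
  lo <- x <= 1e4
  if (any(lo)) out[lo] <- besselI(x[lo], nu, expon.scaled = TRUE)
  xb <- x[!lo]
  m <- as.integer(round(nu - 0.5))
  if (m < 0L) {                       # nu = -1/2: scaled cosh form
    out[!lo] <- (1 + exp(-2 * xb)) / sqrt(2 * pi * xb)
    return(out)
  }
  s_alt <- rep(1, length(xb))
  s_pos <- rep(1, length(xb))
  ck <- rep(1, length(xb))
  if (m >= 1L) {
    for (k in 0:(m - 1L)) {
      ck <- ck * ((m - k) * (m + k + 1)) / (2 * (k + 1)) / xb
      s_alt <- s_alt + (-1)^(k + 1) * ck
      s_pos <- s_pos + ck
    }
  }
  out[!lo] <- (s_alt + (-1)^(m + 1) * exp(-2 * xb) * s_pos) / sqrt(2 * pi * xb)
  out
}

# log(I_nu(t) / t^nu); even in t. Power series for |t| <= 30 (all terms
# positive, no cancellation, accumulated relative to the leading term so the
# result never under- or overflows), exponentially scaled Bessel with
# log-space exponent recombination beyond.
log_bessel_ratio <- function(nu, t) {
  t <- abs(t)
  out <- numeric(length(t))
  small <- t <= 30
  if (any(small)) {
    ts <- t[small]
    S <- rep(1, length(ts))
    ck <- rep(1, length(ts))
    for (k in 0:400) {
      ck <- ck * (ts^2 / 4) / ((k + 1) * (k + nu + 1))
      S <- S + ck
      if (all(ck < 1e-17 * S)) break
    }
    out[small] <- -nu * log(2) - lgamma(nu + 1) + log(S)
  }
  if (any(!small)) {
    tb <- t[!small]
    out[!small] <- log(ive(nu, tb)) + tb - nu * log(tb)
  }
  out
}

# log( h_nu1(t) + t * h_{nu1+1}(t) ) for signed t -- the odd-N bracket
# mu^(-nu1) * [I_nu1 + I_{nu1+1}] rewritten in the ratio form. For large |t|
# with t < 0 the two Bessel terms nearly cancel; the difference is taken on
# the exponentially scaled values, which keeps the relative error at
# ~ eps * |t| / nu.
log_bessel_pair <- function(nu1, t) {
  out <- numeric(length(t))
  at <- abs(t)
  big <- at > 30
  if (any(!big)) {
    ts <- t[!big]
    lh1 <- log_bessel_ratio(nu1, ts)
    lh2 <- log_bessel_ratio(nu1 + 1, ts)
    out[!big] <- lh1 + log1p(ts * exp(lh2 - lh1))
  }
  if (any(big)) {
    tb <- t[big]
    atb <- at[big]
    i1 <- ive(nu1, atb)
    i2 <- ive(nu1 + 1, atb)
    out[big] <- atb - nu1 * log(atb) + log(ifelse(tb > 0, i1 + i2, i1 - i2))
  }
  out
}

#' Density of the first stopping point inside a random tessel
#'
#' A photon starting at a tessel boundary stops inside that tessel (without
#' crossing it) at a distance distributed as an exponential with the
#' composite rate `mu_t + sigma`. The same function is both the stop density
#' and the single-tessel path density.
#'
#' @param s Path length (mm, >= 0). Vectorised.
#' @param mu_t Extinction coefficient (1/mm).
#' @param sigma Inverse mean chord (1/mm). `mu_t + sigma` must be > 0.
#' @return Probability density values.
#' @examples
#' pdf_first_tessel_stop(0, mu_t = 1, sigma = 2)  # composite rate 3
#' @export
pdf_first_tessel_stop <- function(s, mu_t, sigma) {
  check_nonneg(s, "s")
  if (!is.numeric(mu_t) || !is.numeric(sigma) || mu_t < 0 || sigma < 0 ||
      mu_t + sigma <= 0) {
    stop("`mu_t` and `sigma` must be >= 0 with a strictly positive sum", call. = FALSE)
  }
  r <- mu_t + sigma
  r * exp(-r * s)
}

#' Path density across N tessels of the same material
#'
#' Sum of `N` independent exponential chords with common composite rate
#' `mu_t + sigma`: the gamma density with shape `N` and that rate.
#'
#' @inheritParams pdf_first_tessel_stop
#' @param N Number of tessels (integer >= 1).
#' @return Probability density values.
#' @examples
#' pdf_sum_same_material(1, mu_t = 1, sigma = 1, N = 3)
#' @export
pdf_sum_same_material <- function(s, mu_t, sigma, N) {
  check_nonneg(s, "s")
  if (length(N) != 1L || N < 1 || N != round(N)) {
    stop("`N` must be a single integer >= 1", call. = FALSE)
  }
  r <- mu_t + sigma
  if (r <= 0) stop("`mu_t + sigma` must be strictly positive", call. = FALSE)
  stats::dgamma(s, shape = N, rate = r)
}

#' Path density across N alternating tessels
#'
#' Density of the total length of `N` consecutive tessel chords with
#' alternating materials (the first of type `start`): the two-rate
#' hypoexponential law in its modified-Bessel closed form. The evaluation is
#' overflow-free for `s * max(r_a, r_b)` well beyond 700, valid for every
#' sign of the rate contrast `mu`, and reduces exactly to the gamma law when
#' the two composite rates coincide.
#'
#' @param s Path length (mm, >= 0). Vectorised.
#' @param params A [mixture_params()] object.
#' @param N Number of tessels (integer >= 1).
#' @param start Material of the first tessel, `"a"` (default) or `"b"`.
#' @return Probability density values; integrates to 1 for every `N >= 1`.
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' pdf_tessel_sum(c(0.5, 1, 2), mp, N = 3)
#' @export
pdf_tessel_sum <- function(s, params, N, start = c("a", "b")) {
  stopifnot(inherits(params, "mixture_params"))
  check_nonneg(s, "s")
  if (length(N) != 1L || N < 1 || N != round(N)) {
    stop("`N` must be a single integer >= 1", call. = FALSE)
  }
  p <- params_for_start(params, start)
  ra <- p$r_a
  rb <- p$r_b
  # The single-tessel case carries no dependence on the second material.
  if (N == 1) return(ra * exp(-ra * s))

  m <- (ra + rb) / 2
  mu <- p$mu
  t <- s * mu / 2
  out <- numeric(length(s))
  pos <- s > 0
  sp <- s[pos]
  tp <- t[pos]
  if (N %% 2 == 0) {
    nu <- (N - 1) / 2
    lp <- 0.5 * log(pi) + (N / 2) * (log(ra) + log(rb)) - lgamma(N / 2) +
      nu * log(sp^2 / 2) + log_bessel_ratio(nu, tp) - m * sp
  } else {
    nu1 <- (N - 2) / 2
    lp <- 0.5 * log(pi) + ((N - 1) / 2) * log(rb) + ((N + 1) / 2) * log(ra) -
      log(2) - lgamma((N + 1) / 2) + (N / 2) * log(sp) + nu1 * log(sp / 2) +
      log_bessel_pair(nu1, tp) - m * sp
  }
  if (any(!is.finite(lp) & !(lp == -Inf))) {
    stop("non-finite intermediate in the Bessel-form density (N = ", N, ")",
         call. = FALSE)
  }
  out[pos] <- exp(lp)
  out  # density at s = 0 is 0 for N >= 2
}

#' Density of a step that jumps over N tessels
#'
#' A step that crosses exactly `N` whole tessels and then stops inside the
#' (N+1)-th has the same length law as the sum of `N + 1` alternating
#' chords, because the stop density inside a tessel coincides with the
#' single-chord path density.
#'
#' @inheritParams pdf_tessel_sum
#' @param N Number of tessels jumped over (integer >= 0).
#' @return Probability density values.
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' pdf_step_over_N(1, mp, N = 0)  # == pdf_first_tessel_stop(1, 1, 0.5)
#' @export
pdf_step_over_N <- function(s, params, N, start = c("a", "b")) {
  if (length(N) != 1L || N < 0 || N != round(N)) {
    stop("`N` must be a single integer >= 0", call. = FALSE)
  }
  pdf_tessel_sum(s, params, N + 1, start = start)
}
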