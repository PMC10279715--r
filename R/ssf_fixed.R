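# Fixed-start (equilibrium) step law: the survival function of the mixture
# single-step function divided by its mean, plus the cumulative functions of
# the alternating-tessel densities, with optional hypergeometric closed forms.

#' Evaluation policy for the cumulative tessel-sum functions
#'
#' @param use_closed_form_F Use the finite hypergeometric closed forms of
#'   the cumulative alternating-tessel function instead of quadrature.
#'   Every closed-form value is cross-checked against quadrature; a
#'   disagreement beyond 1e-6 raises a consistency error rather than being
#'   silently returned.
#' @param ctrl A [series_control()] object.
#' @return A `fixed_start_config` object.
#' @export
fixed_start_config <- function(use_closed_form_F = FALSE, ctrl = series_control()) {
  stopifnot(is.logical(use_closed_form_F), length(use_closed_form_F) == 1L,
            inherits(ctrl, "series_control"))
  structure(list(use_closed_form_F = use_closed_form_F, ctrl = ctrl),
            class = "fixed_start_config")
}

# Terminating Gauss hypergeometric 2F1(1, -m; c; z), m a non-negative
# integer: a finite sum, valid for any z (including |z| > 1).
hyp2f1_terminating <- function(b_neg, c, z) {
  m <- -b_neg
  if (m < 0 || m != round(m)) {
    stop("second parameter must be a non-positive integer", call. = FALSE)
  }
  S <- 1
  term <- 1
  if (m >= 1) {
    for (j in 1:m) {
      term <- term * (b_neg + j - 1) / (c + j - 1) * z
      S <- S + term
    }
  }
  S
}

# Binomial coefficient under the integer convention: zero for a negative
# lower index or for k > n (n, k integers here).
choose_int <- function(n, k) {
  if (k < 0 || k > n) 0 else choose(n, k)
}

# Closed-form cumulative of the alternating-tessel density, finite
# hypergeometric form. Terms whose binomial coefficient vanishes under the
# integer convention are dropped before their (then non-terminating)
# hypergeometric factor would be evaluated.
cumulative_F_closed <- function(s, p, N) {
  ra <- p$r_a
  rb <- p$r_b
  mu <- p$mu
  if (N == 1) return(1 - exp(-ra * s))
  if (mu == 0) return(stats::pgamma(s, shape = N, rate = ra))
  if (N %% 2 == 0) {
    t1 <- 0
    t2 <- 0
    sgn <- (-1)^((N + 2) / 2)
    for (k in 1:(N / 2)) {
      cb <- choose_int(N - k, N / 2 - k + 1)
      h1 <- if (cb == 0) 0 else hyp2f1_terminating(1 - N / 2, N / 2 - k + 2, ra / rb)
      h2 <- if (cb == 0) 0 else hyp2f1_terminating(1 - N / 2, N / 2 - k + 2, rb / ra)
      c1 <- -ra^(k - 1) + sgn * (-mu)^(k - N) * ra^(N / 2) * rb^((N - 2) / 2) * cb * h1
      c2 <- -rb^(k - 1) + sgn * mu^(k - N) * rb^(N / 2) * ra^((N - 2) / 2) * cb * h2
      t1 <- t1 + s^(k - 1) / gamma(k) * c1
      t2 <- t2 + s^(k - 1) / gamma(k) * c2
    }
    1 + exp(-ra * s) * t1 + exp(-rb * s) * t2
  } else {
    t1 <- 0
    t2 <- 0
    for (k in 0:((N - 1) / 2)) {
      b1 <- choose_int(N - 1 - k, (N - 1) / 2 - k)
      b2 <- choose_int(N - 1 - k, (N - 3) / 2 - k)
      # The companion terms with binomial lower index -k-1 vanish for all
      # k >= 0 and are dropped with their hypergeometric factors.
      c1 <- if (b1 == 0) 0 else {
        (-1)^((N + 1) / 2) * ra^((N - 1) / 2) * b1 *
          hyp2f1_terminating(k - (N - 1) / 2, (N + 1) / 2, rb / ra)
      }
      c2 <- if (b2 == 0) 0 else {
        (-1)^(k + (N - 1) / 2) * rb^((N - 3) / 2) * b2 *
          hyp2f1_terminating(k - (N - 3) / 2, (N + 3) / 2, ra / rb)
      }
      t1 <- t1 + s^k / gamma(k + 1) / (-mu)^(N - 1 - k) * c1
      t2 <- t2 + s^k / gamma(k + 1) / (-mu)^(N - 1 - k) * c2
    }
    1 + exp(-ra * s) * rb^((N - 1) / 2) * t1 + exp(-rb * s) * ra^((N + 1) / 2) * t2
  }
}

#' Cumulative alternating-tessel path function
#'
#' `F(s; N)`, the probability that the total length of `N` alternating
#' tessel chords (first of type `start`) is at most `s`. The canonical path
#' integrates [pdf_tessel_sum()] by adaptive quadrature; with
#' `cfg$use_closed_form_F` the finite hypergeometric closed form is
#' evaluated instead and validated against the quadrature value -- a
#' disagreement beyond 1e-6 signals a condition of class
#' `ssfmix_consistency_error`.
#'
#' @param s Path length (mm, >= 0). Vectorised.
#' @param params A [mixture_params()] object.
#' @param N Number of tessels (integer >= 1).
#' @param cfg A [fixed_start_config()].
#' @param start Material of the first tessel.
#' @return Probabilities in `[0, 1]`, non-decreasing in `s`.
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' cumulative_F(1, mp, N = 1)  # 1 - exp(-1.5)
#' @export
cumulative_F <- function(s, params, N, cfg = fixed_start_config(),
                         start = c("a", "b")) {
  stopifnot(inherits(params, "mixture_params"), inherits(cfg, "fixed_start_config"))
  check_nonneg(s, "s")
  if (length(N) != 1L || N < 1 || N != round(N)) {
    stop("`N` must be a single integer >= 1", call. = FALSE)
  }
  start <- match.arg(start)
  p <- params_for_start(params, start)
  quad <- function(x) {
    f <- function(u) pdf_tessel_sum(u, params, N, start = start)
    vapply(x, function(xi) {
      if (xi == 0) return(0)
      stats::integrate(f, 0, xi, rel.tol = cfg$ctrl$quad_rel_tol,
                       abs.tol = cfg$ctrl$quad_rel_tol)$value
    }, numeric(1))
  }
  if (!cfg$use_closed_form_F) {
    return(pmin(pmax(quad(s), 0), 1))
  }
  closed <- vapply(s, function(xi) cumulative_F_closed(xi, p, N), numeric(1))
  qv <- quad(s)
  if (any(abs(closed - qv) > 1e-6)) {
    cnd <- structure(
      class = c("ssfmix_consistency_error", "error", "condition"),
      list(message = sprintf(
        "closed-form cumulative disagrees with quadrature (max |diff| = %.3g, N = %d)",
        max(abs(closed - qv)), N), call = sys.call(-1)))
    stop(cnd)
  }
  pmin(pmax(closed, 0), 1)
}

#' Fixed-start single-step function
#'
#' Step-length density for photons launched from a fixed position (a source
#' or a boundary) rather than from an interaction point: the survival
#' function of the mixture single-step function divided by its mean. It is
#' always a proper density, non-increasing in `s`, with value
#' `1/mean_step_mix(params)` at the origin; for a homogeneous medium it
#' coincides with the step law itself.
#'
#' @inheritParams pdf_ssf_mix
#' @return Probability density values.
#' @examples
#' mp <- mixture_params(1, 1, 0.6, 0.6, P = 0.5)
#' pdf_ssf_fixed(0, mp)  # 1 / mean = mu_t
#' @export
pdf_ssf_fixed <- function(s, params, ctrl = series_control()) {
  stopifnot(inherits(params, "mixture_params"))
  check_nonneg(s, "s")
  m <- mean_step_mix(params)
  (1 - cdf_ssf_mix(s, params, ctrl)) / m
}
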