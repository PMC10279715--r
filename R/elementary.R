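#' Beer-Lambert free-path density in a homogeneous medium
#'
#' Density of the distance a photon travels before an interaction in a
#' homogeneous medium with extinction coefficient `mu_t`:
#' `mu_t * exp(-mu_t * s)`.
#'
#' @param s Path length (mm, >= 0). Vectorised.
#' @param mu_t Extinction coefficient (1/mm, > 0).
#' @return Probability density values, same length as `s`.
#' @examples
#' pdf_beer_lambert(0, mu_t = 2)   # density at the origin equals the rate
#' @export
pdf_beer_lambert <- function(s, mu_t) {
  check_nonneg(s, "s")
  check_pos_rate(mu_t, "mu_t")
  mu_t * exp(-mu_t * s)
}

#' Chord-length density of a tessel
#'
#' Along any straight photon direction, the length of one tessel of an
#' isotropic Poisson tessellation is exponential with rate `sigma`
#' (mean chord `1/sigma`).
#'
#' @param ell Chord length (mm, >= 0). Vectorised.
#' @param sigma Inverse mean chord (1/mm, > 0). A degenerate `sigma = 0`
#'   has no proper density and is rejected; zero-chord limits are handled
#'   analytically by the probability functions instead.
#' @return Probability density values.
#' @examples
#' pdf_tessel(0, sigma = 0.5)
#' @export
pdf_tessel <- function(ell, sigma) {
  check_nonneg(ell, "ell")
  check_pos_rate(sigma, "sigma")
  sigma * exp(-sigma * ell)
}

#' Probability that a free path exceeds a given length
#'
#' Survival function of the Beer-Lambert law: `exp(-mu_t * s)`.
#'
#' @inheritParams pdf_beer_lambert
#' @return Probabilities in `[0, 1]`, decreasing in `s` with value 1 at 0.
#' @examples
#' prob_step_exceeds(log(2), 1)  # 0.5
#' @export
prob_step_exceeds <- function(s, mu_t) {
  check_nonneg(s, "s")
  check_pos_rate(mu_t, "mu_t")
  exp(-mu_t * s)
}

#' Probability that a photon crosses one whole tessel
#'
#' Probability that a candidate free path (rate `mu_t`) is longer than an
#' exponential chord (rate `sigma`): `sigma / (sigma + mu_t)`. Degenerate
#' limits are exact: `mu_t = 0` gives 1 (no extinction, the photon always
#' crosses), `sigma = 0` gives 0 (tessels are infinitely long).
#'
#' @param mu_t Extinction coefficient (1/mm, >= 0).
#' @param sigma Inverse mean chord (1/mm, >= 0). `mu_t + sigma` must be > 0.
#' @return A probability in `[0, 1]`.
#' @examples
#' prob_jump_one(mu_t = 1, sigma = 1)  # 0.5
#' @export
prob_jump_one <- function(mu_t, sigma) {
  if (!is.numeric(mu_t) || !is.numeric(sigma) || any(mu_t < 0) || any(sigma < 0)) {
    stop("`mu_t` and `sigma` must be non-negative", call. = FALSE)
  }
  if (any(mu_t + sigma <= 0)) {
    stop("`mu_t + sigma` must be strictly positive", call. = FALSE)
  }
  sigma / (sigma + mu_t)
}

#' Probability mass function of the number of tessels crossed
#'
#' Probability that a photon whose first tessel is of type a (use
#' `start = "b"` to permute the materials) crosses exactly `N` whole tessels
#' before stopping. Crossing probabilities alternate between the two
#' materials, and the final factor is the probability of stopping inside
#' the (N+1)-th tessel, so the sequence sums to one.
#'
#' @param params A [mixture_params()] object.
#' @param N Number of crossings (integer >= 0). Vectorised.
#' @param start Material of the first tessel, `"a"` (default) or `"b"`.
#' @return Probabilities in `[0, 1]`, one per element of `N`.
#' @examples
#' mp <- mixture_params(1, 2, 1, 2, P = 0.5)
#' pmf_jump_count(mp, 0)  # mu_ta / (mu_ta + sigma_a) = 0.5
#' @export
pmf_jump_count <- function(params, N, start = c("a", "b")) {
  stopifnot(inherits(params, "mixture_params"))
  p <- params_for_start(params, start)
  if (!is.numeric(N) || any(N < 0) || any(N != round(N))) {
    stop("`N` must contain non-negative integers", call. = FALSE)
  }
  p1a <- prob_jump_one(p$mu_ta, p$sigma_a)
  p1b <- prob_jump_one(p$mu_tb, p$sigma_b)
  out <- numeric(length(N))
  even <- N %% 2 == 0   # includes N = 0: the photon stops in a type-a tessel
  out[even] <- (p1a * p1b)^(N[even] / 2) * (1 - p1a)
  out[!even] <- p1a * (p1a * p1b)^((N[!even] - 1) / 2) * (1 - p1b)
  out
}

#' Truncation point for the jump-count series
#'
#' Smallest `N_max` such that the neglected mass
#' `sum(pmf_jump_count(params, N > N_max))` is below `ctrl$epsilon_tail`,
#' using the geometric tail bound with per-pair ratio
#' `prob_jump_one(a) * prob_jump_one(b)`.
#'
#' @inheritParams pmf_jump_count
#' @param ctrl A [series_control()] object.
#' @return An integer `N_max` with attribute `tail_bound` (the bound on the
#'   neglected mass). If the bound cannot be met within `ctrl$n_max_cap`, a
#'   condition of class `ssfmix_truncation_error` is signalled, carrying the
#'   achieved tail bound in its `tail_bound` field.
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' jump_count_truncation(mp, series_control(1e-10))
#' @export
jump_count_truncation <- function(params, ctrl = series_control(), start = c("a", "b")) {
  stopifnot(inherits(params, "mixture_params"), inherits(ctrl, "series_control"))
  p <- params_for_start(params, start)
  p1a <- prob_jump_one(p$mu_ta, p$sigma_a)
  p1b <- prob_jump_one(p$mu_tb, p$sigma_b)
  q <- p1a * p1b  # < 1 because at least one extinction coefficient is positive
  # Every path with N >= 1 crossings starts by crossing the first (type-a)
  # tessel, so P_N <= p1a * q^floor((N-1)/2) and the tail beyond N_max is
  # bounded by 2 * p1a * q^floor(N_max/2) / (1 - q).
  tail_bound <- function(n_max) {
    if (p1a == 0) return(0)
    2 * p1a * q^floor(n_max / 2) / (1 - q)
  }
  for (n_max in 0:ctrl$n_max_cap) {
    tb <- tail_bound(n_max)
    if (tb < ctrl$epsilon_tail) {
      return(structure(n_max, tail_bound = tb))
    }
  }
  cnd <- structure(
    class = c("ssfmix_truncation_error", "error", "condition"),
    list(message = sprintf(
      "cannot bound the jump-count tail below %.3g within n_max_cap = %d (achieved %.3g)",
      ctrl$epsilon_tail, ctrl$n_max_cap, tail_bound(ctrl$n_max_cap)),
      call = sys.call(-1), tail_bound = tail_bound(ctrl$n_max_cap))
  )
  stop(cnd)
}

# -- input checks shared by the elementary densities --------------------------

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("`", name, "` must be finite and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

check_pos_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single finite number > 0", call. = FALSE)
  }
  invisible(TRUE)
}
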