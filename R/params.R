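#' Optical and geometric parameters of a binary mixture
#'
#' Bundles the five scalars that define a binary isotropic-Poisson mixture:
#' the extinction coefficients of the two materials, the inverse mean chord
#' lengths of their tessels, and the mixing probability. Composite rates
#' `r_a = mu_ta + sigma_a`, `r_b = mu_tb + sigma_b` and their difference
#' `mu = r_b - r_a` are derived on construction. All rates are in inverse
#' millimetres and lengths in millimetres by convention; the mathematics is
#' unit-free.
#'
#' @param mu_ta,mu_tb Extinction coefficients of materials a and b
#'   (1/mm). Both must be non-negative and at least one strictly positive.
#' @param sigma_a,sigma_b Inverse mean chord lengths of tessels of type a
#'   and b (1/mm). Non-negative; the composite rates `mu_ta + sigma_a` and
#'   `mu_tb + sigma_b` must each be strictly positive.
#' @param P Probability that a tessel is of type b. `1 - P` is the
#'   probability of type a.
#'
#' @return An object of class `mixture_params`: a list with the five input
#'   fields plus derived `r_a`, `r_b` and `mu` (which may be negative, zero
#'   or positive -- every function in the package is well-defined for all
#'   three signs).
#' @examples
#' mp <- mixture_params(mu_ta = 1, mu_tb = 2, sigma_a = 0.5, sigma_b = 0.7, P = 0.2)
#' mp$mu   # r_b - r_a
#' @export
mixture_params <- function(mu_ta, mu_tb, sigma_a, sigma_b, P = 0.5) {
  for (nm in c("mu_ta", "mu_tb", "sigma_a", "sigma_b", "P")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (mu_ta < 0 || mu_tb < 0) stop("extinction coefficients must be >= 0", call. = FALSE)
  if (mu_ta == 0 && mu_tb == 0) {
    stop("at least one of `mu_ta`, `mu_tb` must be strictly positive", call. = FALSE)
  }
  if (sigma_a < 0 || sigma_b < 0) stop("`sigma_a` and `sigma_b` must be >= 0", call. = FALSE)
  if (P < 0 || P > 1) stop("`P` must lie in [0, 1]", call. = FALSE)
  r_a <- mu_ta + sigma_a
  r_b <- mu_tb + sigma_b
  if (r_a <= 0 || r_b <= 0) {
    stop("composite rates mu_t + sigma must be strictly positive for both materials",
         call. = FALSE)
  }
  structure(
    list(mu_ta = mu_ta, mu_tb = mu_tb, sigma_a = sigma_a, sigma_b = sigma_b,
         P = P, r_a = r_a, r_b = r_b, mu = r_b - r_a),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("Binary mixture parameters (rates in 1/mm)\n")
  cat(sprintf("  material a: mu_ta = %g, sigma_a = %g  (rate r_a = %g)\n",
              x$mu_ta, x$sigma_a, x$r_a))
  cat(sprintf("  material b: mu_tb = %g, sigma_b = %g  (rate r_b = %g)\n",
              x$mu_tb, x$sigma_b, x$r_b))
  cat(sprintf("  P(type b) = %g, rate contrast mu = r_b - r_a = %g\n", x$P, x$mu))
  invisible(x)
}

# Permute the roles of the two materials (type-b start). P is complemented so
# the mixture weights stay attached to the same physical material.
swap_materials <- function(params) {
  mixture_params(mu_ta = params$mu_tb, mu_tb = params$mu_ta,
                 sigma_a = params$sigma_b, sigma_b = params$sigma_a,
                 P = 1 - params$P)
}

# Resolve the "first tessel type" argument convention: operations are written
# for a type-a start and the parameters are permuted for a type-b start.
params_for_start <- function(params, start = c("a", "b")) {
  start <- match.arg(start)
  if (start == "a") params else swap_materials(params)
}

#' Absorption/scattering split of the extinction coefficients
#'
#' Per-material decomposition `mu_t = mu_a + mu_s` used by the effective
#' albedo of the mixture ([albedo_mix()]).
#'
#' @param mu_aa,mu_sa Absorption and scattering coefficients of material a (1/mm).
#' @param mu_ab,mu_sb Absorption and scattering coefficients of material b (1/mm).
#' @return An object of class `optical_split`.
#' @examples
#' optical_split(mu_aa = 0.1, mu_sa = 0.9, mu_ab = 0.5, mu_sb = 1.5)
#' @export
optical_split <- function(mu_aa, mu_sa, mu_ab, mu_sb) {
  v <- c(mu_aa = mu_aa, mu_sa = mu_sa, mu_ab = mu_ab, mu_sb = mu_sb)
  if (!all(is.finite(v)) || any(v < 0)) {
    stop("all absorption/scattering coefficients must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(v), class = "optical_split")
}

# The split must be consistent with the extinction coefficients it is paired with.
check_split <- function(params, split, tol = 1e-10) {
  if (!inherits(split, "optical_split")) stop("`split` must be an optical_split", call. = FALSE)
  ok_a <- abs(split$mu_aa + split$mu_sa - params$mu_ta) <= tol * max(1, params$mu_ta)
  ok_b <- abs(split$mu_ab + split$mu_sb - params$mu_tb) <= tol * max(1, params$mu_tb)
  if (!ok_a || !ok_b) {
    stop("optical split is inconsistent with the mixture: mu_t must equal mu_a + mu_s ",
         "for each material", call. = FALSE)
  }
  invisible(TRUE)
}

#' Truncation and quadrature policy for the infinite series
#'
#' The mixture step density is an infinite sum over the number of crossed
#' tessels. `series_control` fixes how that sum is truncated and how
#' accurately the numeric quadratures are carried out.
#'
#' @param epsilon_tail Bound on the neglected probability mass of the
#'   jump-count series (dimensionless, in (0, 1)).
#' @param n_max_cap Hard upper bound on the summed number of crossings.
#' @param quad_rel_tol Relative tolerance for numeric quadrature.
#' @return An object of class `series_control`.
#' @examples
#' series_control(epsilon_tail = 1e-12)
#' @export
series_control <- function(epsilon_tail = 1e-10, n_max_cap = 4096L, quad_rel_tol = 1e-10) {
  if (!is.numeric(epsilon_tail) || length(epsilon_tail) != 1L ||
      epsilon_tail <= 0 || epsilon_tail >= 1) {
    stop("`epsilon_tail` must be a single number in (0, 1)", call. = FALSE)
  }
  n_max_cap <- as.integer(n_max_cap)
  if (is.na(n_max_cap) || n_max_cap < 2L) stop("`n_max_cap` must be >= 2", call. = FALSE)
  if (!is.numeric(quad_rel_tol) || length(quad_rel_tol) != 1L ||
      quad_rel_tol <= 0 || quad_rel_tol >= 1) {
    stop("`quad_rel_tol` must be a single number in (0, 1)", call. = FALSE)
  }
  structure(list(epsilon_tail = epsilon_tail, n_max_cap = n_max_cap,
                 quad_rel_tol = quad_rel_tol),
            class = "series_control")
}

#' Chord rates of an isotropic Poisson tessellation
#'
#' For the tessellation to have the same exponential chord law in every
#' direction, the two inverse mean chords must be tied to the construction
#' scale `L` and the mixing probability `P` by `sigma_a = (1 - P)/L`,
#' `sigma_b = P/L`, so that `sigma_a + sigma_b = 1/L`.
#'
#' @param L Construction length scale of the tessellation (mm, > 0).
#' @param P Probability that a tessel is of type b.
#' @return A named list with elements `sigma_a` and `sigma_b` (1/mm).
#' @examples
#' isotropy_sigmas(L = 2, P = 0.25)
#' @export
isotropy_sigmas <- function(L, P) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("`L` must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P < 0 || P > 1) {
    stop("`P` must lie in [0, 1]", call. = FALSE)
  }
  # Compute the larger share directly and the smaller as its complement:
  # the subtraction is then exact (Sterbenz), so sigma_a + sigma_b == 1/L
  # holds bit-exactly.
  inv_L <- 1 / L
  if (P <= 0.5) {
    sigma_a <- (1 - P) / L
    sigma_b <- inv_L - sigma_a
  } else {
    sigma_b <- P / L
    sigma_a <- inv_L - sigma_b
  }
  list(sigma_a = sigma_a, sigma_b = sigma_b)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.mixture_params <- function(x, ...) {
  tibble::tibble(
    term = c("mu_ta", "mu_tb", "sigma_a", "sigma_b", "P", "r_a", "r_b", "mu"),
    value = c(x$mu_ta, x$mu_tb, x$sigma_a, x$sigma_b, x$P, x$r_a, x$r_b, x$mu)
  )
}
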