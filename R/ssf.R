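# The mixture single-step function: weighted series of jump-over densities
# with jump-count weights, its distribution function, mean, quantile table
# and effective albedo.

# Truncated jump-count weights for one start type.
ssf_weights <- function(params, ctrl, start = "a") {
  n_max <- jump_count_truncation(params, ctrl, start = start)
  w <- pmf_jump_count(params, 0:n_max, start = start)
  list(n_max = as.integer(n_max), weights = w,
       tail_bound = attr(n_max, "tail_bound"),
       neglected = max(0, 1 - sum(w)))
}

#' Single-step density for a fixed first-tessel type
#'
#' Free-path density of a photon whose first tessel is of type `start`:
#' the series over the number of crossed tessels of the jump-over densities
#' weighted by the jump-count probabilities, truncated so that the neglected
#' probability mass is below `ctrl$epsilon_tail`. The truncation residual is
#' not rescaled away; the density is reported as computed (see
#' [ssf_diagnostics()] for the neglected mass).
#'
#' @param s Path length (mm, >= 0). Vectorised.
#' @param params A [mixture_params()] object.
#' @param ctrl A [series_control()] object.
#' @param start Material of the first tessel, `"a"` (default) or `"b"`.
#' @return Probability density values.
#' @examples
#' mp <- mixture_params(1, 1, 0.6, 0.6, P = 0.5)  # homogeneous medium
#' pdf_ssf_one_start(1, mp)  # equals 1 * exp(-1)
#' @export
pdf_ssf_one_start <- function(s, params, ctrl = series_control(), start = c("a", "b")) {
  stopifnot(inherits(params, "mixture_params"))
  check_nonneg(s, "s")
  start <- match.arg(start)
  w <- ssf_weights(params, ctrl, start)
  out <- numeric(length(s))
  for (N in 0:w$n_max) {
    if (w$weights[N + 1] > 0) {
      out <- out + w$weights[N + 1] * pdf_tessel_sum(s, params, N + 1, start = start)
    }
  }
  out
}

#' Single-step function of the binary mixture
#'
#' The free-path density of the mixture: the type-a and type-b start
#' densities weighted by the probabilities `1 - P` and `P` of the first
#' tessel type. Valid for any `P` and for both signs of the rate contrast;
#' the isotropy construction is not assumed.
#'
#' @inheritParams pdf_ssf_one_start
#' @return Probability density values; integrates to 1 up to the series
#'   truncation residual.
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' pdf_ssf_mix(c(0.1, 1, 3), mp)
#' @export
pdf_ssf_mix <- function(s, params, ctrl = series_control()) {
  stopifnot(inherits(params, "mixture_params"))
  P <- params$P
  out <- 0
  if (P < 1) out <- out + (1 - P) * pdf_ssf_one_start(s, params, ctrl, start = "a")
  if (P > 0) out <- out + P * pdf_ssf_one_start(s, params, ctrl, start = "b")
  out
}

#' Distribution function of the mixture single-step function
#'
#' `P(step <= s)`, computed by adaptive quadrature of [pdf_ssf_mix()] at the
#' relative tolerance in `ctrl`. For evaluating the distribution function at
#' many points (e.g. for Kolmogorov-Smirnov tests on large samples) build a
#' quantile table once and use [cdf_ssf_interp()] instead.
#'
#' @inheritParams pdf_ssf_mix
#' @return Probabilities, non-decreasing in `s`, tending to 1 (up to the
#'   truncation residual) as `s` grows.
#' @examples
#' mp <- mixture_params(1, 1, 0.6, 0.6, P = 0.5)
#' cdf_ssf_mix(1, mp)  # 1 - exp(-1)
#' @export
cdf_ssf_mix <- function(s, params, ctrl = series_control()) {
  stopifnot(inherits(params, "mixture_params"))
  check_nonneg(s, "s")
  f <- function(x) pdf_ssf_mix(x, params, ctrl)
  ord <- order(s)
  su <- s[ord]
  vals <- numeric(length(su))
  acc <- 0
  prev <- 0
  for (i in seq_along(su)) {
    if (i > 1 && su[i] == su[i - 1]) {
      vals[i] <- acc
      next
    }
    if (su[i] > prev) {
      acc <- acc + stats::integrate(f, prev, su[i],
                                    rel.tol = ctrl$quad_rel_tol,
                                    abs.tol = ctrl$quad_rel_tol)$value
      prev <- su[i]
    }
    vals[i] <- acc
  }
  out <- numeric(length(s))
  out[ord] <- vals
  pmin(out, 1)
}

#' Mean step length in the binary mixture
#'
#' Closed-form first moment of the mixture single-step function. In the
#' homogeneous case (`mu_ta == mu_tb`) it reduces to `1/mu_ta`.
#'
#' @param params A [mixture_params()] object. At least one extinction
#'   coefficient must be strictly positive (otherwise the mean is infinite),
#'   which the constructor already guarantees.
#' @return The mean step length (mm).
#' @examples
#' mean_step_mix(mixture_params(2, 2, 0.5, 0.7, P = 0.3))  # 0.5
#' @export
mean_step_mix <- function(params) {
  stopifnot(inherits(params, "mixture_params"))
  p <- params
  den_a <- p$mu_tb * p$sigma_a + p$mu_ta * (p$mu_tb + p$sigma_b)
  den_b <- p$mu_ta * p$sigma_b + p$mu_tb * (p$mu_ta + p$sigma_a)
  if (den_a <= 0 || den_b <= 0) {
    stop("mean step length is infinite: extinction vanishes along one material chain",
         call. = FALSE)
  }
  (1 - p$P) * (p$mu_tb + p$sigma_a + p$sigma_b) / den_a +
    p$P * (p$mu_ta + p$sigma_b + p$sigma_a) / den_b
}

#' Effective albedo of the binary mixture
#'
#' Probability that an interaction in the mixture is a scattering event:
#' the occupation-weighted scattering rate over the occupation-weighted
#' extinction rate. Reduces to the classical `mu_s/mu_t` when the two
#' materials share the same coefficients.
#'
#' @param params A [mixture_params()] object (supplies `mu_ta`, `mu_tb`, `P`).
#' @param split An [optical_split()] object consistent with `params`.
#' @return A probability in `[0, 1]`.
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.5)
#' sp <- optical_split(mu_aa = 0.1, mu_sa = 0.9, mu_ab = 0.5, mu_sb = 1.5)
#' albedo_mix(mp, sp)  # 0.8
#' @export
albedo_mix <- function(params, split) {
  stopifnot(inherits(params, "mixture_params"))
  check_split(params, split)
  P <- params$P
  den <- (1 - P) * params$mu_ta + P * params$mu_tb
  if (den <= 0) stop("zero occupation-weighted extinction", call. = FALSE)
  ((1 - P) * split$mu_sa + P * split$mu_sb) / den
}

#' Series truncation diagnostics
#'
#' Reports, for each start type, the truncation point of the jump-count
#' series and the bound on the neglected probability mass under `ctrl`.
#'
#' @inheritParams pdf_ssf_mix
#' @return A tibble with columns `start`, `n_max`, `tail_bound`,
#'   `neglected_mass` (the exact mass beyond the truncation).
#' @export
ssf_diagnostics <- function(params, ctrl = series_control()) {
  rows <- lapply(c("a", "b"), function(st) {
    w <- ssf_weights(params, ctrl, st)
    tibble::tibble(start = st, n_max = w$n_max, tail_bound = w$tail_bound,
                   neglected_mass = w$neglected)
  })
  do.call(rbind, rows)
}

# Cumulative integral of f at the given increasing knots (value 0 at the
# first knot), by composite 3-point Gauss-Legendre with `nsub` panels per
# interval. One vectorised call to f.
gauss_cumulative <- function(f, knots, nsub = 8L) {
  x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  w <- c(5, 8, 5) / 9
  a <- rep(knots[-length(knots)], each = nsub) +
    (rep(seq_len(nsub) - 1L, times = length(knots) - 1L)) *
    rep(diff(knots) / nsub, each = nsub)
  h <- rep(diff(knots) / nsub, each = nsub)
  pts <- as.vector(outer(x, rep(1, length(a))) * rep(h / 2, each = 3) +
                   rep(a + h / 2, each = 3))
  fv <- matrix(f(pts), nrow = 3)
  panel <- colSums(fv * w) * h / 2
  per_interval <- colSums(matrix(panel, nrow = nsub))
  c(0, cumsum(per_interval))
}

# Upper end point s_star with cdf(s_star) >= 1 - 1e-8 (up to the series
# truncation residual), found by doubling from a multiple of the mean.
find_upper_tail <- function(params, ctrl, tail_target = 5e-9) {
  f <- function(x) pdf_ssf_mix(x, params, ctrl)
  s_star <- 10 * mean_step_mix(params)
  for (i in 1:60) {
    tail <- stats::integrate(f, s_star, Inf,
                             rel.tol = 1e-8, abs.tol = tail_target / 10)$value
    if (tail <= tail_target) return(s_star)
    s_star <- 2 * s_star
  }
  stop("failed to bracket the upper tail of the step distribution", call. = FALSE)
}

#' Quantile look-up table of the single-step function
#'
#' Tabulates the distribution function of the mixture single-step function
#' on a grid placed at equally spaced probability levels (inverse
#' placement), so that interpolation error is uniform in probability. The
#' table is the look-up object used for inverse-transform sampling of
#' photon steps; it is computed once, instead of re-summing the series at
#' every photon step.
#'
#' @inheritParams pdf_ssf_mix
#' @param table_size Number of grid nodes (>= 64; default 4096).
#' @return An `ssf_quantile_table`: a tibble with columns `s` and `cdf`
#'   (first row `(0, 0)`), and attributes `params`, `ctrl`, `coverage` (the
#'   distribution function at the last node, `>= 1 - 1e-8`) and
#'   `params_hash`.
#' @examples
#' mp <- mixture_params(1, 1, 0.6, 0.6, P = 0.5)
#' qt <- build_quantile_table(mp, table_size = 256)
#' quantile_ssf_mix(qt, 0.5)  # close to log(2) / 1
#' @export
build_quantile_table <- function(params, ctrl = series_control(), table_size = 4096L) {
  stopifnot(inherits(params, "mixture_params"))
  table_size <- as.integer(table_size)
  if (is.na(table_size) || table_size < 64L) {
    stop("`table_size` must be an integer >= 64", call. = FALSE)
  }
  f <- function(x) pdf_ssf_mix(x, params, ctrl)
  s_star <- find_upper_tail(params, ctrl)
  # Dense forward pass: cumulative quadrature on a uniform grid, then
  # inversion onto uniform probability levels.
  n_dense <- max(4L * table_size, 4096L)
  dense_s <- seq(0, s_star, length.out = n_dense + 1L)
  dense_cdf <- gauss_cumulative(f, dense_s, nsub = 4L)
  coverage <- dense_cdf[length(dense_cdf)]
  if (coverage < 1 - 1e-8) {
    stop(sprintf("quantile table coverage %.10f is below 1 - 1e-8", coverage),
         call. = FALSE)
  }
  # Invert: strictly increasing cdf knots only.
  keep <- c(TRUE, diff(dense_cdf) > 0)
  inv <- stats::splinefun(dense_cdf[keep], dense_s[keep], method = "monoH.FC")
  levels <- seq(0, coverage, length.out = table_size)
  s_grid <- inv(levels)
  s_grid[1] <- 0
  s_grid <- cummax(s_grid)
  tbl <- tibble::tibble(s = s_grid, cdf = levels)
  attr(tbl, "params") <- params
  attr(tbl, "ctrl") <- ctrl
  attr(tbl, "coverage") <- coverage
  attr(tbl, "params_hash") <- params_hash(params)
  class(tbl) <- c("ssf_quantile_table", class(tbl))
  tbl
}

params_hash <- function(params) {
  paste0("ssfmix:", paste(sprintf("%.17g",
    c(params$mu_ta, params$mu_tb, params$sigma_a, params$sigma_b, params$P)),
    collapse = ","))
}

#' Quantiles of the single-step function from a look-up table
#'
#' Monotone piecewise-cubic interpolation of the inverse distribution
#' function tabulated by [build_quantile_table()].
#'
#' @param table An `ssf_quantile_table`.
#' @param xi Probability levels in `[0, coverage)`. Vectorised.
#' @return Step lengths (mm); `quantile_ssf_mix(table, 0)` is 0.
#' @examples
#' mp <- mixture_params(1, 1, 0.6, 0.6, P = 0.5)
#' qt <- build_quantile_table(mp, table_size = 256)
#' quantile_ssf_mix(qt, c(0.1, 0.5, 0.9))
#' @export
quantile_ssf_mix <- function(table, xi) {
  stopifnot(inherits(table, "ssf_quantile_table"))
  if (!is.numeric(xi) || any(!is.finite(xi)) || any(xi < 0)) {
    stop("`xi` must be finite and >= 0", call. = FALSE)
  }
  coverage <- attr(table, "coverage")
  if (any(xi >= coverage)) {
    cnd <- structure(
      class = c("ssfmix_tail_error", "error", "condition"),
      list(message = sprintf(
        "quantile level beyond table coverage (%.10f); extend the table",
        coverage), call = sys.call(-1)))
    stop(cnd)
  }
  keep <- c(TRUE, diff(table$cdf) > 0)
  fn <- stats::splinefun(table$cdf[keep], table$s[keep], method = "monoH.FC")
  pmax(0, fn(xi))
}

#' Distribution function interpolated from a quantile table
#'
#' Forward (s to probability) monotone interpolation of a tabulated
#' distribution function. Cheap to evaluate at millions of points; the
#' interpolation error is uniform in probability at the level of the table
#' spacing squared.
#'
#' @param table An `ssf_quantile_table`.
#' @param s Step lengths (mm, >= 0). Values beyond the last node return the
#'   coverage.
#' @return Probabilities.
#' @export
cdf_ssf_interp <- function(table, s) {
  stopifnot(inherits(table, "ssf_quantile_table"))
  check_nonneg(s, "s")
  keep <- c(TRUE, diff(table$s) > 0)
  fn <- stats::splinefun(table$s[keep], table$cdf[keep], method = "monoH.FC")
  coverage <- attr(table, "coverage")
  out <- fn(pmin(s, max(table$s)))
  pmin(pmax(out, 0), coverage)
}

#' Tabulated single-step function
#'
#' Evaluates the mixture single-step density and distribution function on a
#' grid of step lengths and returns them as a tibble, ready for plotting or
#' export.
#'
#' @inheritParams pdf_ssf_mix
#' @param s Optional increasing grid of step lengths (mm). By default a
#'   uniform grid of `n` points up to the scale where all but `tail_target`
#'   of the mass lies.
#' @param n Number of grid points when `s` is not supplied.
#' @param tail_target Neglected upper-tail mass of the default grid.
#' @param cdf Also tabulate the distribution function (set `FALSE` to skip
#'   the cumulative quadrature when only the density is needed).
#' @return A tibble with columns `s`, `pdf` and (unless `cdf = FALSE`)
#'   `cdf`, carrying `params` and `ctrl` as attributes.
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' head(ssf_table(mp, n = 64))
#' @export
ssf_table <- function(params, s = NULL, ctrl = series_control(), n = 512L,
                      tail_target = 1e-6, cdf = TRUE) {
  stopifnot(inherits(params, "mixture_params"))
  if (is.null(s)) {
    s_star <- find_upper_tail(params, ctrl, tail_target = tail_target)
    s <- seq(0, s_star, length.out = n)
  }
  check_nonneg(s, "s")
  if (is.unsorted(s, strictly = TRUE)) {
    stop("`s` must be strictly increasing", call. = FALSE)
  }
  f <- function(x) pdf_ssf_mix(x, params, ctrl)
  pdf_vals <- f(s)
  out <- tibble::tibble(s = s, pdf = pdf_vals)
  if (cdf) {
    knots <- if (s[1] > 0) c(0, s) else s
    cum <- gauss_cumulative(f, knots, nsub = 8L)
    cdf_vals <- if (s[1] > 0) cum[-1] else cum
    out$cdf <- pmin(cdf_vals, 1)
  }
  attr(out, "params") <- params
  attr(out, "ctrl") <- ctrl
  out
}
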