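# Direct Monte Carlo validators: explicit tessel-by-tessel photon stepping,
# interior-start memorylessness demonstration, and the equivalent-homogeneous
# sampler driven by the quantile look-up table.
#
# All simulators use one seedable base-R generator per call. Draws are made
# in round-major order (one vectorised draw for all still-active photons per
# iteration), so results are bit-reproducible given the seed and the number
# of photons. Exponential deviates use the inverse transform
# -log(1 - xi)/rate, which keeps xi = 0 finite, and the first-tessel type
# uses the strict comparison xi < 1 - P.

rexp_inv <- function(n, rate) {
  -log1p(-stats::runif(n)) / rate
}

#' Direct Monte Carlo simulation of photon steps in the binary mixture
#'
#' Propagates each photon tessel by tessel: draw the first-tessel type
#' (`xi < 1 - P` gives type a), then repeatedly draw a chord length and a
#' candidate free path in the current material; if the candidate exceeds the
#' chord the photon crosses into the next (alternating) material, otherwise
#' it stops and the total travelled length is recorded. A fresh tessellation
#' is drawn for every photon.
#'
#' @param params A [mixture_params()] object.
#' @param n_photons Number of photons (>= 1).
#' @param seed Integer seed for the run.
#' @return A tibble with one row per photon: `s` (total step length, mm),
#'   `n_tessels` (whole tessels crossed before stopping) and `start_type`
#'   (`"a"` or `"b"`).
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' steps <- simulate_direct_steps(mp, n_photons = 1000, seed = 7)
#' mean(steps$s)
#' @export
simulate_direct_steps <- function(params, n_photons, seed) {
  stopifnot(inherits(params, "mixture_params"))
  n_photons <- as.integer(n_photons)
  if (is.na(n_photons) || n_photons < 1L) stop("`n_photons` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  mu_t <- c(params$mu_ta, params$mu_tb)
  sigma <- c(params$sigma_a, params$sigma_b)

  xi <- stats::runif(n_photons)
  cur <- ifelse(xi < 1 - params$P, 1L, 2L)
  start_type <- c("a", "b")[cur]
  s_tot <- numeric(n_photons)
  n_cross <- integer(n_photons)
  active <- seq_len(n_photons)
  while (length(active) > 0L) {
    m <- length(active)
    ca <- cur[active]
    ell <- rexp_inv(m, sigma[ca])    # sigma = 0 gives an infinite chord
    step <- rexp_inv(m, mu_t[ca])    # mu_t = 0 gives an infinite candidate
    stops <- step <= ell
    s_tot[active] <- s_tot[active] + ifelse(stops, step, ell)
    crossed <- active[!stops]
    n_cross[crossed] <- n_cross[crossed] + 1L
    cur[crossed] <- 3L - cur[crossed]
    active <- crossed
  }
  tibble::tibble(s = s_tot, n_tessels = n_cross, start_type = start_type)
}

#' Interior-start residual chord simulation
#'
#' Demonstrates the memorylessness of the chord law: pick a point at depth
#' `s_cte` from the boundary, accumulate alternating tessel chords (type a
#' first) until their sum exceeds `s_cte`, and record the overshoot -- the
#' residual distance from the point to the next tessel boundary. Split by
#' the material containing the point, the residuals are again exponential
#' with the matching chord rate, so interior starting points are
#' statistically equivalent to boundary starts.
#'
#' @param params A [mixture_params()] object with both `sigma_a > 0` and
#'   `sigma_b > 0` (the walk must be able to pass `s_cte`).
#' @param s_cte_values Depths from the boundary (mm, >= 0). One simulation
#'   of `n_reps` walks is run per value.
#' @param n_reps Number of walks per depth.
#' @param seed Integer seed.
#' @return A tibble with columns `s_cte`, `ell` (residual length, mm),
#'   `n_tessels` (index n of the tessel containing the point) and `type`
#'   (material of that tessel: odd n is `"a"`).
#' @examples
#' mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
#' res <- simulate_interior_start(mp, c(0.5, 5), n_reps = 500, seed = 3)
#' @export
simulate_interior_start <- function(params, s_cte_values, n_reps, seed) {
  stopifnot(inherits(params, "mixture_params"))
  check_nonneg(s_cte_values, "s_cte_values")
  if (params$sigma_a <= 0 || params$sigma_b <= 0) {
    stop("both chord rates must be strictly positive", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  sigma <- c(params$sigma_a, params$sigma_b)
  out <- vector("list", length(s_cte_values))
  for (j in seq_along(s_cte_values)) {
    s_cte <- s_cte_values[j]
    total <- numeric(n_reps)
    ell <- numeric(n_reps)
    n_at <- integer(n_reps)
    active <- seq_len(n_reps)
    k <- 0L
    while (length(active) > 0L) {
      k <- k + 1L
      chord <- rexp_inv(length(active), sigma[if (k %% 2L == 1L) 1L else 2L])
      total[active] <- total[active] + chord
      done <- total[active] > s_cte
      idx <- active[done]
      ell[idx] <- total[idx] - s_cte
      n_at[idx] <- k
      active <- active[!done]
    }
    out[[j]] <- tibble::tibble(
      s_cte = s_cte, ell = ell, n_tessels = n_at,
      type = ifelse(n_at %% 2L == 1L, "a", "b"))
  }
  do.call(rbind, out)
}

#' Sample photon steps from the equivalent homogeneous medium
#'
#' Inverse-transform sampling of the mixture single-step function through a
#' quantile look-up table: the binary medium is replaced by one equivalent
#' homogeneous medium whose free paths follow the mixture step law.
#'
#' @param table An `ssf_quantile_table` from [build_quantile_table()].
#' @param n_photons Number of steps to draw.
#' @param seed Integer seed.
#' @param tail Policy for uniform draws beyond the table coverage:
#'   `"resample"` (default) redraws them, `"error"` propagates the tail
#'   condition from [quantile_ssf_mix()].
#' @return A tibble with column `s` (step lengths, mm).
#' @examples
#' mp <- mixture_params(1, 1, 0.6, 0.6, P = 0.5)
#' qt <- build_quantile_table(mp, table_size = 256)
#' sim <- simulate_equivalent_homogeneous(qt, 1000, seed = 11)
#' @export
simulate_equivalent_homogeneous <- function(table, n_photons, seed,
                                            tail = c("resample", "error")) {
  stopifnot(inherits(table, "ssf_quantile_table"))
  tail <- match.arg(tail)
  n_photons <- as.integer(n_photons)
  if (is.na(n_photons) || n_photons < 1L) stop("`n_photons` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  coverage <- attr(table, "coverage")
  xi <- stats::runif(n_photons)
  if (tail == "resample") {
    for (i in 1:100) {
      bad <- xi >= coverage
      if (!any(bad)) break
      xi[bad] <- stats::runif(sum(bad))
    }
  }
  tibble::tibble(s = quantile_ssf_mix(table, xi))
}

#' Density-normalised histogram of photon steps
#'
#' Bins step lengths and normalises so that the histogram integrates to one
#' over the supplied bins; records falling outside the bin range are
#' rejected.
#'
#' @param records A tibble with a numeric column `s` (e.g. from
#'   [simulate_direct_steps()]) or a numeric vector of step lengths.
#' @param bin_edges Strictly increasing bin edges (mm).
#' @return A `step_histogram`: a tibble with columns `bin_left`,
#'   `bin_right`, `count`, `density`, and attributes `n_samples` and
#'   `bin_edges`.
#' @examples
#' h <- histogram_steps(c(0.1, 0.2, 0.9), bin_edges = seq(0, 1, 0.5))
#' sum(h$density * (h$bin_right - h$bin_left))  # 1
#' @export
histogram_steps <- function(records, bin_edges) {
  s <- if (is.data.frame(records)) records$s else records
  if (is.null(s) || length(s) == 0L) stop("no step records supplied", call. = FALSE)
  if (!is.numeric(bin_edges) || length(bin_edges) < 2L ||
      is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing with at least two values",
         call. = FALSE)
  }
  inside <- s >= bin_edges[1] & s <= bin_edges[length(bin_edges)]
  if (!any(inside)) stop("no records fall inside `bin_edges`", call. = FALSE)
  s <- s[inside]
  idx <- findInterval(s, bin_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  widths <- diff(bin_edges)
  dens <- counts / (sum(counts) * widths)
  out <- tibble::tibble(
    bin_left = bin_edges[-length(bin_edges)],
    bin_right = bin_edges[-1],
    count = counts,
    density = dens)
  attr(out, "n_samples") <- length(s)
  attr(out, "bin_edges") <- bin_edges
  class(out) <- c("step_histogram", class(out))
  out
}
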