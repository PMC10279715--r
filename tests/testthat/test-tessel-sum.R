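test_that("first-tessel stop density is the composite-rate exponential", {
  expect_equal(pdf_first_tessel_stop(0, 1, 2), 3)
  expect_equal(integrate(function(s) pdf_first_tessel_stop(s, 1, 2), 0, Inf)$value,
               1, tolerance = 1e-9)
  s <- seq(0, 4, by = 0.25)
  expect_equal(pdf_first_tessel_stop(s, 1, 2), pdf_beer_lambert(s, 3))
})

test_that("same-material path density is the gamma law", {
  s <- seq(0, 6, by = 0.1)
  expect_equal(pdf_sum_same_material(s, 1, 1, 1), pdf_first_tessel_stop(s, 1, 1))
  # independent oracle: matrix exponential of the three-stage chain
  skip_if_not_installed("Matrix")
  s3 <- seq(0.25, 6, by = 0.25)
  expect_lt(max(abs(pdf_sum_same_material(s3, 1.5, 0.5, 3) -
                    expm_chain_pdf(s3, rep(2, 3)))), 1e-6)
  # gamma mode at (N - 1)/rate
  grid <- seq(3.5, 4.5, by = 1e-3)
  dens <- pdf_sum_same_material(grid, 0.4, 0.6, 5)
  expect_equal(grid[which.max(dens)], 4, tolerance = 1e-3)
  expect_error(pdf_sum_same_material(1, 1, 1, 0), ">= 1")
})

test_that("single-tessel case drops the second material entirely", {
  s <- seq(0, 5, by = 0.25)
  mp1 <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  mp2 <- mixture_params(1, 17, 0.5, 9.3, P = 0.9)
  expect_identical(pdf_tessel_sum(s, mp1, 1), pdf_tessel_sum(s, mp2, 1))
  expect_equal(pdf_tessel_sum(s, mp1, 1), pdf_first_tessel_stop(s, 1, 0.5))
})

test_that("two-tessel density matches the two-exponential convolution", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  ra <- mp$r_a
  rb <- mp$r_b
  s <- seq(0, 8, by = 0.1)
  closed <- ra * rb * (exp(-ra * s) - exp(-rb * s)) / (rb - ra)
  expect_equal(pdf_tessel_sum(s, mp, 2), closed, tolerance = 1e-13)
})

test_that("equal composite rates reduce to the gamma law", {
  mp <- mixture_params(1.2, 0.9, 0.3, 0.6, P = 0.5)  # r_a == r_b = 1.5
  expect_equal(mp$mu, 0)
  s <- seq(0, 10, by = 0.2)
  for (N in c(2, 3, 5, 8)) {
    expect_equal(pdf_tessel_sum(s, mp, N),
                 pdf_sum_same_material(s, 1.2, 0.3, N), tolerance = 1e-12)
  }
})

test_that("alternating-chord densities integrate to one for N = 1..10", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  for (N in 1:10) {
    val <- integrate(function(s) pdf_tessel_sum(s, mp, N), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_lt(abs(val - 1), 1e-8)
  }
})

test_that("Bessel forms match direct numeric alternating convolutions", {
  skip_if_not_installed("Matrix")
  sets <- random_param_sets(10, seed = 31)
  s <- seq(0.25, 8, by = 0.25)
  for (params in sets) {
    for (N in c(2, 3, 5, 8)) {
      rates <- chain_rates(params, N)
      expect_lt(max(abs(pdf_tessel_sum(s, params, N) - expm_chain_pdf(s, rates))),
                1e-6)
    }
  }
  # grid-convolution route (fully independent of matrix exponentials) on a
  # subset of the regimes
  for (params in validation_regimes()[c(1, 2)]) {
    for (N in c(3, 6)) {
      rates <- chain_rates(params, N)
      expect_lt(max(abs(pdf_tessel_sum(s, params, N) - conv_chain_pdf(s, rates))),
                1e-6)
    }
  }
})

test_that("even-N densities are symmetric under material exchange", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  sw <- ssfmix:::swap_materials(mp)
  s <- seq(0, 12, by = 0.2)
  for (N in c(2, 4, 6, 8)) {
    expect_equal(pdf_tessel_sum(s, mp, N), pdf_tessel_sum(s, sw, N),
                 tolerance = 1e-12)
  }
})

test_that("negative rate contrast is handled without complex arithmetic", {
  skip_if_not_installed("Matrix")
  mp_neg <- mixture_params(2, 1, 0.7, 0.5, P = 0.5)  # mu < 0
  expect_lt(mp_neg$mu, 0)
  s <- seq(0.25, 8, by = 0.25)
  # even N: equals the swapped (mu > 0) evaluation
  sw <- ssfmix:::swap_materials(mp_neg)
  for (N in c(2, 6)) {
    expect_equal(pdf_tessel_sum(s, mp_neg, N), pdf_tessel_sum(s, sw, N),
                 tolerance = 1e-12)
  }
  # odd N: checked against its own convolution oracle
  for (N in c(3, 7)) {
    expect_lt(max(abs(pdf_tessel_sum(s, mp_neg, N) -
                      expm_chain_pdf(s, chain_rates(mp_neg, N)))), 1e-6)
  }
})

test_that("evaluation stays finite far into the exponential tail", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  s_far <- 700 / max(mp$r_a, mp$r_b)
  for (N in c(1, 2, 3, 10, 25)) {
    v <- pdf_tessel_sum(s_far, mp, N)
    expect_true(is.finite(v) && v >= 0)
  }
  # large argument to the scaled-Bessel branch as well
  wide <- mixture_params(0.1, 8, 0.1, 4, P = 0.5)
  v <- pdf_tessel_sum(seq(50, 80, by = 5), wide, 4)
  expect_true(all(is.finite(v) & v >= 0))
})

test_that("jump-over density is the (N+1)-chord law", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  s <- seq(0, 6, by = 0.2)
  expect_equal(pdf_step_over_N(s, mp, 0), pdf_first_tessel_stop(s, 1, 0.5))
  # N = 1: numeric convolution of the a-side chord and b-side stop densities
  conv <- vapply(s[s > 0], function(si) {
    integrate(function(u) pdf_tessel_sum(u, mp, 1) *
                pdf_first_tessel_stop(si - u, mp$mu_tb, mp$sigma_b),
              0, si, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(pdf_step_over_N(s[s > 0], mp, 1), conv, tolerance = 1e-8)
  for (N in 0:6) {
    val <- integrate(function(x) pdf_step_over_N(x, mp, N), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_lt(abs(val - 1), 1e-8)
  }
  expect_error(pdf_step_over_N(1, mp, -1), ">= 0")
})
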