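test_that("homogeneous media recover the pure exponential step law", {
  s <- seq(0, 8, by = 0.05)
  for (P in c(0, 0.3, 0.5, 1)) {
    mp <- mixture_params(1.3, 1.3, 0.6, 0.6, P = P)
    expect_lt(max(abs(pdf_ssf_mix(s, mp) - 1.3 * exp(-1.3 * s))), 1e-10)
  }
  mp <- mixture_params(0.7, 0.7, 1.1, 1.1, P = 0.4)
  expect_lt(max(abs(pdf_ssf_one_start(s, mp) - 0.7 * exp(-0.7 * s))), 1e-10)
})

test_that("vanishing type-b chords recover the type-a exponential law", {
  mp <- mixture_params(1, 2, sigma_a = 0.5, sigma_b = 1e6, P = 0.3)
  s <- seq(0, 5 / mp$mu_ta, length.out = 201)
  expect_lt(max(abs(pdf_ssf_one_start(s, mp) - mp$mu_ta * exp(-mp$mu_ta * s))),
            1e-3)
})

test_that("infinite mean chords recover the two-exponential mixture", {
  mp <- mixture_params(1, 2, sigma_a = 1e-9, sigma_b = 1e-9, P = 0.3)
  s <- seq(0, 6, length.out = 201)
  # one start type: all mass in the no-crossing term
  expect_lt(max(abs(pdf_ssf_one_start(s, mp) - 1 * exp(-1 * s))), 1e-3)
  lim <- 0.7 * 1 * exp(-1 * s) + 0.3 * 2 * exp(-2 * s)
  expect_lt(max(abs(pdf_ssf_mix(s, mp) - lim)), 1e-3)
})

test_that("mixture step density is normalised and non-negative", {
  for (params in random_param_sets(8, seed = 55)) {
    s <- seq(0, 20, length.out = 301)
    expect_true(all(pdf_ssf_mix(s, params) >= 0))
    val <- integrate(function(x) pdf_ssf_mix(x, params), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_lt(abs(val - 1), 1e-8)
  }
})

test_that("series evaluation matches the absorbing-chain oracle", {
  skip_if_not_installed("Matrix")
  s <- seq(0.1, 8, by = 0.35)
  for (params in c(validation_regimes(), random_param_sets(4, seed = 17))) {
    for (start in c("a", "b")) {
      o <- phase_type_ssf_pdf(s, params, start = start)
      v <- pdf_ssf_one_start(s, params, start = start)
      expect_lt(max(abs(v - o)), 1e-9)
    }
  }
})

test_that("distribution function behaves as an integral of the density", {
  mp <- mixture_params(1.3, 1.3, 0.6, 0.6, P = 0.5)
  expect_equal(cdf_ssf_mix(0, mp), 0)
  s <- c(0.2, 0.5, 1, 2, 4)
  expect_equal(cdf_ssf_mix(s, mp), 1 - exp(-1.3 * s), tolerance = 1e-9)

  mp2 <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  v <- cdf_ssf_mix(s, mp2)
  expect_true(all(diff(v) > 0))
  # central differences of the cdf reproduce the density
  h <- 1e-4
  num <- (cdf_ssf_mix(s + h, mp2) - cdf_ssf_mix(s - h, mp2)) / (2 * h)
  expect_lt(max(abs(num / pdf_ssf_mix(s, mp2) - 1)), 1e-4)
})

test_that("closed-form mean step agrees with quadrature and known limits", {
  expect_equal(mean_step_mix(mixture_params(2, 2, 0.5, 0.7, P = 0.3)), 0.5)
  for (params in random_param_sets(8, seed = 77)) {
    quad <- integrate(function(x) x * pdf_ssf_mix(x, params), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(mean_step_mix(params), quad, tolerance = 1e-6)
  }
  # infinite-chord limit: mean of the two-exponential mixture
  mp0 <- mixture_params(1, 2, 1e-12, 1e-12, P = 0.3)
  expect_equal(mean_step_mix(mp0), 0.7 / 1 + 0.3 / 2, tolerance = 1e-9)
})

test_that("effective albedo is the occupation-weighted rate ratio", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.5)
  sp <- optical_split(mu_aa = 0.1, mu_sa = 0.9, mu_ab = 0.5, mu_sb = 1.5)
  expect_equal(albedo_mix(mp, sp), 0.8)
  mp_hom <- mixture_params(2, 2, 0.5, 0.7, P = 0.4)
  sp_hom <- optical_split(0.4, 1.6, 0.4, 1.6)
  expect_equal(albedo_mix(mp_hom, sp_hom), 1.6 / 2)
  mp_a <- mixture_params(1, 2, 0.5, 0.7, P = 0)
  expect_equal(albedo_mix(mp_a, sp), 0.9)
})

test_that("quantile table inverts the homogeneous exponential", {
  mp <- mixture_params(1, 1, 0.8, 0.8, P = 0.5)
  qt <- build_quantile_table(mp, table_size = 1024)
  expect_equal(qt$cdf[1], 0)
  expect_true(all(diff(qt$cdf) >= 0))
  expect_gte(attr(qt, "coverage"), 1 - 1e-8)
  xi <- seq(0.1, 0.9, by = 0.1)
  expect_lt(max(abs(quantile_ssf_mix(qt, xi) - (-log(1 - xi)))), 1e-4)
  expect_equal(quantile_ssf_mix(qt, 0), 0)
})

test_that("quantile and distribution function are mutually inverse", {
  for (params in random_param_sets(4, seed = 5)) {
    qt <- build_quantile_table(params, table_size = 1024)
    xi <- seq(0.05, 0.95, by = 0.09)
    s_xi <- quantile_ssf_mix(qt, xi)
    expect_true(all(diff(s_xi) > 0))
    back <- cdf_ssf_mix(s_xi, attr(qt, "params"))
    expect_lt(max(abs(back - xi)), 1e-5)
  }
})

test_that("quantile lookups beyond coverage raise a tail error", {
  mp <- mixture_params(1, 1, 0.8, 0.8, P = 0.5)
  qt <- build_quantile_table(mp, table_size = 256)
  expect_error(quantile_ssf_mix(qt, 1), class = "ssfmix_tail_error")
  expect_error(build_quantile_table(mp, table_size = 8), ">= 64")
})

test_that("interpolated distribution function tracks the quadrature one", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  qt <- build_quantile_table(mp, table_size = 4096)
  s <- seq(0.05, 6, by = 0.37)
  expect_lt(max(abs(cdf_ssf_interp(qt, s) - cdf_ssf_mix(s, mp))), 1e-4)
})

test_that("tabulated step function is consistent and mass-conserving", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  tab <- ssf_table(mp, n = 257)
  expect_s3_class(tab, "tbl_df")
  expect_equal(tab$pdf, pdf_ssf_mix(tab$s, mp))
  trapz <- sum(diff(tab$s) * (head(tab$pdf, -1) + tail(tab$pdf, -1)) / 2)
  expect_lt(abs(trapz - 1), 2e-3)  # 1e-6 tail target plus trapezoid error
  expect_true(all(diff(tab$cdf) >= 0))
  expect_equal(max(tab$cdf), 1, tolerance = 1e-5)
})

test_that("series diagnostics report truncation and neglected mass", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  d <- ssf_diagnostics(mp)
  expect_equal(d$start, c("a", "b"))
  expect_true(all(d$tail_bound < 1e-10))
  expect_true(all(d$neglected_mass <= d$tail_bound))
})
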