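test_that("direct simulation reproduces the homogeneous exponential mean", {
  hom <- mixture_params(1, 1, 0.6, 0.6, P = 0.5)
  n <- 1e5
  sim <- simulate_direct_steps(hom, n, seed = 101)
  expect_lt(abs(mean(sim$s) - 1), 3 / sqrt(n))
})

test_that("direct simulation matches the analytic mean step length", {
  for (params in validation_regimes()[c(1, 4)]) {
    n <- 1e5
    sim <- simulate_direct_steps(params, n, seed = 202)
    se <- sd(sim$s) / sqrt(n)
    expect_lt(abs(mean(sim$s) - mean_step_mix(params)), 4 * se)
  }
})

test_that("direct simulation is reproducible and seed-sensitive", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  a <- simulate_direct_steps(mp, 2000, seed = 9)
  b <- simulate_direct_steps(mp, 2000, seed = 9)
  c <- simulate_direct_steps(mp, 2000, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$s, c$s))
})

test_that("start types follow the strict xi < 1 - P rule", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.25)
  sim <- simulate_direct_steps(mp, 5000, seed = 4)
  set.seed(4L)
  xi <- runif(5000)
  expect_identical(sim$start_type, ifelse(xi < 0.75, "a", "b"))
})

test_that("tessel-crossing counts follow the jump-count pmf", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  n <- 2e5
  sim <- simulate_direct_steps(mp, n, seed = 303)
  for (st in c("a", "b")) {
    ns <- sim$n_tessels[sim$start_type == st]
    kmax <- 8
    obs <- c(tabulate(factor(pmin(ns, kmax) + 1, levels = 1:(kmax + 1))))
    probs <- pmf_jump_count(mp, 0:(kmax - 1), start = st)
    probs <- c(probs, 1 - sum(probs))
    ct <- suppressWarnings(chisq.test(obs, p = probs))
    expect_gt(ct$p.value, 0.01)
  }
})

test_that("interior starts see exponential residual chords (memorylessness)", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  res <- simulate_interior_start(mp, c(0.5, 10), n_reps = 2e4, seed = 404)
  for (sc in c(0.5, 10)) {
    for (ty in c("a", "b")) {
      ell <- res$ell[res$s_cte == sc & res$type == ty]
      rate <- if (ty == "a") mp$sigma_a else mp$sigma_b
      if (length(ell) > 50) {
        ks <- suppressWarnings(ks.test(ell, "pexp", rate))
        expect_gt(ks$p.value, 0.01)
      }
    }
  }
  # deeper points sit in later tessels
  m_small <- mean(res$n_tessels[res$s_cte == 0.5])
  m_large <- mean(res$n_tessels[res$s_cte == 10])
  expect_gt(m_large, m_small)
})

test_that("zero-depth interior start returns the full first chord", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  res <- simulate_interior_start(mp, 0, n_reps = 2e4, seed = 505)
  expect_true(all(res$n_tessels == 1L))
  expect_true(all(res$type == "a"))
  ks <- suppressWarnings(ks.test(res$ell, "pexp", mp$sigma_a))
  expect_gt(ks$p.value, 0.01)
})

test_that("look-up-table sampler reproduces the analytic distribution", {
  mp <- mixture_params(1, 2, 0.5, 0.7, P = 0.2)
  qt <- build_quantile_table(mp, table_size = 2048)
  sim <- simulate_equivalent_homogeneous(qt, 5e4, seed = 606)
  ks <- suppressWarnings(ks.test(sim$s, function(q) cdf_ssf_interp(qt, q)))
  expect_gt(ks$p.value, 0.01)
  # homogeneous table: indistinguishable from direct exponential sampling
  hom <- mixture_params(1, 1, 0.8, 0.8, P = 0.5)
  qth <- build_quantile_table(hom, table_size = 2048)
  simh <- simulate_equivalent_homogeneous(qth, 5e4, seed = 707)
  ksh <- suppressWarnings(ks.test(simh$s, "pexp", 1))
  expect_gt(ksh$p.value, 0.01)
  # determinism
  expect_identical(simulate_equivalent_homogeneous(qt, 1000, seed = 8),
                   simulate_equivalent_homogeneous(qt, 1000, seed = 8))
})

test_that("step histograms conserve probability mass", {
  h1 <- histogram_steps(c(0.25), bin_edges = c(0, 0.5))
  expect_equal(h1$density, 2)  # 1 / bin width
  set.seed(12)
  x <- rexp(5000, 1.7)
  h <- histogram_steps(tibble::tibble(s = x), seq(0, max(x) + 0.1, length.out = 33))
  expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1, tolerance = 1e-12)
  expect_error(histogram_steps(numeric(0), c(0, 1)), "no step records")
  expect_error(histogram_steps(x, c(1, 1)), "strictly increasing")
})
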