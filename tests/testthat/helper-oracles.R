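# Independent numerical oracles used across the suite. Both deliberately
# avoid the package's Bessel-series evaluation path: one builds the
# alternating-chord density by direct grid convolution of exponential
# factors, the other by the matrix exponential of the absorbing-chain
# generator.

# FFT-padded open convolution of two sampled functions (times h), with
# trapezoid end correction.
conv_open <- function(f, g, h) {
  n <- length(f)
  m <- stats::nextn(2L * n)
  fp <- c(f, numeric(m - n))
  gp <- c(g, numeric(m - n))
  full <- Re(stats::fft(stats::fft(fp) * stats::fft(gp), inverse = TRUE)) / m
  out <- full[1:n] * h - h * (f[1] * g + f * g[1]) / 2
  out[1] <- 0
  out
}

# Density of a sum of independent exponentials with the given rates,
# evaluated by iterated grid convolution with one Richardson step
# (h^2 error eliminated). `s_eval` should lie on multiples of `h`.
conv_chain_pdf <- function(s_eval, rates, h = 1 / 512) {
  L <- max(s_eval)
  one_pass <- function(hh) {
    x <- seq(0, L, by = hh)
    dens <- lapply(rates, function(r) r * exp(-r * x))
    f <- dens[[1]]
    if (length(rates) > 1) {
      for (k in 2:length(rates)) f <- conv_open(f, dens[[k]], hh)
    }
    stats::approx(x, f, xout = s_eval)$y
  }
  a <- one_pass(h)
  b <- one_pass(h / 2)
  (4 * b - a) / 3
}

# Alternating-material chain rates for a type-`start` first tessel.
chain_rates <- function(params, N, start = "a") {
  p <- if (start == "a") params else {
    mixture_params(params$mu_tb, params$mu_ta, params$sigma_b, params$sigma_a,
                   1 - params$P)
  }
  ifelse(seq_len(N) %% 2 == 1, p$r_a, p$r_b)
}

# Hypoexponential density via the matrix exponential of the bidiagonal
# absorbing-chain generator (requires Matrix).
expm_chain_pdf <- function(s_eval, rates) {
  N <- length(rates)
  Tm <- diag(-rates, N, N)
  if (N > 1) for (i in 1:(N - 1)) Tm[i, i + 1] <- rates[i]
  vapply(s_eval, function(si) {
    E <- as.matrix(Matrix::expm(Tm * si))
    E[1, N] * rates[N]
  }, numeric(1))
}

# Two-state absorbing-chain oracle for the full single-step density with a
# fixed start type: state 1 = inside material a, state 2 = inside material
# b; crossing moves between states, extinction absorbs.
phase_type_ssf_pdf <- function(s_eval, params, start = "a") {
  Tm <- matrix(c(-params$r_a, params$sigma_b,
                 params$sigma_a, -params$r_b), 2, 2)
  t0 <- c(params$mu_ta, params$mu_tb)
  alpha <- if (start == "a") c(1, 0) else c(0, 1)
  vapply(s_eval, function(si) {
    E <- as.matrix(Matrix::expm(Tm * si))
    sum(alpha %*% E * t0)
  }, numeric(1))
}

# Randomised but reproducible mixture parameter sets spanning negative,
# (near-)zero and positive rate contrast.
random_param_sets <- function(n, seed = 421) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    kind <- i %% 3
    mu_ta <- runif(1, 0.2, 3)
    sigma_a <- runif(1, 0.05, 2)
    if (kind == 0) {          # near-zero contrast
      mu_tb <- mu_ta
      sigma_b <- sigma_a
    } else if (kind == 1) {   # positive contrast
      mu_tb <- mu_ta + runif(1, 0.1, 2)
      sigma_b <- sigma_a + runif(1, 0.05, 1)
    } else {                  # negative contrast
      mu_tb <- max(0.05, mu_ta - runif(1, 0.1, 1.5))
      sigma_b <- max(0.02, sigma_a - runif(1, 0.02, 1))
    }
    mixture_params(mu_ta, mu_tb, sigma_a, sigma_b, P = runif(1))
  })
  out
}

# The four canonical validation regimes: positive, negative and zero rate
# contrast plus a strong optical contrast, with mixing P in {0.2, 0.5, 0.8}.
validation_regimes <- function() {
  list(
    mixture_params(1, 2, 0.5, 0.7, P = 0.2),
    mixture_params(2, 1, 0.7, 0.5, P = 0.8),
    mixture_params(1.3, 1.3, 0.6, 0.6, P = 0.5),
    mixture_params(0.2, 3, 2, 0.1, P = 0.5)
  )
}
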