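# quadrature oracle: Gaussian x exponential convolution integral
emg_quadrature <- function(t, tau, sigma, delta = 0) {
  stats::integrate(function(s) stats::dnorm(t - s, delta, sigma) *
                     exp(-s / tau) / tau,
                   0, Inf, rel.tol = 1e-12, abs.tol = 1e-300)$value
}

test_that("emg_density matches the convolution quadrature oracle", {
  for (tau in c(0.125, 0.388, 2.5)) {
    for (sigma in c(0.05, 0.1, 0.2)) {
      ts <- seq(-2, 8, length.out = 100)
      want <- vapply(ts, emg_quadrature, numeric(1), tau = tau, sigma = sigma)
      got <- emg_density(ts, tau, sigma)
      keep <- want > 1e-12   # above quadrature underflow
      expect_true(all(abs(got[keep] - want[keep]) / want[keep] <= 1e-8))
    }
  }
})

test_that("emg_density has the right limits and normalization", {
  # sigma -> 0 limit is the pure exponential
  expect_equal(emg_density(1, 1, 1e-6), exp(-1), tolerance = 1e-4)
  expect_equal(emg_density(0.5, 2, 1e-7, delta = 0.1),
               exp(-0.4 / 2) / 2, tolerance = 1e-4)
  # unit mass (split at 2 ns so quadrature resolves the sharp peak)
  for (tau in c(0.125, 2.5)) {
    z <- stats::integrate(function(t) emg_density(t, tau, 0.12), -20, 2,
                          rel.tol = 1e-10)$value +
      stats::integrate(function(t) emg_density(t, tau, 0.12), 2, 200,
                       rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-8)
  }
  expect_error(emg_density(0, -1, 0.1), "tau")
  expect_error(emg_density(0, 1, 0), "sigma")
})

test_that("emg_density stays finite in extreme regimes", {
  ts <- seq(-50, 50, length.out = 401)
  for (tau in c(0.01, 0.125, 2.5, 10)) {
    for (sigma in c(tau * 1e-3, tau, tau * 10)) {
      v <- emg_density(ts, tau, sigma)
      expect_true(all(is.finite(v)))
      expect_true(all(v >= 0))
    }
  }
})

test_that("mixture density keeps unit mass for any simplex point", {
  set.seed(41)
  for (r in 1:5) {
    g <- stats::rgamma(3, c(0.75, 3.1, 1.15))
    br <- g / sum(g)
    p <- lifetime_params(tau3 = stats::runif(1, 1.8, 2.6), br = br,
                         sigma = 0.12, delta = 0, n_total = 1, b = 0)
    z <- stats::integrate(function(t) {
      br[1] * emg_density(t, p$tau1, p$sigma) +
        br[2] * emg_density(t, p$tau2, p$sigma) +
        br[3] * emg_density(t, p$tau3, p$sigma)
    }, -20, 300, rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-7)
  }
})

test_that("model expectation reduces to the background at N = 0 and is monotone", {
  h <- build_tdd(sample_tdd_direct(1.82, t4_br(), n_signal = 2e4,
                                   n_background = 2e3, seed = 42))
  h <- estimate_background(h)
  p0 <- lifetime_params(1.82, t4_br(), 0.12, 0, n_total = 0, b = h$b)
  mu0 <- model_expectation(h, p0)
  expect_true(all(mu0 == h$b))
  # bin-wise monotone in N and in b
  p1 <- lifetime_params(1.82, t4_br(), 0.12, 0, n_total = 1e4, b = h$b)
  p2 <- lifetime_params(1.82, t4_br(), 0.12, 0, n_total = 2e4, b = h$b)
  p3 <- lifetime_params(1.82, t4_br(), 0.12, 0, n_total = 1e4, b = h$b + 1)
  expect_true(all(model_expectation(h, p2) >= model_expectation(h, p1)))
  expect_true(all(model_expectation(h, p3) > model_expectation(h, p1)))
  expect_error(model_expectation(h, p1, fit_range = c(-10, 8)), "support")
})

test_that("summed expectation recovers the total count", {
  # over a range enclosing essentially all density, sum(mu - b) ~= N
  h <- build_tdd(numeric(0), range = c(-10, 60))
  h$b <- 2
  p <- lifetime_params(2.5, c(0.1, 0.6, 0.3), 0.12, 0, n_total = 1e5, b = 2)
  mu <- model_expectation(h, p, fit_range = c(-10, 60))
  expect_equal(sum(mu - 2), 1e5, tolerance = 5e-3)
})

test_that("log-space tail slope recovers tau3", {
  h <- build_tdd(numeric(0))
  h$b <- 0
  p <- lifetime_params(2.2, c(0, 1e-12, 1 - 1e-12), 0.1, 0,
                       n_total = 1e6, b = 0)
  mu <- model_expectation(h, p)
  ctr <- attr(mu, "centers")
  keep <- ctr > 1 & ctr < 7
  fit <- stats::lm(log(mu[keep]) ~ ctr[keep])
  expect_equal(-1 / stats::coef(fit)[[2]], 2.2, tolerance = 0.01)
})

test_that("midpoint and bin-integral expectations agree where tau3 lives", {
  # the midpoint rule is only approximate on the steep Gaussian rise
  # (absorbed by the free sigma and delta); in the exponential tail that
  # determines tau3 the two quadratures coincide
  h <- build_tdd(numeric(0))
  h$b <- 1
  p <- lifetime_params(1.82, t4_br(), 0.12, 0, n_total = 1e5, b = 1)
  a <- model_expectation(h, p, method = "midpoint")
  b <- model_expectation(h, p, method = "integral")
  ctr <- attr(a, "centers")
  # bin-curvature bound: (w^2/24)/tau^2 per component; the slow tau3
  # exponential contributes ~2e-4, the direct component a few 1e-3 while
  # it still matters near t ~ 1 ns
  tail_reg <- ctr > 1
  expect_lt(max(abs(a[tail_reg] - b[tail_reg]) / b[tail_reg]), 5e-3)
  deep_tail <- ctr > 4
  expect_lt(max(abs(a[deep_tail] - b[deep_tail]) / b[deep_tail]), 5e-4)
  # both conserve total counts to well under a percent
  expect_lt(abs(sum(a - 1) - sum(b - 1)) / sum(b - 1), 2e-3)
})

test_that("compute_A is the background-subtracted fit-range sum", {
  h <- build_tdd(numeric(0), range = c(-3, 8))
  h$counts[] <- 5L
  h$b <- 5
  a0 <- compute_A(h, fit_range = c(-2, 8))
  expect_equal(as.numeric(a0), 0)
  expect_false(attr(a0, "fittable"))
  h$counts[h$centers >= -2] <- h$counts[h$centers >= -2] + 2L
  nfit <- sum(h$centers >= -2 & h$centers <= 8)
  expect_equal(as.numeric(compute_A(h)), 2 * nfit)
  # Poisson propagation on a simulated voxel
  set.seed(43)
  n_sig <- 2000
  x <- sample_tdd_direct(1.82, t4_br(), sigma = 0.12, n_signal = n_sig,
                         n_background = 970)
  hh <- estimate_background(build_tdd(x))
  A <- as.numeric(compute_A(hh))
  n_sig_fit <- n_sig * 0.995   # tiny loss below -2 ns / above 7.9 ns
  expect_lt(abs(A - n_sig_fit), 3 * sqrt(sum(hh$counts)))
})

test_that("log posterior behaves as an MCMC target", {
  x <- sample_tdd_direct(1.82, t4_br(), sigma = 0.12, n_signal = 2e4,
                         n_background = 2200, seed = 44)
  h <- estimate_background(build_tdd(x))
  p <- lifetime_params(1.82, t4_br(), 0.12, 0,
                       n_total = as.numeric(compute_A(h)), b = h$b)
  lp <- log_posterior(p, h)
  expect_true(is.finite(lp))
  # invalid states give -Inf, not an error
  bad <- p
  bad$tau3 <- -1
  expect_identical(log_posterior(bad, h), -Inf)
  # zero-residual data: posterior = prior + Gaussian normalization terms
  mu <- model_expectation(h, p)
  h2 <- h
  keep <- which(h$centers >= -2 & h$centers <= 8)
  h2$counts[keep] <- mu
  A2 <- as.numeric(compute_A(h2))
  want <- pslife:::log_prior(p$tau3, p$br, p$sigma, p$delta, p$n_total,
                             prior_spec(), A2) -
    0.5 * sum(log(2 * pi * pmax(mu, 1)))
  expect_equal(log_posterior(p, h2), want, tolerance = 1e-8)
})

test_that("the Dirichlet prior has the printed mean", {
  a <- prior_spec()$alpha
  expect_equal(a / sum(a), c(0.15, 0.62, 0.23), tolerance = 1e-12)
  expect_equal(sum(a), 5)
})
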