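test_that("NB mass matches closed forms and normalizes", {
  # mu = theta = 1 is geometric with mass 0.5^(y+1)
  expect_equal(nb_pmf(0, mu = 1, theta = 1), 0.5)
  expect_equal(nb_pmf(0:5, mu = 1, theta = 1), 0.5^(1:6))
  expect_equal(sum(nb_pmf(0:2000, mu = 3, theta = 2)), 1,
               tolerance = 1e-10)
  # Poisson limit
  expect_equal(nb_pmf(3, mu = 2, theta = 1e6), dpois(3, 2),
               tolerance = 1e-4)
  expect_equal(nb_pmf(3, mu = 2, theta = Inf), dpois(3, 2))
  expect_error(nb_pmf(-1, 1, 1), "non-negative integer")
  expect_error(nb_pmf(1.5, 1, 1), "non-negative integer")
  expect_error(nb_pmf(1, -1, 1), "positive")
})

test_that("truncated NB mass renormalizes on its support", {
  expect_equal(tnb_pmf(1, mu = 1, theta = 1, t = 0), 0.5)
  expect_error(tnb_pmf(0, mu = 1, theta = 1, t = 0), "support")
  expect_equal(sum(tnb_pmf(3:2000, mu = 3, theta = 2, t = 2)), 1,
               tolerance = 1e-10)
  # t = -1 recovers the untruncated mass
  expect_equal(tnb_pmf(4, mu = 2, theta = 3, t = -1),
               nb_pmf(4, mu = 2, theta = 3))
})

test_that("truncated NB normalization holds across the parameter box", {
  set.seed(42)
  for (i in 1:25) {
    mu <- runif(1, 0.01, 100)
    theta <- runif(1, 0.1, 100)
    t <- sample(0:5, 1)
    s <- sum(tnb_pmf((t + 1):4000, mu, theta, t))
    expect_equal(s, 1, tolerance = 1e-8,
                 label = sprintf("sum at mu=%.3f theta=%.3f t=%d",
                                 mu, theta, t))
  }
})

test_that("saturated mean maximizes the truncated likelihood", {
  # untruncated: maximizer is the observation itself
  expect_equal(saturated_mu(c(1, 5, 50), theta = 2, t = -1), c(1, 5, 50))
  # zero-truncated y = 1: likelihood increases towards mu = 0 (boundary)
  expect_equal(saturated_mu(1, theta = 1, t = 0), 1e-8)
  # far from the truncation point the correction is negligible
  expect_equal(saturated_mu(50, theta = 5, t = 0), 50, tolerance = 0.01)
  # grid-search oracle agreement at interior solutions
  for (case in list(c(3, 2, 0), c(7, 1, 2), c(12, 5, 3))) {
    got <- saturated_mu(case[1], case[2], case[3])
    want <- oracle_saturated_mu(case[1], case[2], case[3])
    expect_equal(got, want, tolerance = 1e-3)
  }
  expect_error(saturated_mu(2, theta = 1, t = 2), "exceed")
})

test_that("deviance residuals are signed likelihood gaps", {
  # fitted mean equal to the saturated mean gives a zero residual
  ms <- saturated_mu(10, theta = 2, t = 0)
  expect_equal(deviance_residual(10, ms, theta = 2, t = 0), 0,
               tolerance = 1e-6)
  expect_gt(deviance_residual(12, 3, theta = 2, t = 0), 0)
  expect_lt(deviance_residual(1, 3, theta = 2, t = 0), 0)
  # direct recomputation from the truncated mass
  y <- 12; mu_hat <- 3; th <- 2; t <- 0
  ms <- saturated_mu(y, th, t)
  want <- sign(y - mu_hat) *
    sqrt(2 * abs(tnb_pmf(y, ms, th, t, log = TRUE) -
                   tnb_pmf(y, mu_hat, th, t, log = TRUE)))
  expect_equal(deviance_residual(y, mu_hat, th, t), want)
})

test_that("NB upper tails agree with exhaustive summation", {
  expect_equal(nb_tail_prob(0, mu = 5, theta = 2), 1)
  expect_equal(nb_tail_prob(10, mu = 1.09),
               sum(dpois(10:1000, 1.09)), tolerance = 1e-12)
  expect_equal(nb_tail_prob(10, mu = 3, theta = 2),
               sum(dnbinom(10:5000, size = 2, mu = 3)), tolerance = 1e-12)
  # tail probability below the observed count increases with the mean
  mus <- seq(0.5, 9, by = 0.5)
  tails <- vapply(mus, function(m) nb_tail_prob(10, m), numeric(1))
  expect_true(all(diff(tails) > 0))
})
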