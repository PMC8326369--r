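test_that("gradient scaling maps the survey range onto [0, 1]", {
  expect_equal(scale_gradient(c(3.63, 8.75), 3.63, 8.75), c(0, 1))
  expect_equal(scale_gradient(6.19, 3.63, 8.75), 0.5)
  expect_equal(scale_gradient(2.63, 3.63, 8.75), -1 / 5.12)
  expect_equal(unscale_gradient(scale_gradient(5.5, 3.63, 8.75), 3.63, 8.75),
               5.5)
  expect_error(scale_gradient(5, 7, 7), "exceed")
})

test_that("HOF shapes evaluate as products of logistic terms", {
  g <- function(t) 1 / (1 + exp(t))
  expect_equal(hof_response(c(0, 0.3, 1), "I", c(a = 0), M = 10),
               rep(5, 3))
  # II with b = 0 equals I at the same a
  x <- seq(0, 1, 0.1)
  expect_equal(hof_response(x, "II", c(a = 1.3, b = 0), M = 7),
               hof_response(x, "I", c(a = 1.3), M = 7))
  # IV at x = 0.5: brute-force product of the two logistic terms
  expect_equal(hof_response(0.5, "IV", c(a = -2, b = 4, c = 2), M = 1),
               g(-2 + 4 * 0.5) * g(2 - 4 * 0.5))
  # V nests IV at d = b and III at d = 0
  expect_equal(hof_response(x, "V", c(a = -1, b = 6, c = 2, d = 6), M = 3),
               hof_response(x, "IV", c(a = -1, b = 6, c = 2), M = 3))
  expect_equal(hof_response(x, "V", c(a = -1, b = 6, c = 2, d = 0), M = 3),
               hof_response(x, "III", c(a = -1, b = 6, c = 2), M = 3))
  expect_error(hof_response(x, "IV", c(a = -2, b = NA, c = 1), M = 1),
               "non-finite")
})

test_that("responses stay within [0, M] across random parameters", {
  set.seed(11)
  x <- seq(-0.2, 1.2, length.out = 101) # includes affine extension
  for (i in 1:50) {
    type <- sample(c("II", "III", "IV", "V"), 1)
    p <- c(a = runif(1, -50, 50), b = runif(1, 0, 200),
           c = runif(1, -50, 50), d = runif(1, 0, 200))
    M <- exp(runif(1, 0, 6))
    mu <- hof_response(x, type, p, M)
    expect_true(all(mu >= 0 & mu <= M))
  }
})

test_that("poisson_nll equals the summed negative log pmf", {
  expect_equal(poisson_nll(1L, 1), 1.0)
  expect_equal(poisson_nll(0L, 2), 2.0)
  expect_equal(poisson_nll(2L, 2), -dpois(2, 2, log = TRUE))
  set.seed(3)
  y <- rpois(40, 6)
  mu <- runif(40, 0.5, 12)
  expect_equal(poisson_nll(y, mu), -sum(dpois(y, mu, log = TRUE)))
  expect_error(poisson_nll(c(-1L), 1), "non-negative")
  expect_error(poisson_nll(1:3, 1:2), "length")
})

test_that("a flat fit recovers the sample mean (Poisson MLE)", {
  sim <- sim_counts("I", c(a = 0), M = 20, n = 500, seed = 5)
  fit <- fit_single_model(sim$counts, sim$ph, "I")
  mu_hat <- hof_response(0.5, "I", fit$params["a"], fit$M)
  expect_equal(mu_hat, mean(sim$counts), tolerance = 1e-6)
  expect_lt(abs(mu_hat - 10) / 10, 0.05)
  expect_equal(fit$AIC, 2 * 1 - 2 * fit$logLik, tolerance = 1e-9)
})

test_that("single-model fits honour preconditions", {
  expect_error(fit_single_model(rep(0L, 50), runif(50, 4, 8), "II"),
               "all zero")
  expect_error(fit_single_model(c(1L, 2L), c(4, 5), "V"), "at least")
  expect_error(fit_single_model(1:3, c(4, 5), "II"), "length")
})

test_that("both gradient orientations are reachable for monotone shapes", {
  # increasing response toward high pH needs the reversed gradient with b >= 0
  sim <- sim_counts("II", c(a = -1, b = 8), M = 40, n = 400, seed = 8,
                    rev = TRUE)
  fit <- fit_single_model(sim$counts, sim$ph, "II",
                          gradient_range = c(3.63, 8.75))
  expect_true(fit$rev)
  resp_lo <- hof_response(if (fit$rev) 1 else 0, "II",
                          fit$params[c("a", "b")], fit$M)
  resp_hi <- hof_response(if (fit$rev) 0 else 1, "II",
                          fit$params[c("a", "b")], fit$M)
  expect_gt(resp_hi, resp_lo)
})

test_that("log-likelihood is monotone along the nesting hierarchy", {
  set.seed(21)
  for (i in 1:12) {
    type <- sample(c("I", "II", "III", "IV", "V"), 1)
    p <- switch(type,
      I = c(a = runif(1, -3, 1)),
      II = c(a = runif(1, -5, 2), b = runif(1, 2, 30)),
      III = c(a = runif(1, -5, 2), b = runif(1, 2, 30), c = runif(1, -2, 2)),
      IV = c(a = runif(1, -8, 0), b = runif(1, 4, 30), c = runif(1, -2, 4)),
      V = c(a = runif(1, -8, 0), b = runif(1, 4, 30), c = runif(1, -2, 4),
            d = runif(1, 4, 30)))
    sim <- sim_counts(type, p, M = exp(runif(1, log(10), log(200))), n = 200,
                      seed = 100 + i)
    if (all(sim$counts == 0)) next
    cand <- hof_fit(sim$counts, sim$ph, n_boot = 0,
                    gradient_range = c(3.63, 8.75))$candidates
    ll <- setNames(cand$logLik, cand$model_type)
    expect_gte(ll["II"], ll["I"] - 1e-6)
    expect_gte(ll["III"], ll["II"] - 1e-6)
    expect_gte(ll["V"], ll["III"] - 1e-6)
    expect_gte(ll["V"], ll["IV"] - 1e-6)
  }
})

test_that("AIC selection takes the minimum with parsimony tie-breaks", {
  cand <- function(type, aic) {
    k <- c(I = 1, II = 2, III = 3, IV = 3, V = 4)[[type]]
    list(model_type = type, k = k, AIC = aic)
  }
  expect_equal(select_model(list(II = cand("II", 100), V = cand("V", 98))),
               "V")
  expect_equal(select_model(list(IV = cand("IV", 50))), "IV")
  expect_equal(select_model(list(III = cand("III", 100), V = cand("V", 100))),
               "III")
})
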