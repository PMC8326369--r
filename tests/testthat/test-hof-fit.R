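test_that("bootstrap vote overrides the AIC choice only when modes differ", {
  tally <- function(...) {
    t <- setNames(integer(5), c("I", "II", "III", "IV", "V"))
    v <- c(...)
    t[names(v)] <- v
    t
  }
  resolve <- ecohof:::resolve_boot_choice
  expect_equal(resolve("V", tally(IV = 60, V = 40)), "IV")
  expect_equal(resolve("II", tally(II = 90, III = 10)), "II")
  expect_equal(resolve("V", tally(IV = 50, V = 50)), "IV") # tie -> fewer k
  expect_equal(resolve("III", tally()), "III") # no successful resamples
})

test_that("full fits are deterministic given a seed and tally to n_boot", {
  sim <- sim_counts("V", c(a = -4, b = 12, c = 3, d = 25), M = 80,
                    n = 250, seed = 13)
  f1 <- hof_fit(sim$counts, sim$ph, n_boot = 30, seed = 7,
                gradient_range = c(3.63, 8.75))
  f2 <- hof_fit(sim$counts, sim$ph, n_boot = 30, seed = 7,
                gradient_range = c(3.63, 8.75))
  expect_identical(f1[names(f1) != "data"], f2[names(f2) != "data"])
  expect_equal(sum(f1$bootstrap_tally) + f1$n_boot_failed, 30L)
  expect_equal(f1$AIC, 2 * f1$k - 2 * f1$logLik, tolerance = 1e-9)
  expect_true(all(f1$optima_pH >= 3.63 & f1$optima_pH <= 8.75))
})

test_that("optima: IV closed form, II boundary, III plateau edges", {
  mk <- function(type, params, rev = FALSE, rng = c(3.63, 8.75))
    list(model_type = type, params = params, rev = rev, M = 1,
         gradient_range = rng)

  # closed form x* = (c - a) / (2b) for symmetric unimodal fits
  expect_equal(extract_optima(mk("IV", c(a = -2, b = 4, c = 2))),
               unscale_gradient(0.5, 3.63, 8.75), tolerance = 1e-6)
  set.seed(31)
  for (i in 1:25) {
    a <- runif(1, -8, 2); b <- runif(1, 3, 40)
    c_ <- a + runif(1, 0.2, 1.8) * b # interior optimum
    x_star <- (c_ - a) / (2 * b)
    if (x_star <= 0 || x_star >= 1) next
    got <- extract_optima(mk("IV", c(a = a, b = b, c = c_)))
    expect_lt(abs(scale_gradient(got, 3.63, 8.75) - x_star), 2e-3)
  }
  # symmetry: c = a + b puts the optimum mid-gradient
  expect_equal(scale_gradient(
    extract_optima(mk("IV", c(a = -3, b = 10, c = 7))), 3.63, 8.75),
    0.5, tolerance = 2e-3)

  # II: endpoint with the higher response
  expect_equal(extract_optima(mk("II", c(a = 0, b = 5))), 3.63) # decreasing
  expect_equal(extract_optima(mk("II", c(a = 0, b = 5), rev = TRUE)), 8.75)

  # I: flat, no optimum
  expect_length(extract_optima(mk("I", c(a = 0))), 0)

  # III: two pH values bounding the 95%-of-maximum plateau
  opt3 <- extract_optima(mk("III", c(a = -20, b = 30, c = 0)))
  expect_length(opt3, 2)
  expect_true(opt3[1] < opt3[2])
  resp_at <- function(ph) hof_response(
    scale_gradient(ph, 3.63, 8.75), "III", c(a = -20, b = 30, c = 0), 1)
  peak <- resp_at(3.63)
  expect_gte(resp_at(opt3[2]), 0.949 * peak)
  expect_lt(resp_at(opt3[2] + 0.06), 0.95 * peak)
})

test_that("hof_fit recovers a strongly unimodal truth and its optimum", {
  truth_opt <- unscale_gradient((6 - -6) / (2 * 14), 3.63, 8.75)
  sim <- sim_counts("IV", c(a = -6, b = 14, c = 6), M = 120, n = 400,
                    seed = 17)
  fit <- hof_fit(sim$counts, sim$ph, n_boot = 50, seed = 3,
                 gradient_range = c(3.63, 8.75))
  expect_true(fit$model_type %in% c("IV", "V"))
  expect_lt(abs(fit$optima_pH[1] - truth_opt), 0.25)
})

test_that("model object methods behave like classic fitted models", {
  sim <- sim_counts("II", c(a = -2, b = 6), M = 50, n = 150, seed = 23)
  fit <- hof_fit(sim$counts, sim$ph, n_boot = 0, otu_id = "OTU_a",
                 gradient_range = c(3.63, 8.75))
  expect_s3_class(fit, "hof_fit")
  expect_named(coef(fit), c("a", "b"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), fit$k)
  expect_equal(AIC(fit), fit$AIC)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(length(residuals(fit)), 150)
  expect_warning(predict(fit, 9.4), "extrapolating")
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(150L, 3L))
  expect_true(all(sims >= 0 & sims == round(sims)))
  expect_output(print(fit), "HOF fit for 'OTU_a'")
  expect_output(print(summary(fit)), "Candidate shapes")
})

test_that("table-level fitting is keyed by OTU and independent of order", {
  truths <- generate_truths(c(1, 1, 0, 1, 0), strong_signal = TRUE, seed = 2)
  samples <- generate_gradient(150, seed = 3)
  tab <- generate_community(samples, truths, seed = 4)
  fits <- hof_fit_table(tab, n_boot = 10, seed = 5)
  df <- as.data.frame(fits)
  expect_equal(df$otu_id, rownames(tab$counts))
  expect_equal(df$boot_I + df$boot_II + df$boot_III + df$boot_IV + df$boot_V +
                 df$n_boot_failed, rep(10L, nrow(df)))
  # per-OTU derived seeds: fitting a subset reproduces the same rows
  sub <- tab
  sub$counts <- tab$counts[2, , drop = FALSE]
  fit_sub <- hof_fit_table(sub, n_boot = 10, seed = 5)
  expect_equal(as.data.frame(fit_sub), df[2, ], ignore_attr = TRUE)
})
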