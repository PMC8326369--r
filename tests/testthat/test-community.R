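test_that("bray_curtis matches hand computation on a toy matrix", {
  m <- cbind(s1 = c(2, 0, 4), s2 = c(2, 0, 4), s3 = c(0, 3, 0))
  d <- bray_curtis(m, renormalize = FALSE)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1) # disjoint support
  expect_equal(d, t(d))

  m2 <- cbind(a = c(1, 3), b = c(2, 2))
  # by hand: (|1-2| + |3-2|) / (1+2+3+2) = 2/8
  expect_equal(bray_curtis(m2, renormalize = FALSE)["a", "b"], 0.25)
  # renormalized: columns (0.25, 0.75) vs (0.5, 0.5) -> 0.5/2 = 0.25
  expect_equal(bray_curtis(m2)["a", "b"], 0.25)
  expect_error(bray_curtis(cbind(c(-1, 2), c(1, 1))), "negative")
  expect_error(bray_curtis(cbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("nmds recovers a line and handles duplicated samples", {
  pos <- c(0, 1, 2.2, 3.9, 7, 10)
  d <- as.matrix(dist(pos))
  dimnames(d) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  fit <- nmds(d, k = 1, n_restarts = 10, seed = 3)
  expect_lt(fit$stress, 0.01)
  expect_true(all(diff(order(fit$points[, 1])) == 1) ||
              all(diff(order(-fit$points[, 1])) == 1))

  # duplicated sample -> identical scores
  pos2 <- c(0, 1, 1, 4, 6)
  d2 <- as.matrix(dist(pos2))
  fit2 <- nmds(d2, k = 2, n_restarts = 10, seed = 4)
  expect_lt(max(abs(fit2$points[2, ] - fit2$points[3, ])), 1e-4)

  # stress non-increasing in k
  set.seed(6)
  dr <- as.matrix(dist(matrix(runif(24), ncol = 3)))
  s1 <- nmds(dr, k = 1, n_restarts = 10, seed = 5)$stress
  s2 <- nmds(dr, k = 2, n_restarts = 10, seed = 5)$stress
  expect_lte(s2, s1 + 1e-8)
  expect_error(nmds(matrix(0, 3, 3)), "zero")
  # determinism
  expect_identical(nmds(dr, k = 2, n_restarts = 5, seed = 11)$points,
                   nmds(dr, k = 2, n_restarts = 5, seed = 11)$points)
})

test_that("axis1_agreement is reflection-invariant", {
  x <- c(-2, 0.5, 1, 3, 4)
  expect_equal(axis1_agreement(x, x), 1)
  expect_equal(axis1_agreement(x, -x), 1)
  expect_equal(axis1_agreement(x, 3 - 2 * x), 1)
  y <- c(1, -1, 2, 0, 5)
  expect_equal(axis1_agreement(x, y), cor(x, y)^2)
  expect_error(axis1_agreement(x, y[1:3]), "length")
  expect_error(axis1_agreement(x[1:2], y[1:2]), "at least 3")
})

test_that("predictions follow the fitted curve shapes", {
  # flat fit predicts the same value everywhere (constant data cannot be
  # improved on by any shape, so parsimony picks type I)
  set.seed(41)
  ph_flat <- runif(200, 3.63, 8.75)
  flat <- hof_fit(rep(15L, 200), ph_flat, n_boot = 0,
                  gradient_range = c(3.63, 8.75))
  expect_equal(flat$model_type, "I")
  expect_equal(predict_abundance(flat, 4, 10000),
               predict_abundance(flat, 8, 10000))

  # decreasing monotone: higher prediction at the acid end
  sim2 <- sim_counts("II", c(a = -3, b = 10), M = 60, n = 300, seed = 42)
  mono <- hof_fit(sim2$counts, sim2$ph, n_boot = 0,
                  gradient_range = c(3.63, 8.75))
  expect_gt(predict_abundance(mono, 3.7, 1e4),
            predict_abundance(mono, 8.7, 1e4))

  # unimodal: optimum beats any other pH on a grid
  sim3 <- sim_counts("IV", c(a = -5, b = 12, c = 5), M = 90, n = 300,
                     seed = 43)
  uni <- hof_fit(sim3$counts, sim3$ph, n_boot = 0,
                 gradient_range = c(3.63, 8.75))
  if (uni$model_type %in% c("IV", "V")) {
    at_opt <- predict_abundance(uni, uni$optima_pH[1], 1e4)
    grid <- predict_abundance(uni, seq(3.63, 8.75, by = 0.05), 1e4)
    expect_gte(at_opt, max(grid) - 1e-9)
  }
})

test_that("predicted community matrices track the noiseless truth", {
  truths <- generate_truths(c(0, 2, 2, 3, 3), strong_signal = TRUE, seed = 51)
  samples <- generate_gradient(250, seed = 52)
  tab <- generate_community(samples, truths, seed = 53)
  fits <- hof_fit_table(tab, n_boot = 0, seed = 54)
  shared <- setNames(rownames(tab$counts), rownames(tab$counts))
  pc <- predict_community(fits, shared, tab$samples, ref_median_depth = 1e4)
  expect_s3_class(pc, "predicted_community")
  expect_equal(dim(pc$predicted), c(10L, 250L))
  expect_true(all(pc$predicted >= 0))

  mu <- synthetic_mu(truths, samples)
  cors <- vapply(seq_len(nrow(mu)), function(i)
    cor(pc$predicted[i, ], mu[i, ]), numeric(1))
  expect_true(all(cors >= 0.9))

  expect_error(predict_community(fits, c(qx = "missing_ref"), tab$samples,
                                 1e4), "no finalized fit")
})

test_that("top_matched_otus ranks by abundance then filters to hits", {
  counts <- rbind(q1 = c(50, 50), q2 = c(400, 400), q3 = c(30, 30),
                  q4 = c(200, 200))
  tab <- toy_table(counts, ph = c(5, 7))
  best <- data.frame(qseqid = c("q1", "q4", "q3"),
                     sseqid = c("r1", "r4", "r3"))
  sel <- top_matched_otus(tab, best, n = 2)
  expect_equal(names(sel), c("q4", "q1")) # q2 unmatched, q4 most abundant
  expect_equal(unname(sel), c("r4", "r1"))
})
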