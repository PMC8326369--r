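test_that("samples land in pH bands with the shared boundary convention", {
  meta <- toy_metadata(sprintf("s%d", 1:5), ph = c(4.0, 5.2, 6.3, 7.0, 7.5))
  g <- assign_ph_groups(meta)
  expect_equal(unname(g), c("acid", "mid", "mid", "mid", "neutral"))
  expect_equal(names(g), meta$sample_id)
})

test_that("indval equals exhaustive hand computation on a toy table", {
  # 6 samples, two pH groups (3 acid-band, 3 neutral-band)
  counts <- rbind(
    only_acid = c(5, 3, 4, 0, 0, 0),
    shared    = c(2, 2, 2, 2, 2, 2),
    skewed    = c(8, 0, 2, 1, 0, 0))
  ph <- c(4.1, 4.5, 4.9, 7.2, 7.6, 8.0)
  tab <- toy_table(counts, ph = ph)
  groups <- assign_ph_groups(tab)
  res <- indval(tab, groups)

  # independent brute-force computation of A, B and indval
  rel <- sweep(counts, 2, colSums(counts), "/")
  for (i in 1:3) {
    m_acid <- mean(rel[i, 1:3]); m_neut <- mean(rel[i, 4:6])
    A <- c(acid = m_acid, neutral = m_neut) / (m_acid + m_neut)
    B <- c(acid = mean(counts[i, 1:3] > 0), neutral = mean(counts[i, 4:6] > 0))
    expect_equal(res$A[i, c("acid", "neutral")], A, tolerance = 1e-12)
    expect_equal(res$B[i, c("acid", "neutral")], B, tolerance = 1e-12)
    expect_equal(res$indval[i, c("acid", "neutral")], 100 * A * B,
                 tolerance = 1e-12)
  }
  expect_equal(res$best$indval, 100 * res$best$A * res$best$B,
               tolerance = 1e-9)

  # perfect single-group indicator scores 100 in its group
  expect_equal(res$indval["only_acid", "acid"], 100)
  expect_equal(res$best$group[1], "acid")
  # specificity normalization
  expect_equal(unname(rowSums(res$A)), rep(1, 3))

  # equal mean relative abundance + full occupancy in both groups -> 50 each
  # (equal depths so relative and raw abundances are proportional)
  eq <- toy_table(rbind(shared = rep(2, 6), other = rep(3, 6)),
                  ph = ph)
  res_eq <- indval(eq, assign_ph_groups(eq))
  expect_equal(unname(res_eq$indval["shared", ]), c(50, 50))
  expect_equal(unname(res_eq$indval["other", ]), c(50, 50))
})

test_that("indval is invariant to relabeling samples within groups", {
  set.seed(9)
  counts <- matrix(rpois(8 * 12, 3), nrow = 8)
  ph <- rep(c(4.2, 7.5), each = 6)
  tab <- toy_table(counts, ph = ph)
  res1 <- indval(tab, assign_ph_groups(tab))
  perm <- c(sample(1:6), sample(7:12)) # shuffle within bands
  tab2 <- toy_table(counts[, perm], ph = ph[perm])
  res2 <- indval(tab2, assign_ph_groups(tab2))
  expect_equal(res1$indval, res2$indval, tolerance = 1e-12)
})

test_that("permutation p-values separate signal from noise", {
  # perfect indicator of the acid band, 6 + 6 balanced groups: only the
  # label permutations reproducing the split (2 of choose(12, 6)) can
  # reach the observed statistic
  counts <- rbind(
    perfect = c(9, 7, 8, 6, 9, 8, 0, 0, 0, 0, 0, 0),
    background = rep(5L, 12))
  ph <- rep(c(4.2, 7.5), each = 6)
  tab <- toy_table(counts, ph = ph)
  groups <- assign_ph_groups(tab)
  p <- indval_permutation_test(tab, groups, n_perm = 999, seed = 6)
  expect_lte(p[["perfect"]], 0.01)
  expect_true(all(p > 0 & p <= 1))
  # deterministic under seed
  p2 <- indval_permutation_test(tab, groups, n_perm = 999, seed = 6)
  expect_identical(p, p2)

  # an OTU identical across all samples (in a table of constant columns)
  # has a permutation-invariant statistic, so p = 1 exactly
  const <- toy_table(rbind(flat1 = rep(4L, 12), flat2 = rep(7L, 12)),
                     ph = ph)
  p_const <- indval_permutation_test(const, assign_ph_groups(const),
                                     n_perm = 199, seed = 7)
  expect_equal(unname(p_const), c(1, 1))
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(12)
  n_samp <- 24
  counts <- matrix(rpois(200 * n_samp, 5), nrow = 200,
                   dimnames = list(sprintf("o%03d", 1:200),
                                   sprintf("s%02d", 1:n_samp)))
  tab <- toy_table(counts, ph = runif(n_samp, 3.7, 8.7))
  groups <- setNames(sample(c("g1", "g2", "g3"), n_samp, replace = TRUE),
                     colnames(counts))
  p <- indval_permutation_test(tab, groups, n_perm = 199, seed = 10)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("query indicators inherit classes from matched reference OTUs", {
  indicators <- data.frame(
    otu_id = c("q1", "q2", "q3", "q4"),
    group = c("acid", "acid", "mid", "neutral"))
  best <- data.frame(qseqid = c("q1", "q2", "q3"),
                     sseqid = c("r1", "r2", "r3"))
  ref_classes <- data.frame(
    otu_id = c("r1", "r2", "r3"),
    pH_class = c("acid", "mid", "acid_to_mid"),
    opt1_pH = c(4.2, 6.1, 4.9), opt2_pH = c(NA, NA, 6.3))
  ct <- crosstab_indicators_vs_reference(indicators, best, ref_classes)
  expect_equal(ct$n_matched, 3L)
  expect_equal(ct$n_unmatched, 1L)
  # q1 agrees; q2 observed acid but ref mid disagrees; q3 mid is within
  # the acid_to_mid span
  expect_equal(ct$agreement, 2 / 3)
  expect_equal(ct$detail$ref_opt1_pH[1], 4.2)
})
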