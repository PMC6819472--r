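test_that("exact binomial branch matches pmf enumeration", {
  for (n in c(1, 7, 20, 41, 60)) {
    for (k in unique(c(0, 1, floor(n / 3), floor(n / 2), n))) {
      expect_lt(abs(imprintr:::binom_p_twosided(k, n) -
                      oracle_binom_p(k, n)), 1e-12)
    }
  }
  # worked case: 105 maternal vs 95 paternal reads
  p <- imprintr:::binom_p_twosided(105, 200)
  expect_equal(round(p, 2), 0.52)
})

test_that("bias test handles the documented edge cases", {
  # mat = 105, pat = 95, single replicate: not significant
  cnt <- make_counts("r1", 105L, 95L)
  res <- allelic_bias_test(cnt, rho = 0)
  expect_false(res$significant)
  expect_equal(res$direction, "none")
  # overwhelming maternal bias
  cnt2 <- rbind(make_counts("r2", 100L, 0L, 1L),
                make_counts("r2", 110L, 1L, 2L))
  res2 <- allelic_bias_test(cnt2, rho = 0)
  expect_lt(res2$p, 1e-60)
  expect_equal(res2$direction, "maternal")
  # exact balance in every replicate
  cnt3 <- rbind(make_counts("r3", 50L, 50L, 1L),
                make_counts("r3", 60L, 60L, 2L))
  res3 <- allelic_bias_test(cnt3, rho = 0.02)
  expect_equal(res3$p, 1.0, tolerance = 1e-6)
  expect_equal(res3$direction, "none")
  # zero reads everywhere: untested, not significant
  cnt4 <- make_counts("r4", 0L, 0L)
  res4 <- allelic_bias_test(cnt4, rho = 0)
  expect_true(is.na(res4$p))
  expect_false(res4$significant)
})

test_that("mat/pat swap flips direction and log2 ratio, preserves p", {
  cnt <- rbind(make_counts("r1", 80L, 30L, 1L),
               make_counts("r1", 75L, 25L, 2L))
  sw <- cnt
  sw$mat <- cnt$pat
  sw$pat <- cnt$mat
  a <- allelic_bias_test(cnt, rho = 0.02)
  b <- allelic_bias_test(sw, rho = 0.02)
  expect_equal(a$p, b$p, tolerance = 1e-9)
  expect_equal(a$log2_ratio, -b$log2_ratio)
  expect_equal(a$direction, "maternal")
  expect_equal(b$direction, "paternal")
})

test_that("BH adjustment matches the brute-force step-up", {
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("dispersion estimator recovers the simulation parameter", {
  cfg <- sim_config(seed = 21, n_peaks = 1000, rho = 0.02,
                    mean_total_depth = 200,
                    class_proportions = c(biallelic = 1))
  truth <- data.frame(region_id = sprintf("r%04d", 1:1000),
                      class = "biallelic", stringsAsFactors = FALSE)
  cnt <- simulate_allelic_chip_counts(NULL, truth, cfg, "B6/CAST")
  est <- estimate_dispersion(cnt)
  expect_gte(est$rho, 0.01)
  expect_lte(est$rho, 0.03)
  # exact binomial data: estimate collapses to ~0
  cfg0 <- sim_config(seed = 22, n_peaks = 1000, rho = 0,
                     mean_total_depth = 200,
                     class_proportions = c(biallelic = 1))
  cnt0 <- simulate_allelic_chip_counts(NULL, truth, cfg0, "B6/CAST")
  expect_lte(estimate_dispersion(cnt0)$rho, 0.005)
  # identical replicate fractions at high depth: no excess variance
  cnt_id <- rbind(make_counts(sprintf("q%02d", 1:30), 5000L, 5000L, 1L),
                  make_counts(sprintf("q%02d", 1:30), 5000L, 5000L, 2L))
  expect_lte(estimate_dispersion(cnt_id)$rho, 1e-6)
  # single-replicate data warns and returns 0
  expect_warning(e1 <- estimate_dispersion(make_counts("r1", 10L, 10L)),
                 "returning rho = 0")
  expect_equal(e1$rho, 0)
})

test_that("rejection rate is non-decreasing in depth and effect size", {
  rates <- sapply(c(0.5, 0.7, 0.9), function(pi) {
    sapply(c(30, 300), function(depth) {
      cfg <- sim_config(seed = 23, n_peaks = 300, rho = 0.02,
                        mean_total_depth = depth, allelic_pi = max(pi, 0.5),
                        class_proportions = c(
                          imprinted_canonical_maternal = 1))
      truth <- data.frame(region_id = sprintf("r%03d", 1:300),
                          class = if (pi == 0.5) "biallelic" else
                            "imprinted_canonical_maternal",
                          stringsAsFactors = FALSE)
      cnt <- simulate_allelic_chip_counts(NULL, truth, cfg, "B6/CAST")
      res <- allelic_bias_test(cnt, rho = 0.02)
      mean(res$p < 0.05, na.rm = TRUE)
    })
  })
  # columns: pi = 0.5, 0.7, 0.9; rows: depth 30, 300
  expect_true(all(diff(t(rates)) >= -0.02))   # power grows with pi
  expect_true(all(rates[2, 2:3] >= rates[1, 2:3]))  # and with depth
})

test_that("location tests match hand-derived Welch and one-sample values", {
  w <- location_tests(c(1, 2, 3), c(4, 5, 6), kind = "welch_two_sample")
  expect_lt(abs(w$t - (-3 / sqrt(2 / 3))), 1e-9)
  expect_equal(w$df, 4)
  expect_equal(w$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  # cross-check against the reference implementation
  tt <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(w$t), unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)

  o <- location_tests(c(0.40, 0.45, 0.50), mu0 = 0.45, kind = "one_sample")
  expect_equal(o$t, 0)
  expect_equal(o$p, 1)
  o2 <- location_tests(c(0.40, 0.45, 0.50), mu0 = 0.30, kind = "one_sample")
  t2 <- t.test(c(0.40, 0.45, 0.50), mu = 0.30)
  expect_equal(unname(o2$t), unname(t2$statistic), tolerance = 1e-12)

  # degenerate branches
  same <- location_tests(c(2, 2), c(2, 2), kind = "welch_two_sample")
  expect_equal(same$p, 1)
  expect_warning(
    z <- location_tests(c(2, 2), c(3, 3), kind = "welch_two_sample"),
    "zero variance")
  expect_equal(z$p, 0)
})

test_that("allelic ratio pools replicates with optional size correction", {
  cnt <- rbind(make_counts("r1", 30L, 10L, 1L, sample_id = "s1"),
               make_counts("r1", 0L, 0L, 2L, sample_id = "s2"),
               make_counts("r2", 0L, 50L, 1L, sample_id = "s1"),
               make_counts("r2", 0L, 0L, 2L, sample_id = "s2"),
               make_counts("r3", 0L, 0L, 1L, sample_id = "s1"),
               make_counts("r3", 0L, 0L, 2L, sample_id = "s2"))
  r <- allelic_ratio(cnt)
  expect_equal(r$ratio[r$region_id == "r1"], 0.75)
  expect_equal(r$ratio[r$region_id == "r2"], 0)
  expect_true(is.na(r$ratio[r$region_id == "r3"]))
  # doubling one sample's counts with a matching size factor is a no-op
  cnt2 <- cnt
  dbl <- cnt2$sample_id == "s2"
  cnt2$mat[dbl] <- cnt2$mat[dbl] * 2L
  cnt2$pat[dbl] <- cnt2$pat[dbl] * 2L
  r2 <- allelic_ratio(cnt2, size_factors = c(s1 = 1, s2 = 2))
  expect_equal(r2$ratio, r$ratio)
})
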