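test_that("duration-adjusted relative risks follow the geometric escalation", {
  expect_equal(duration_adjusted_rr(2.0, 1.13, 2), 2.0 * 1.13^2,
               tolerance = 1e-12)
  expect_equal(duration_adjusted_rr(1.7, 1.0, 0:5), rep(1.7, 6))
  expect_equal(duration_adjusted_rr(1.0, 1.2, 5), 1.2^5, tolerance = 1e-12)
  expect_error(duration_adjusted_rr(2, 1.1, 6), "0\\.\\.5")
})

test_that("the extended Levin formula reproduces worked values and null cases", {
  p <- c(0.05, 0.03, 0.02, 0, 0, 0)
  rr <- c(1.5, 2.0, 3.0, 1, 1, 1)
  expect_equal(parf_multicategory(p, rr), 0.095 / 1.095, tolerance = 1e-12)
  expect_equal(parf_multicategory(p, rep(1, 6)), 0)
  expect_equal(parf_multicategory(rep(0, 6), rr), 0)
  # protective exposure gives a negative fraction
  expect_lt(parf_multicategory(c(0.1, 0, 0, 0, 0, 0), c(0.5, 1, 1, 1, 1, 1)), 0)
  expect_error(parf_multicategory(c(0.6, 0.6, 0, 0, 0, 0), rep(1, 6)),
               "sum to <= 1")
  expect_error(parf_multicategory(c(-0.1, 0.2, 0, 0, 0, 0), rep(1, 6)),
               "nonnegative")
})

test_that("the Levin fraction agrees with the two-arm brute-force risk computation", {
  set.seed(123)
  for (k in 1:1000) {
    p <- stats::runif(6, 0, 0.15)
    rr <- exp(stats::rnorm(6, 0, 0.5))
    r0 <- stats::runif(1, 1e-4, 0.05)           # arbitrary unexposed risk
    r_total <- r0 * (1 - sum(p) + sum(p * rr))  # population average risk
    oracle <- (r_total - r0) / r_total
    expect_equal(parf_multicategory(p, rr), oracle, tolerance = 1e-12)
  }
})

test_that("delta PARF is a signed difference", {
  p_hi <- parf_multicategory(c(0.10, 0.06, 0.04, 0, 0, 0),
                             c(1.5, 2.0, 3.0, 1, 1, 1))
  p_lo <- parf_multicategory(c(0.05, 0.03, 0.02, 0, 0, 0),
                             c(1.5, 2.0, 3.0, 1, 1, 1))
  expect_equal(p_hi, 0.19 / 1.19, tolerance = 1e-12)
  expect_equal(delta_parf(p_hi, p_lo), 0.19 / 1.19 - 0.095 / 1.095,
               tolerance = 1e-12)
  expect_equal(delta_parf(p_lo, p_hi), -delta_parf(p_hi, p_lo))
  expect_equal(delta_parf(0.3, 0.3), 0)
  expect_equal(delta_parf(0.05, 0.08), -0.03)  # lower exposure => negative
})

test_that("transition probabilities are rescaled exactly and monotonically", {
  p_lo <- 0.095 / 1.095
  p_hi <- 0.19 / 1.19
  # exact ratio form, matching the two-arm risk recomputation
  r0 <- 0.02 * (1 - p_lo)  # unexposed risk implied by tp 0.02 at baseline
  expect_equal(apply_parf(0.02, p_lo, p_hi), r0 / (1 - p_hi),
               tolerance = 1e-12)
  expect_equal(apply_parf(0.02, p_lo, p_hi), 0.021735, tolerance = 1e-5)
  expect_identical(apply_parf(0.37, 0.12, 0.12), 0.37)
  # lower exposure => lower risk
  expect_lt(apply_parf(0.02, p_hi, p_lo), 0.02)
  expect_warning(out <- apply_parf(0.99, 0, 0.5), "clipped")
  expect_equal(out, 1)
})

test_that("the ratio form agrees with 1 + delta PARF to first order", {
  # exact algebra: apply_parf - tp * (1 + dPARF) = tp * PARF * dPARF / (1 - PARF),
  # a second-order quantity; assert the derived bound over a seeded grid
  set.seed(4)
  for (k in 1:200) {
    parfs <- sort(stats::runif(2, -0.2, 0.2))
    tp <- stats::runif(1, 0.001, 0.2)
    exact <- apply_parf(tp, parfs[1], parfs[2])
    approx1 <- tp * (1 + delta_parf(parfs[2], parfs[1]))
    bound <- 1.3 * tp * abs(parfs[2]) * abs(parfs[2] - parfs[1])
    expect_lte(abs(exact - approx1), bound + 1e-15)
  }
})

test_that("PARF tables carry the right values and signs per transition family", {
  rr_set <- default_rr_specs()
  rr_set$duration_multiplier <- 1  # no escalation: category RRs all equal base
  dp_s <- toy_duration_array(c(0.05, 0.03, 0.02, 0, 0, 0))
  dp_b <- toy_duration_array(rep(0, 6))
  # hand-built single stratum with equal category RRs, so the table entry
  # must equal the direct Levin computation
  rr_one <- rr_set
  rr_one$base_rr <- 2
  rr_one$base_rr[rr_one$transition == "disability_recovery"] <- 0.8
  pt <- build_parf_table(dp_s, dp_b, rr_one, 2030)
  p_expect <- parf_multicategory(c(0.05, 0.03, 0.02, 0, 0, 0), rep(2, 6))
  expect_equal(attr(pt, "parf_scenario")["cvd_death", 1, 1, 1], p_expect,
               tolerance = 1e-12)
  expect_equal(attr(pt, "parf_baseline")["cvd_death", 1, 1, 1], 0)

  # identical arms zero out the table
  pt0 <- build_parf_table(dp_s, dp_s, rr_one, 2030:2032)
  expect_true(all(pt0 == 0))

  # higher scenario exposure: positive delta for harmful transitions,
  # negative for recovery
  fams <- dimnames(pt)$transition
  for (f in fams) {
    if (f == "disability_recovery") expect_lt(pt[f, 1, 1, 1], 0)
    else expect_gt(pt[f, 1, 1, 1], 0)
  }
})

test_that("PARF tables convert to a tidy data frame", {
  dp <- toy_duration_array()
  rr <- default_rr_specs(); rr$duration_multiplier <- 1.13
  pt <- build_parf_table(dp, dp, rr, 2020:2021)
  d <- as.data.frame(pt)
  expect_equal(nrow(d), 6 * 1 * 1 * 2)
  expect_true(all(c("delta_parf", "parf_scenario", "parf_baseline")
                  %in% names(d)))
  expect_true(all(d$delta_parf == 0))
})
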