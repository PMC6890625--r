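test_that("interpolated trajectories reproduce every shipped anchor exactly", {
  tab <- scenario_table()
  for (nm in unique(tab$scenario)) {
    sc <- diabetes_scenario(nm)
    rows <- tab[tab$scenario == nm, ]
    expect_equal(scenario_prevalence(sc, rows$year),
                 rows$prevalence_pct / 100, tolerance = 1e-15)
  }
})

test_that("between anchors the trajectory is piecewise linear", {
  a <- diabetes_scenario("A")
  expect_equal(scenario_prevalence(a, 2025), (0.091 + 0.101) / 2,
               tolerance = 1e-12)
  # generic midpoint property on every segment of every scenario
  for (nm in c("baseline", "A", "B", "C")) {
    sc <- diabetes_scenario(nm)
    anc <- sc$anchors
    for (k in seq_len(nrow(anc) - 1)) {
      mid <- (anc$year[k] + anc$year[k + 1]) / 2
      expect_equal(scenario_prevalence(sc, mid),
                   (anc$prevalence[k] + anc$prevalence[k + 1]) / 2,
                   tolerance = 1e-12)
    }
  }
  expect_error(scenario_prevalence(a, 2061), "out of the scenario range")
  expect_error(scenario_prevalence(a, 2014), "out of the scenario range")
})

test_that("relative prevalence changes match the printed scenario summaries after rounding", {
  expect_equal(round(relative_change(0.086, 0.128)), 49)  # scenario A
  expect_equal(round(relative_change(0.086, 0.108)), 26)  # baseline
  expect_equal(round(relative_change(0.086, 0.103)), 20)  # scenario B
  expect_equal(round(relative_change(0.086, 0.092)), 7)   # scenario C
  expect_equal(relative_change(0.086, 0.086), 0)
  expect_error(relative_change(0, 0.1), "p_start")
})

test_that("baseline duration evolution keeps category shares constant and totals on the trajectory", {
  b <- fixture_bundle()
  base <- b$duration_prevalence
  bl <- diabetes_scenario("baseline")
  ds <- duration_series(base, bl, c(2016, 2030, 2045, 2060))
  shares0 <- base / array(apply(base, c(1, 2), sum), dim = dim(base))
  for (y in names(ds)) {
    dp <- ds[[y]]
    tot <- apply(dp, c(1, 2), sum)
    # totals follow the trajectory, stratum by stratum
    expect_equal(tot,
                 apply(base, c(1, 2), sum) *
                   (scenario_prevalence(bl, as.integer(y)) /
                      scenario_prevalence(bl, 2015)),
                 tolerance = 1e-9)
    # shares identical to the reference shares
    expect_equal(dp / array(tot, dim = dim(dp)), shares0, tolerance = 1e-12)
  }
})

test_that("a constant-prevalence scenario is a fixed point of the duration update", {
  base <- fixture_bundle()$duration_prevalence
  const <- diabetes_scenario(data.frame(year = c(2015, 2060),
                                        prevalence = c(0.086, 0.086)))
  ds <- duration_series(base, const, 2015:2060)
  for (dp in ds) expect_equal(dp, base, tolerance = 1e-9)
})

test_that("zero diabetes prevalence yields all-zero duration categories", {
  zero_bundle <- generate_inputs(synthetic_config(seed = 2,
                                                  baseline_diabetes_prevalence = 0))
  base <- zero_bundle$duration_prevalence
  dp <- evolve_duration(base, diabetes_scenario("A"), 2040)
  expect_true(all(dp == 0))
})

test_that("anchored evolution matches the scenario trajectory and orders scenarios pointwise", {
  base <- fixture_bundle()$duration_prevalence
  bl <- diabetes_scenario("baseline")
  base_tot <- apply(base, c(1, 2), sum)
  yrs <- 2015:2059
  ds_a <- duration_series(base, diabetes_scenario("A"), yrs, anchor = bl)
  ds_b <- duration_series(base, bl, yrs)
  for (y in as.character(c(2020, 2040, 2059))) {
    # mass balance: stratum totals equal the scenario trajectory scaling
    expect_equal(apply(ds_a[[y]], c(1, 2), sum),
                 base_tot * scenario_prevalence(diabetes_scenario("A"),
                                                as.integer(y)) / 0.086,
                 tolerance = 1e-9)
    # a pointwise-higher trajectory never has less mass in any category
    expect_true(all(ds_a[[y]] >= ds_b[[y]] - 1e-12))
  }
  ds_c <- suppressWarnings(
    duration_series(base, diabetes_scenario("C"), yrs, anchor = bl))
  for (y in as.character(c(2020, 2040, 2059)))
    expect_true(all(ds_c[[y]] <= ds_b[[y]] + 1e-12))
})

test_that("single-year evolution agrees with the iterated series", {
  base <- fixture_bundle()$duration_prevalence
  bl <- diabetes_scenario("baseline")
  a <- diabetes_scenario("A")
  expect_identical(evolve_duration(base, a, 2037, anchor = bl),
                   duration_series(base, a, 2015:2040, anchor = bl)[["2037"]])
})

test_that("prevented cases beyond the prevalent stock are clipped with a warning", {
  base <- fixture_bundle()$duration_prevalence
  crash <- diabetes_scenario(data.frame(year = c(2015, 2020, 2060),
                                        prevalence = c(0.086, 0.001, 0.001)))
  expect_warning(
    dp <- evolve_duration(base, crash, 2030, anchor = diabetes_scenario("baseline")),
    "clipped")
  expect_true(all(dp >= 0))
})

test_that("custom trajectories are validated", {
  expect_error(diabetes_scenario(data.frame(year = 2015, foo = 1)),
               "year and prevalence")
  expect_error(diabetes_scenario(data.frame(year = c(2015, 2060),
                                            prevalence = c(0.08, 1.2))),
               "in \\(0,1\\)")
  expect_error(diabetes_scenario("Z"), "unknown scenario")
})
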