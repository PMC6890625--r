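test_that("incident cases and rates follow the flow arithmetic", {
  arrs <- empty_toy_arrays(2019:2021)
  s <- match(c("free", "dis"), bam_states())
  arrs$counts[1, 1, 1, s[1]] <- 2500          # 2500 alive at 2019
  arrs$flows[1, 1, 1, s[1], s[2]] <- 50       # 50 new disability cases
  p <- toy_projection(2019:2021, arrs$counts, arrs$flows)
  got <- incident_cases(p, "disability", 2019)
  expect_equal(got$cases, 50)
  expect_equal(got$rate_per_1000, 20)
  expect_equal(incident_cases(p, "dementia", 2019)$cases, 0)
  expect_error(incident_cases(p, "arthritis", 2019), "should be one of")
  expect_error(incident_cases(p, "dementia", 2021), "flows not available")
})

test_that("dementia entries are counted from every non-dementia state", {
  arrs <- empty_toy_arrays(2019:2020)
  st <- match(c("ci", "dis", "cvd_ci", "cvd_dis", "dem", "cvd_dem"),
              bam_states())
  arrs$counts[1, 1, 1, st[1]] <- 1000
  arrs$flows[1, 1, 1, st[1], st[5]] <- 7    # ci -> dem
  arrs$flows[1, 1, 1, st[2], st[5]] <- 5    # dis -> dem
  arrs$flows[1, 1, 2, st[3], st[6]] <- 3    # cvd_ci -> cvd_dem (women)
  arrs$flows[1, 1, 2, st[4], st[6]] <- 2    # cvd_dis -> cvd_dem
  arrs$flows[1, 1, 1, st[5], st[6]] <- 99   # dem -> cvd_dem: NOT incident
  p <- toy_projection(2019:2020, arrs$counts, arrs$flows)
  expect_equal(incident_cases(p, "dementia", 2019)$cases, 7 + 5 + 3 + 2)
  expect_equal(incident_cases(p, "dementia", 2019, sex = "men")$cases, 12)
  expect_equal(incident_cases(p, "dementia", 2019, sex = "women")$cases, 5)
})

test_that("percent decline reproduces the headline rate arithmetic", {
  expect_equal(round(percent_decline(38.7, 23.6)), 39)
  expect_equal(percent_decline(38.7, 23.6), 39.0180878, tolerance = 1e-6)
  expect_equal(percent_decline(21.4, 13.9), 35.046729, tolerance = 1e-6)
  expect_equal(percent_decline(17, 17), 0)
  expect_error(percent_decline(0, 5), "rate_start")
})

test_that("scenario comparison accumulates differences with the avoided sign convention", {
  yrs <- 2015:2017
  mk <- function(deaths_by_year) {
    arrs <- empty_toy_arrays(yrs)
    arrs$counts[, 1, 1, 1] <- 1000
    for (i in seq_along(deaths_by_year))
      arrs$flows[i, 1, 1, 1, 10] <- deaths_by_year[i]
    toy_projection(yrs, arrs$counts, arrs$flows)
  }
  base <- mk(c(10, 10, 0))
  scen <- mk(c(10, 12, 0))
  cmp <- compare_scenarios(scen, base, from_year = 2015)
  all_deaths <- cmp[cmp$sex == "all" & cmp$measure == "deaths", ]
  expect_equal(all_deaths$avoided[all_deaths$year == 2015], 0)
  expect_equal(all_deaths$avoided[all_deaths$year == 2016], -2)
  # identical runs give exactly zero everywhere
  cmp0 <- compare_scenarios(base, base)
  expect_true(all(cmp0$avoided == 0) && all(cmp0$per_100k == 0))
  # antisymmetry under arm exchange
  rev <- compare_scenarios(base, scen, from_year = 2015)
  expect_equal(rev$avoided, -cmp$avoided)
})

test_that("rates are exactly reproducible from counts and populations", {
  res <- fixture_scenario_run("C")
  p <- res$baseline
  for (y in c(2015, 2040)) for (m in c("dementia", "disability", "deaths")) {
    got <- incident_cases(p, m, y)
    pop <- sum(p$counts[as.character(y), p$ages >= 65, , 1:8])
    expect_identical(got$rate_per_1000, 1000 * got$cases / pop)
  }
})

test_that("life years and time spent with disability follow the person-year identity", {
  yrs <- 2015:2024
  arrs <- empty_toy_arrays(yrs)
  # one person alive 10 years, 2 of them in a disability state
  dis <- match("dis", bam_states())
  arrs$counts[, 1, 1, 1] <- 1
  arrs$counts[9:10, 1, 1, 1] <- 0
  arrs$counts[9:10, 1, 1, dis] <- 1
  scen <- toy_projection(yrs, arrs$counts, arrs$flows)

  base_arrs <- empty_toy_arrays(yrs)
  base_arrs$counts[, 1, 1, 1] <- 1  # alive, never disabled
  base <- toy_projection(yrs, base_arrs$counts, base_arrs$flows)

  ly <- life_years(scen, base, from_year = 2015)
  last <- ly[ly$sex == "all" & ly$year == 2024, ]
  expect_equal(last$lyg, 0)  # both alive 10 person-years
  expect_equal(last$pct_disability_scenario, 20)
  expect_equal(last$pct_disability_baseline, 0)
  # identical arms: zero gain, identical percentages
  ly0 <- life_years(base, base)
  expect_true(all(ly0$lyg == 0))
  expect_identical(ly0$pct_disability_scenario, ly0$pct_disability_baseline)
})

test_that("life-years gained equals the person-year accounting identity on a real run", {
  res <- fixture_scenario_run("C")
  ly <- life_years(res$scenario, res$baseline, from_year = 2015)
  sel <- res$scenario$ages >= 65
  y_idx <- as.character(2015:2060)
  py_s <- sapply(y_idx, function(y) sum(res$scenario$counts[y, sel, , 1:8]))
  py_b <- sapply(y_idx, function(y) sum(res$baseline$counts[y, sel, , 1:8]))
  expect_equal(ly$lyg[ly$sex == "all"], unname(cumsum(py_s) - cumsum(py_b)),
               tolerance = 1e-12)
})

test_that("the outcome table covers all measures and sex groups", {
  res <- fixture_scenario_run("C")
  tab <- outcome_table(res$baseline, years = c(2015, 2045))
  expect_equal(nrow(tab), 3 * 3 * 2)
  expect_true(all(tab$cases >= 0) && all(tab$rate_per_1000 >= 0))
  men <- tab[tab$sex == "men" & tab$year == 2015, "cases"]
  women <- tab[tab$sex == "women" & tab$year == 2015, "cases"]
  all_ <- tab[tab$sex == "all" & tab$year == 2015, "cases"]
  expect_equal(men + women, all_, tolerance = 1e-9)
})
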