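test_that("identity transitions with no entrants just age the population", {
  b <- fixture_bundle()
  n_age <- length(b$config$age_min:b$config$age_max)
  P_id <- array(0, dim = c(n_age, 2, 10, 10))
  for (i in 1:10) P_id[, , i, i] <- 1
  out <- step_year(b$population, P_id, entry_cohort = 0)
  expect_equal(out$counts[2:(n_age - 1), , ],
               b$population[1:(n_age - 2), , ],
               tolerance = 1e-15, ignore_attr = TRUE)
  # terminal age accumulates its own survivors plus the previous age
  expect_equal(out$counts[n_age, , ],
               b$population[n_age, , ] + b$population[n_age - 1, , ],
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(sum(out$counts[1, , ]), 0)
})

test_that("a two-state toy cohort splits by the death probability", {
  counts <- array(c(100, 0), dim = c(1, 1, 2))
  P <- array(c(0.9, 0, 0.1, 1), dim = c(1, 1, 2, 2))
  out <- step_year(counts, P)
  expect_equal(as.vector(out$counts), c(90, 10))
  expect_equal(out$flows[1, 1, 1, 2], 10)
  # forcing certain death empties the alive state while conserving mass
  P1 <- array(c(0, 0, 1, 1), dim = c(1, 1, 2, 2))
  out1 <- step_year(counts, P1)
  expect_equal(as.vector(out1$counts), c(0, 100))
})

test_that("entrants join the youngest age in the requested state", {
  counts <- array(0, dim = c(3, 2, 10))
  P_id <- array(0, dim = c(3, 2, 10, 10))
  for (i in 1:10) P_id[, , i, i] <- 1
  out <- step_year(counts, P_id, entry_cohort = 500)
  expect_equal(out$counts[1, 1, 1], 250)
  expect_equal(out$counts[1, 2, 1], 250)
  expect_equal(sum(out$counts), 500)
})

test_that("three steps match an independent straightforward loop implementation", {
  b <- fixture_bundle()
  P <- b$transitions
  ages <- b$config$age_min:b$config$age_max
  n_age <- length(ages)

  # oracle: explicit per-cohort vector-matrix products and manual ageing
  oracle <- b$population
  for (step in 1:3) {
    post <- oracle * 0
    for (a in seq_len(n_age)) for (s in 1:2)
      post[a, s, ] <- as.vector(oracle[a, s, ] %*% P[a, s, , ])
    nxt <- oracle * 0
    for (a in seq_len(n_age - 1)) nxt[a + 1, , ] <- post[a, , ]
    nxt[n_age, , ] <- nxt[n_age, , ] + post[n_age, , ]
    nxt[1, 1, 1] <- 7000; nxt[1, 2, 1] <- 7000
    oracle <- nxt
  }

  cur <- b$population
  for (step in 1:3)
    cur <- step_year(cur, P, entry_cohort = c(7000, 7000))$counts
  expect_equal(cur, oracle, tolerance = 1e-9)
})

test_that("negative probabilities surface as a hard error, never silent clipping", {
  counts <- array(c(100, 0), dim = c(1, 1, 2))
  P <- array(c(1.5, 0, -0.5, 1), dim = c(1, 1, 2, 2))
  expect_error(step_year(counts, P), "negative occupancy")
  expect_error(step_year(counts, array(1, dim = c(2, 1, 2, 2))),
               "different strata")
})

test_that("the full projection conserves persons and is deterministic", {
  b <- fixture_bundle()
  pm <- fixture_mortality()
  p1 <- run_projection(b, pm)
  p2 <- run_projection(b, pm)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$flows, p2$flows)
  expect_lt(conservation_error(p1), 1e-6)
  expect_true(all(p1$counts >= 0))
})

test_that("occupancy change equals inflows minus outflows, year by year", {
  p <- run_projection(fixture_bundle(), fixture_mortality(),
                      years = 2006:2016)
  n_age <- length(p$ages)
  for (yi in c(1, 5, 10)) {
    inflow <- apply(p$flows[yi, , , , ], c(1, 2, 4), sum)  # into each state
    # ageing shifts cohorts: occupancy of age a+1 next year equals this
    # year's post-transition occupancy of age a; the terminal age pools its
    # own survivors with the cohort ageing into it
    expect_equal(p$counts[yi + 1, 2:(n_age - 1), , ],
                 inflow[1:(n_age - 2), , ], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(p$counts[yi + 1, n_age, , ],
                 inflow[n_age - 1, , ] + inflow[n_age, , ],
                 tolerance = 1e-9, ignore_attr = TRUE)
    # youngest age holds exactly the entrants
    expect_equal(sum(p$counts[yi + 1, 1, , ]), p$entry[yi], tolerance = 1e-9)
  }
})

test_that("scaling the population scales every occupancy and flow linearly", {
  b <- fixture_bundle()
  pm <- fixture_mortality()
  b2 <- b
  b2$population <- b$population * 3
  cfg <- b$config
  p1 <- run_projection(b, pm, entry_cohort = cfg$annual_entry_cohort)
  p3 <- run_projection(b2, pm, entry_cohort = 3 * cfg$annual_entry_cohort)
  expect_equal(p3$counts, 3 * p1$counts, tolerance = 1e-10)
  expect_equal(p3$flows, 3 * p1$flows, tolerance = 1e-10)
})

test_that("an all-zero PARF table reproduces the baseline run bit for bit", {
  b <- fixture_bundle()
  pm <- fixture_mortality()
  res <- fixture_scenario_run("baseline")
  expect_true(all(res$parf_table == 0))
  expect_identical(res$scenario$counts, res$baseline$counts)
  expect_identical(res$scenario$flows, res$baseline$flows)
})

test_that("missing projection years are a validation error", {
  b <- fixture_bundle()
  pm_short <- project_mortality(b$mortality, horizon_year = 2030)
  expect_error(run_projection(b, pm_short), "missing years")
})
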