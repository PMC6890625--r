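# lazily built, cached fixtures shared across test files
.fx <- new.env(parent = emptyenv())

fixture_bundle <- function(seed = 1) {
  key <- paste0("bundle_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_inputs(synthetic_config(seed = seed))
  .fx[[key]]
}

fixture_mortality <- function(seed = 1) {
  key <- paste0("pm_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- project_mortality(fixture_bundle(seed)$mortality,
                                    horizon_year = 2060)
  .fx[[key]]
}

fixture_scenario_run <- function(name, seed = 1) {
  key <- paste0("run_", name, "_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- suppressWarnings(
      project_scenario(fixture_bundle(seed), name,
                       projected_mortality = fixture_mortality(seed)))
  .fx[[key]]
}

# a small single-stratum duration-prevalence array for PARF table tests
toy_duration_array <- function(p = c(0.05, 0.03, 0.02, 0, 0, 0)) {
  array(p, dim = c(1, 1, 6),
        dimnames = list(age_band = "35-44", sex = "male",
                        duration = duration_categories()))
}

# hand-assembled minimal projection object for outcome arithmetic tests:
# one age (65), one sex dimension kept at 2, `n_years` years
toy_projection <- function(years, counts, flows) {
  structure(list(counts = counts, flows = flows, years = years,
                 ages = 65L, entry = rep(0, length(years)),
                 scenario = "toy", start_year = years[1]),
            class = "bam_projection")
}

empty_toy_arrays <- function(years) {
  n <- length(years)
  states <- bam_states()
  counts <- array(0, dim = c(n, 1, 2, 10),
                  dimnames = list(year = years, age = 65, sex = c("male", "female"),
                                  state = states))
  flows <- array(0, dim = c(n, 1, 2, 10, 10),
                 dimnames = list(year = years, age = 65, sex = c("male", "female"),
                                 from = states, to = states))
  list(counts = counts, flows = flows)
}
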