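#' Run a scenario and its baseline through the full pipeline
#'
#' Convenience wrapper that ties the stages together for one scenario:
#' projects the mortality series, evolves the diabetes duration
#' distribution under the scenario and the baseline, builds the PARF table,
#' and runs the cohort engine twice — once unmodified (baseline) and once
#' with the PARF-rescaled transitions (scenario).
#'
#' @param bundle an [generate_inputs()] input bundle.
#' @param scenario a [diabetes_scenario()] (or scenario name).
#' @param baseline_scenario the reference trajectory (default the
#'   `"baseline"` scenario).
#' @param projected_mortality optional precomputed [project_mortality()]
#'   result; computed from `bundle$mortality` when `NULL`.
#' @param reference_year year the duration distribution describes and the
#'   first year of PARF modification (default 2015).
#' @return list with elements `scenario` and `baseline` (both
#'   `bam_projection`), `parf_table`, and `projected_mortality`.
#' @export
project_scenario <- function(bundle, scenario,
                             baseline_scenario = diabetes_scenario("baseline"),
                             projected_mortality = NULL,
                             reference_year = 2015) {
  stopifnot(inherits(bundle, "input_bundle"))
  if (is.character(scenario)) scenario <- diabetes_scenario(scenario)
  cfg <- bundle$config
  if (is.null(projected_mortality))
    projected_mortality <- project_mortality(bundle$mortality,
                                             horizon_year = cfg$end_year)
  parf_years <- reference_year:(cfg$end_year - 1)
  dp_s <- duration_series(bundle$duration_prevalence, scenario, parf_years,
                          reference_year, anchor = baseline_scenario)
  dp_b <- duration_series(bundle$duration_prevalence, baseline_scenario,
                          parf_years, reference_year)
  pt <- build_parf_table(function(y) dp_s[[as.character(y)]],
                         function(y) dp_b[[as.character(y)]],
                         bundle$rr_set, parf_years)
  proj_b <- run_projection(bundle, projected_mortality)
  proj_s <- run_projection(bundle, projected_mortality, parf_table = pt)
  proj_s$scenario <- scenario$name
  list(scenario = proj_s, baseline = proj_b, parf_table = pt,
       projected_mortality = projected_mortality)
}
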