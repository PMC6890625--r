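# sex-group column helper: indices into the sex dimension
.sex_groups <- list(all = 1:2, men = 1L, women = 2L)

# persons alive at the start of `year`, aged >= min_age
.alive_pop <- function(proj, year, min_age = 65, sexes = 1:2) {
  sel <- proj$ages >= min_age
  sum(proj$counts[as.character(year), sel, sexes, .ALIVE])
}

# annual events (flows) of a given kind during `year`, aged >= min_age at
# the start of the year
.annual_events <- function(proj, kind, year, min_age = 65, sexes = 1:2) {
  sel <- proj$ages >= min_age
  y <- as.character(year)
  switch(kind,
    dementia = {
      to <- c(.S[["dem"]], .S[["cvd_dem"]])
      from <- setdiff(1:10, to)
      sum(proj$flows[y, sel, sexes, from, to])
    },
    disability = {
      to <- c(.S[["dis"]], .S[["cvd_dis"]])
      from <- setdiff(1:10, to)
      sum(proj$flows[y, sel, sexes, from, to])
    },
    deaths = sum(proj$flows[y, sel, sexes, .ALIVE, .DEAD]),
    stop("unknown condition '", kind, "'")
  )
}

#' Incident cases and rate per 1000
#'
#' Counts the persons entering the dementia states (from any non-dementia
#' state) or the disability states (from any non-disability state) during a
#' year, restricted to the population aged `min_age`+ at the start of the
#' year, and expresses them per 1000 alive persons of that age group.
#'
#' @param proj a [run_projection()] result.
#' @param condition `"dementia"`, `"disability"` or `"deaths"`.
#' @param year calendar year(s); must have recorded flows (i.e. not the
#'   final simulated year).
#' @param min_age lower age cut (default 65, the headline reporting group).
#' @param sex `"all"`, `"men"` or `"women"`.
#' @return data frame with columns `year`, `sex`, `cases`,
#'   `rate_per_1000`.
#' @export
incident_cases <- function(proj, condition, year, min_age = 65,
                           sex = "all") {
  stopifnot(inherits(proj, "bam_projection"))
  condition <- match.arg(condition, c("dementia", "disability", "deaths"))
  sex <- match.arg(sex, names(.sex_groups))
  sx <- .sex_groups[[sex]]
  if (any(!year %in% proj$years[-length(proj$years)]))
    stop("flows not available for some requested years")
  cases <- vapply(year, function(y)
    .annual_events(proj, condition, y, min_age, sx), numeric(1))
  pop <- vapply(year, function(y) .alive_pop(proj, y, min_age, sx),
                numeric(1))
  data.frame(year = year, sex = sex, cases = cases,
             rate_per_1000 = ifelse(pop > 0, 1000 * cases / pop, 0))
}

#' Percent decline between two rates
#'
#' @param rate_start starting rate (> 0).
#' @param rate_end ending rate.
#' @return `100 * (rate_start - rate_end) / rate_start`.
#' @export
percent_decline <- function(rate_start, rate_end) {
  if (any(rate_start <= 0)) stop("rate_start must be > 0")
  100 * (rate_start - rate_end) / rate_start
}

#' Cumulative scenario-vs-baseline differences
#'
#' For deaths, incident dementia and incident disability in the population
#' aged `min_age`+, accumulates annual events from `from_year` onwards in
#' both runs and reports `avoided = cumulative baseline - cumulative
#' scenario` (negative values mean additional burden under the scenario),
#' plus the difference per 100,000 of the scenario-year population.
#'
#' @param proj_scenario,proj_baseline [run_projection()] results sharing
#'   years and strata.
#' @param from_year first year of accumulation (default 2015).
#' @param through_year last year (default: last year with flows).
#' @param min_age lower age cut (default 65).
#' @return object of class `scenario_comparison`: data frame with columns
#'   `year`, `sex`, `measure`, `cumulative_scenario`,
#'   `cumulative_baseline`, `avoided`, `per_100k`.
#' @export
compare_scenarios <- function(proj_scenario, proj_baseline,
                              from_year = 2015, through_year = NULL,
                              min_age = 65) {
  stopifnot(inherits(proj_scenario, "bam_projection"),
            inherits(proj_baseline, "bam_projection"))
  if (!identical(proj_scenario$years, proj_baseline$years) ||
      !identical(proj_scenario$ages, proj_baseline$ages))
    stop("projections cover different year/age grids")
  flow_years <- proj_scenario$years[-length(proj_scenario$years)]
  if (is.null(through_year)) through_year <- max(flow_years)
  yrs <- flow_years[flow_years >= from_year & flow_years <= through_year]
  measures <- c("deaths", "dementia", "disability")
  out <- list()
  for (sx_name in names(.sex_groups)) {
    sx <- .sex_groups[[sx_name]]
    for (m in measures) {
      ev_s <- cumsum(vapply(yrs, function(y)
        .annual_events(proj_scenario, m, y, min_age, sx), numeric(1)))
      ev_b <- cumsum(vapply(yrs, function(y)
        .annual_events(proj_baseline, m, y, min_age, sx), numeric(1)))
      pop <- vapply(yrs, function(y)
        .alive_pop(proj_scenario, y, min_age, sx), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        year = yrs, sex = sx_name, measure = m,
        cumulative_scenario = ev_s, cumulative_baseline = ev_b,
        avoided = ev_b - ev_s,
        per_100k = ifelse(pop > 0, 1e5 * (ev_b - ev_s) / pop, 0))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("scenario_comparison", "data.frame")
  res
}

#' @export
print.scenario_comparison <- function(x, ...) {
  last <- x[x$year == max(x$year) & x$sex == "all", ]
  cat("Scenario comparison, cumulative ", min(x$year), "-", max(x$year),
      " (population aged >= 65):\n", sep = "")
  for (i in seq_len(nrow(last)))
    cat(sprintf("  %-10s avoided: %8.1f thousand (%+.1f per 100,000)\n",
                last$measure[i], last$avoided[i] / 1e3, last$per_100k[i]))
  cat("  (negative values indicate additional burden under the scenario)\n")
  invisible(x)
}

#' Life-years gained and percentage of life spent with disability
#'
#' Person-years are the annual census of alive persons aged `min_age`+ at
#' the start of each year, accumulated from `from_year`.  Life-years gained
#' (LYG) is the scenario-minus-baseline difference of that accumulation.
#' The percentage of life spent with disability divides the person-years
#' spent in the disability-bearing states (the two disability states plus
#' the two dementia states, dementia being cognitive impairment coexisting
#' with disability) by all alive person-years.
#'
#' @inheritParams compare_scenarios
#' @return object of class `life_years_result`: data frame with columns
#'   `year`, `sex`, `lyg` (cumulative), `pct_disability_scenario`,
#'   `pct_disability_baseline` (cumulative shares, in percent).
#' @export
life_years <- function(proj_scenario, proj_baseline, from_year = 2015,
                       through_year = NULL, min_age = 65) {
  stopifnot(inherits(proj_scenario, "bam_projection"),
            inherits(proj_baseline, "bam_projection"))
  if (!identical(proj_scenario$years, proj_baseline$years))
    stop("projections cover different year grids")
  if (is.null(through_year)) through_year <- max(proj_scenario$years)
  yrs <- proj_scenario$years[proj_scenario$years >= from_year &
                               proj_scenario$years <= through_year]
  sel <- proj_scenario$ages >= min_age
  py <- function(proj, states, sx) {
    vapply(yrs, function(y)
      sum(proj$counts[as.character(y), sel, sx, states]), numeric(1))
  }
  out <- list()
  for (sx_name in names(.sex_groups)) {
    sx <- .sex_groups[[sx_name]]
    alive_s <- py(proj_scenario, .ALIVE, sx)
    alive_b <- py(proj_baseline, .ALIVE, sx)
    dis_s <- py(proj_scenario, .DISABILITY_BEARING, sx)
    dis_b <- py(proj_baseline, .DISABILITY_BEARING, sx)
    out[[length(out) + 1]] <- data.frame(
      year = yrs, sex = sx_name,
      lyg = cumsum(alive_s) - cumsum(alive_b),
      pct_disability_scenario = 100 * cumsum(dis_s) / cumsum(alive_s),
      pct_disability_baseline = 100 * cumsum(dis_b) / cumsum(alive_b))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("life_years_result", "data.frame")
  res
}

#' @export
print.life_years_result <- function(x, ...) {
  last <- x[x$year == max(x$year) & x$sex == "all", ]
  cat(sprintf("Life-years gained by %d: %.1f thousand\n", last$year,
              last$lyg / 1e3))
  cat(sprintf("  %% of life spent with disability: %.2f (scenario) vs %.2f (baseline)\n",
              last$pct_disability_scenario, last$pct_disability_baseline))
  invisible(x)
}

#' Headline outcome table for a single run
#'
#' Annual incident disability, incident dementia and deaths with their
#' per-1000 rates for the population aged `min_age`+, by sex group, for a
#' set of reporting years — the shape of a standard burden-projection
#' table.
#'
#' @param proj a [run_projection()] result.
#' @param years reporting years (default every year with flows among 2015,
#'   2030, 2045, 2060).
#' @param min_age lower age cut (default 65).
#' @return data frame with columns `year`, `sex`, `measure`, `cases`,
#'   `rate_per_1000`.
#' @export
outcome_table <- function(proj, years = NULL, min_age = 65) {
  if (is.null(years))
    years <- intersect(c(2015, 2030, 2045, 2060),
                       proj$years[-length(proj$years)])
  out <- list()
  for (sx in names(.sex_groups)) for (m in c("disability", "dementia",
                                             "deaths")) {
    d <- incident_cases(proj, m, years, min_age, sx)
    d$measure <- m
    out[[length(out) + 1]] <- d[, c("year", "sex", "measure", "cases",
                                    "rate_per_1000")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
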