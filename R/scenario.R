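#' Diabetes prevalence scenarios
#'
#' Four projected trajectories of total type 2 diabetes prevalence
#' 2015-2060, anchored at decade values produced by a national diabetes
#' prevalence model under different futures for the obesity trend:
#' `baseline` (+1% obesity per 5 years, prevalence 8.6% -> 10.8%, +26%),
#' `A` (accelerating obesity, +5%/5y, -> 12.8%, +49%),
#' `B` (obesity halted, 0%/5y, -> 10.3%, +20%) and
#' `C` (obesity reversed, -3%/5y, -> 9.2%, +7%).
#' Anchors are shipped with the package (`extdata/scenarios.csv`) and
#' interpolated piecewise-linearly to annual resolution.
#'
#' @param name one of `"baseline"`, `"A"`, `"B"`, `"C"`, or a data frame
#'   with columns `year` and `prevalence` (proportions) supplying a custom
#'   trajectory.
#' @return object of class `diabetes_scenario`: list with `name`,
#'   `anchors` (data frame: year, prevalence as proportion) and
#'   `obesity_change_per_5y`.
#' @export
diabetes_scenario <- function(name = "baseline") {
  if (is.data.frame(name)) {
    anc <- name
    if (!all(c("year", "prevalence") %in% names(anc)))
      stop("custom trajectory needs columns year and prevalence")
    if (any(anc$prevalence < 0 | anc$prevalence >= 1))
      stop("anchor prevalences must lie in (0,1)")
    sc <- list(name = "custom",
               anchors = anc[order(anc$year), c("year", "prevalence")],
               obesity_change_per_5y = NA_real_)
    class(sc) <- "diabetes_scenario"
    return(sc)
  }
  tab <- scenario_table()
  if (!name %in% tab$scenario)
    stop("unknown scenario '", name, "'; use one of: ",
         paste(unique(tab$scenario), collapse = ", "))
  rows <- tab[tab$scenario == name, ]
  sc <- list(name = name,
             anchors = data.frame(year = rows$year,
                                  prevalence = rows$prevalence_pct / 100),
             obesity_change_per_5y = rows$obesity_change_per_5y[1])
  class(sc) <- "diabetes_scenario"
  sc
}

#' @rdname diabetes_scenario
#' @return `scenario_table()` returns the packaged anchor table (scenario,
#'   obesity change per 5 years, year, prevalence in percent).
#' @export
scenario_table <- function() {
  path <- system.file("extdata", "scenarios.csv", package = "demburden",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.diabetes_scenario <- function(x, ...) {
  cat("Diabetes scenario '", x$name, "' (obesity change ",
      x$obesity_change_per_5y, "%/5y)\n", sep = "")
  yr0 <- min(x$anchors$year); yr1 <- max(x$anchors$year)
  p0 <- x$anchors$prevalence[which.min(x$anchors$year)]
  p1 <- x$anchors$prevalence[which.max(x$anchors$year)]
  cat(sprintf("  prevalence %.1f%% (%d) -> %.1f%% (%d): %+.0f%% relative\n",
              100 * p0, yr0, 100 * p1, yr1, relative_change(p0, p1)))
  invisible(x)
}

#' Interpolate a scenario trajectory to a given year
#'
#' Piecewise-linear interpolation between the decade anchors; exact at the
#' anchors.  Years outside the anchored range are an error.
#'
#' @param scenario a [diabetes_scenario()].
#' @param year calendar year(s) within the anchored range.
#' @return total diabetes prevalence (proportion), vectorised over `year`.
#' @export
scenario_prevalence <- function(scenario, year) {
  stopifnot(inherits(scenario, "diabetes_scenario"))
  anc <- scenario$anchors
  if (any(year < min(anc$year) | year > max(anc$year)))
    stop("year out of the scenario range ", min(anc$year), "-",
         max(anc$year))
  stats::approx(anc$year, anc$prevalence, xout = year, method = "linear",
                ties = "ordered")$y
}

#' Relative change between two prevalences, in percent
#'
#' @param p_start starting prevalence (> 0).
#' @param p_end ending prevalence.
#' @return `100 * (p_end - p_start) / p_start`.
#' @export
relative_change <- function(p_start, p_end) {
  if (any(p_start <= 0)) stop("p_start must be > 0")
  100 * (p_end - p_start) / p_start
}

#' Evolve the diabetes duration-category distribution through time
#'
#' Starting from the reference distribution (band x sex x 6 categories),
#' produces the distribution for a later year under a scenario.
#'
#' The prevalent diabetic stock keeps its reference category *shares*, each
#' stratum scaled so its total follows the `anchor` trajectory (for the
#' baseline scenario anchored on itself this is exactly the
#' constant-shares assumption).  The scenario's *excess* prevalence over
#' the anchor — the cases a diverging trajectory adds, or (negatively) the
#' cases it prevents — enters the "<5 years" category as new incidence and
#' ages through the categories: every year each 5-year category passes 1/5
#' of its mass to the next, the terminal ">=25 years" category
#' accumulating.  Stratum totals therefore match the scenario trajectory
#' exactly, unless a category would be driven below zero, in which case it
#' is clipped at zero with a warning (prevented cases cannot exceed the
#' prevalent stock).
#'
#' @param base band x sex x 6 array of reference duration prevalences
#'   (e.g. `bundle$duration_prevalence`), valid for `reference_year`.
#' @param scenario a [diabetes_scenario()].
#' @param year target calendar year (>= `reference_year`).
#' @param reference_year year the base distribution describes (default 2015).
#' @param anchor [diabetes_scenario()] whose trajectory the prevalent stock
#'   follows with constant shares; default `NULL` anchors the scenario on
#'   itself (pure proportional scaling, no duration drift).
#' @return band x sex x 6 array of duration prevalences at `year`.
#' @export
evolve_duration <- function(base, scenario, year, reference_year = 2015,
                            anchor = NULL) {
  duration_series(base, scenario, year, reference_year,
                  anchor)[[as.character(year)]]
}

#' @rdname evolve_duration
#' @param years calendar years (all >= `reference_year`); the annual
#'   advancement is iterated once across the whole span.
#' @return `duration_series()` returns a named list of such arrays, one per
#'   requested year.
#' @export
duration_series <- function(base, scenario, years, reference_year = 2015,
                            anchor = NULL) {
  stopifnot(inherits(scenario, "diabetes_scenario"))
  if (is.null(anchor)) anchor <- scenario
  stopifnot(inherits(anchor, "diabetes_scenario"))
  years <- sort(years)
  if (any(years < reference_year)) stop("years must be >= reference_year")
  p_ref_s <- scenario_prevalence(scenario, reference_year)
  p_ref_a <- scenario_prevalence(anchor, reference_year)
  out <- vector("list", length(years))
  names(out) <- as.character(years)
  base_tot <- apply(base, c(1, 2), sum)  # stratum totals at reference
  if (p_ref_s == 0 || p_ref_a == 0) {
    # degenerate: no diabetes at reference; scale is undefined, keep zeros
    for (i in seq_along(years)) out[[i]] <- base * 0
    return(out)
  }
  delta <- base * 0
  clipped <- FALSE
  y <- reference_year
  for (i in seq_along(years)) {
    while (y < years[i]) {
      y <- y + 1
      # advance the excess stock by one year of duration
      shift <- delta[, , 1:5] / 5
      delta[, , 1:5] <- delta[, , 1:5] - shift
      delta[, , 2:6] <- delta[, , 2:6] + shift
      # incidence into "<5y" sized so stratum totals hit the trajectory
      excess_tgt <- base_tot * (scenario_prevalence(scenario, y) / p_ref_s -
                                  scenario_prevalence(anchor, y) / p_ref_a)
      delta[, , 1] <- delta[, , 1] +
        (excess_tgt - apply(delta, c(1, 2), sum))
    }
    ratio_a <- scenario_prevalence(anchor, y) / p_ref_a
    dp <- base * ratio_a + delta
    if (any(dp < 0)) {
      clipped <- TRUE
      dp[dp < 0] <- 0
    }
    out[[i]] <- dp
  }
  if (clipped)
    warning("prevented cases exceeded a duration category's prevalent ",
            "stock; category clipped at zero", call. = FALSE)
  out
}
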