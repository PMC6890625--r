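#' Duration-adjusted relative risk
#'
#' The relative risk for duration category `k` (0-indexed; category 0 is
#' "<5 years", the reference) escalates geometrically with time lived with
#' diabetes: `base_rr * duration_multiplier^k`, mirroring trial evidence of
#' increasing complication hazards per 5 additional years of duration.
#'
#' @param base_rr relative risk in the shortest-duration category.
#' @param duration_multiplier escalation factor per 5 years of duration.
#' @param category_index integer(s) in 0..5.
#' @return relative risk(s) for the requested categories.
#' @export
duration_adjusted_rr <- function(base_rr, duration_multiplier,
                                 category_index) {
  if (any(category_index < 0 | category_index > 5))
    stop("category_index must lie in 0..5")
  base_rr * duration_multiplier^category_index
}

#' Multi-category population attributable risk fraction
#'
#' Extended Levin formula for an exposure with several levels:
#' \deqn{PARF = \frac{\sum_i p_i (RR_i - 1)}{1 + \sum_i p_i (RR_i - 1)}}
#' where \eqn{p_i} is the population prevalence of exposure level `i` and
#' \eqn{RR_i} its relative risk versus the unexposed.  Equivalently,
#' (total risk - unexposed risk) / total risk, for any unexposed baseline
#' risk.  Valid for protective exposures (RR < 1), where it is negative.
#'
#' @param prevalences numeric vector of category prevalences (>= 0,
#'   sum <= 1).
#' @param rrs numeric vector of category relative risks (> 0), same length.
#' @return the attributable fraction (scalar).
#' @export
parf_multicategory <- function(prevalences, rrs) {
  if (length(prevalences) != length(rrs))
    stop("prevalences and rrs must have equal length")
  if (any(prevalences < 0)) stop("prevalences must be nonnegative")
  if (sum(prevalences) > 1 + 1e-12) stop("prevalences must sum to <= 1")
  if (any(rrs <= 0)) stop("relative risks must be positive")
  s <- sum(prevalences * (rrs - 1))
  denom <- 1 + s
  if (denom <= 0)
    stop("pathological protective inputs: 1 + sum p_i (RR_i - 1) <= 0")
  s / denom
}

#' Difference between scenario and baseline PARF
#'
#' @param parf_scenario PARF under the scenario prevalence distribution.
#' @param parf_baseline PARF under the baseline distribution (PARF').
#' @return `parf_scenario - parf_baseline`; positive when the scenario
#'   carries more exposure, negative when less.
#' @export
delta_parf <- function(parf_scenario, parf_baseline) {
  stopifnot(all(abs(parf_scenario) < 1), all(abs(parf_baseline) < 1))
  parf_scenario - parf_baseline
}

#' Rescale a transition probability for a change in exposure distribution
#'
#' Under the attributable-fraction identity the total risk in a population
#' is `unexposed_risk / (1 - PARF)`, so moving from the baseline exposure
#' distribution to the scenario's multiplies the transition probability by
#' `(1 - parf_baseline) / (1 - parf_scenario)` — exactly, for any
#' unexposed risk.  To first order in small PARFs this is
#' `tp * (1 + delta_parf)`.  Results are clipped to the unit interval with
#' a warning
#' if the rescaling would exceed 1.
#'
#' @param tp_baseline transition probability under the baseline scenario.
#' @param parf_baseline,parf_scenario attributable fractions (< 1).
#' @return modified transition probability, vectorised.
#' @export
apply_parf <- function(tp_baseline, parf_baseline, parf_scenario) {
  if (any(tp_baseline < 0 | tp_baseline > 1))
    stop("tp_baseline must lie in [0,1]")
  if (any(parf_baseline >= 1) || any(parf_scenario >= 1))
    stop("PARFs must be < 1")
  out <- tp_baseline * (1 - parf_baseline) / (1 - parf_scenario)
  if (any(out > 1)) {
    warning("modified transition probability exceeded 1; clipped",
            call. = FALSE)
    out <- pmin(out, 1)
  }
  pmax(out, 0)
}

#' Duration-stratified PARF table for all affected transitions
#'
#' For every affected transition family, 10-year age band, sex and year,
#' computes the multi-category PARF under the scenario's evolved duration
#' distribution, the PARF under the baseline distribution (PARF'), and
#' their difference.  The category relative risks combine the family's base
#' RR with the geometric duration escalation
#' (see [duration_adjusted_rr()]).
#'
#' @param duration_prev_scenario,duration_prev_baseline either a
#'   band x sex x 6 array (a single year) or a function `f(year)` returning
#'   such an array — typically a closure over [evolve_duration()].
#' @param rr_set data frame with columns `transition`, `base_rr`,
#'   `duration_multiplier` (as in `bundle$rr_set`).
#' @param years calendar years to tabulate.
#' @return object of class `parf_table`: a family x band x sex x year
#'   numeric array of `delta_parf` values, with matching `parf_scenario`
#'   and `parf_baseline` arrays as attributes; convert with
#'   [as.data.frame.parf_table()].
#' @export
build_parf_table <- function(duration_prev_scenario, duration_prev_baseline,
                             rr_set, years) {
  fams <- names(bam_transition_families())
  if (!all(fams %in% rr_set$transition))
    stop("rr_set must cover all transition families")
  get_dp <- function(dp, year) if (is.function(dp)) dp(year) else dp
  dp0 <- get_dp(duration_prev_scenario, years[1])
  bands <- dimnames(dp0)[[1]]
  sexes <- dimnames(dp0)[[2]]
  dims <- c(length(fams), length(bands), length(sexes), length(years))
  dn <- list(transition = fams, age_band = bands, sex = sexes,
             year = as.character(years))
  ps <- array(NA_real_, dims, dimnames = dn)
  pb <- array(NA_real_, dims, dimnames = dn)
  for (yi in seq_along(years)) {
    dps <- get_dp(duration_prev_scenario, years[yi])
    dpb <- get_dp(duration_prev_baseline, years[yi])
    if (!identical(dim(dps), dim(dpb)))
      stop("scenario and baseline duration prevalences cover different strata")
    for (fi in seq_along(fams)) {
      row <- rr_set[rr_set$transition == fams[fi], ]
      rrs <- duration_adjusted_rr(row$base_rr[1], row$duration_multiplier[1],
                                  0:5)
      for (b in seq_along(bands)) for (s in seq_along(sexes)) {
        ps[fi, b, s, yi] <- parf_multicategory(dps[b, s, ], rrs)
        pb[fi, b, s, yi] <- parf_multicategory(dpb[b, s, ], rrs)
      }
    }
  }
  delta <- ps - pb
  structure(delta, parf_scenario = ps, parf_baseline = pb,
            class = c("parf_table", "array"))
}

#' @export
#' @rdname build_parf_table
#' @param x a `parf_table`.
#' @param ... unused.
as.data.frame.parf_table <- function(x, ...) {
  d <- as.data.frame.table(unclass(x), responseName = "delta_parf",
                           stringsAsFactors = FALSE)
  d$parf_scenario <- as.vector(attr(x, "parf_scenario"))
  d$parf_baseline <- as.vector(attr(x, "parf_baseline"))
  d$year <- as.integer(d$year)
  d
}

#' @export
print.parf_table <- function(x, ...) {
  dn <- dimnames(x)
  cat("PARF table: ", length(dn$transition), " transitions x ",
      length(dn$age_band), " age bands x ", length(dn$sex), " sexes x ",
      length(dn$year), " years\n", sep = "")
  cat("  delta PARF range: ",
      paste(format(range(x), digits = 3), collapse = " to "), "\n", sep = "")
  invisible(x)
}
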