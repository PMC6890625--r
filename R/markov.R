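#' Advance the population by one annual cycle
#'
#' One model cycle applies, in order: (1) the one-year transition matrices
#' to every (age, sex) cohort; (2) ageing by one year, with the terminal
#' age group open-ended (its survivors remain there); (3) injection of the
#' new entry cohort at the youngest age in the entry state.  Flows record
#' every cell-to-cell movement before ageing.
#'
#' The function is dimension-generic: it accepts any number of ages, sexes
#' and states, so small toy systems can be stepped with the same code as
#' the full ten-state model.
#'
#' @param counts age x sex x state array of occupancy at the start of the
#'   cycle.
#' @param transitions age x sex x state x state array of row-stochastic
#'   one-year transition matrices.
#' @param entry_cohort persons entering at the youngest age (a scalar total
#'   split equally across sexes, or a vector of length `n_sex`; default 0).
#' @param entry_state index (or name) of the state entrants occupy
#'   (default 1, the disease-free state).
#' @return list with `counts` (occupancy at the start of the next cycle)
#'   and `flows` (age x sex x from x to array of movements during the
#'   cycle, indexed by age at the start of the cycle).
#' @export
step_year <- function(counts, transitions, entry_cohort = 0,
                      entry_state = 1L) {
  dc <- dim(counts); dt <- dim(transitions)
  if (length(dc) != 3 || length(dt) != 4 || !all(dt[1:3] == dc) ||
      dt[3] != dt[4])
    stop("counts and transitions cover different strata")
  n_age <- dc[1]; n_sex <- dc[2]; n_state <- dc[3]
  if (length(entry_cohort) == 1)
    entry_cohort <- rep(entry_cohort / n_sex, n_sex)  # total, split equally
  if (length(entry_cohort) != n_sex)
    stop("entry_cohort must be scalar or length n_sex")
  flows <- array(0, dim = c(n_age, n_sex, n_state, n_state),
                 dimnames = dimnames(transitions))
  post <- array(0, dim = dc)
  for (s in seq_len(n_sex)) {
    M <- counts[, s, , drop = TRUE]
    if (n_age == 1) M <- matrix(M, 1, n_state)
    P_s <- array(transitions[, s, , ], dim = c(n_age, n_state, n_state))
    # F[a, i, j] = M[a, i] * P[a, i, j]; column-major layout makes the
    # elementwise product with the recycled occupancy matrix exact
    F_s <- P_s * as.vector(M)
    flows[, s, , ] <- F_s
    post[, s, ] <- colSums(aperm(F_s, c(2, 1, 3)))
  }
  if (any(post < 0))
    stop("negative occupancy produced during transition step")
  new_counts <- array(0, dim = dc, dimnames = dimnames(counts))
  if (n_age > 1) {
    new_counts[2:n_age, , ] <- post[1:(n_age - 1), , ]
    new_counts[n_age, , ] <- new_counts[n_age, , ] + post[n_age, , ]
  } else {
    new_counts[1, , ] <- post[1, , ]
  }
  if (is.character(entry_state))
    entry_state <- match(entry_state, dimnames(counts)[[3]])
  for (s in seq_len(n_sex))
    new_counts[1, s, entry_state] <- new_counts[1, s, entry_state] +
      entry_cohort[s]
  list(counts = new_counts, flows = flows)
}

# projected_mortality data frame -> rate lookup array [band5, sex, cause, year]
.mortality_rate_array <- function(projected_mortality, years) {
  bands <- age_bands_5y()
  sexes <- c("male", "female")
  causes <- c("cvd", "noncvd")
  pm <- projected_mortality[projected_mortality$year %in% years, ]
  have_years <- sort(unique(pm$year))
  if (!all(years %in% have_years))
    stop("projected mortality is missing years: ",
         paste(setdiff(years, have_years), collapse = ", "))
  arr <- array(NA_real_, dim = c(13, 2, 2, length(years)),
               dimnames = list(age_band = bands, sex = sexes, cause = causes,
                               year = as.character(years)))
  arr[cbind(match(pm$age_band, bands), match(pm$sex, sexes),
            match(pm$cause, causes), match(pm$year, years))] <- pm$rate
  if (any(is.na(arr)))
    stop("projected mortality grid is incomplete over band x sex x cause")
  arr
}

#' Run the open-cohort projection
#'
#' Advances the synthetic population annually from the first to the last
#' requested year.  Death-transition cells follow the projected mortality
#' trends: for every state, age and sex a calibration factor is fixed so
#' the start-year death probability reproduces the bundle's transition set
#' (`p = 1 - exp(-rate * calib)`), then the projected stratum rate for each
#' later year is pushed through the same map, preserving the relative
#' ordering of state-specific death risks while tracking the declining
#' trend.  When a PARF table is supplied, each affected cell is rescaled by
#' `(1 - PARF') / (1 - PARF)` for its age band, sex and year before the
#' step (see [apply_parf()]).  Stay-probabilities absorb the residual so
#' every row remains stochastic; a negative residual is a hard error.
#'
#' The engine is deterministic: it propagates expected occupancy
#' (fractional persons), not simulated individuals.
#'
#' @param bundle an [generate_inputs()] bundle.
#' @param projected_mortality a [project_mortality()] result covering all
#'   simulated years.
#' @param parf_table optional [build_parf_table()] result; `NULL` means an
#'   unmodified (baseline) run.  Years missing from the table leave the
#'   transitions unmodified (the table typically starts at the scenario
#'   reference year).
#' @param years calendar years to simulate (default: the bundle's
#'   `start_year:end_year`).
#' @param entry_cohort annual entrants at the youngest age (scalar or
#'   vector over years; default from the bundle config, split equally by
#'   sex).
#' @return object of class `bam_projection`: list with `counts`
#'   (year x age x sex x state occupancy at the start of each year),
#'   `flows` (year x age x sex x from x to movements during each year; the
#'   final year has no flows), `years`, `entry` and `scenario` label.
#' @export
run_projection <- function(bundle, projected_mortality, parf_table = NULL,
                           years = NULL, entry_cohort = NULL) {
  stopifnot(inherits(bundle, "input_bundle"))
  cfg <- bundle$config
  if (is.null(years)) years <- cfg$start_year:cfg$end_year
  if (is.null(entry_cohort)) entry_cohort <- cfg$annual_entry_cohort
  n_years <- length(years)
  if (length(entry_cohort) == 1) entry_cohort <- rep(entry_cohort, n_years)
  ages <- cfg$age_min:cfg$age_max
  n_age <- length(ages)
  states <- bam_states()
  sexes <- c("male", "female")
  s <- .S

  rates <- .mortality_rate_array(projected_mortality, years)
  b5 <- match(band5_of_age(ages), age_bands_5y())
  b10 <- match(band10_of_age(ages), age_bands_10y())

  # per-(age, sex, state, cause) calibration from the bundle's start-year
  # death probabilities and the fitted start-year stratum rate
  calib <- array(NA_real_, dim = c(n_age, 2, 8, 2))
  y0 <- as.character(years[1])
  for (si in 1:2) for (ci in 1:2) {
    dcol <- if (ci == 1) s["death_cvd"] else s["death_noncvd"]
    r0 <- rates[b5, si, ci, y0]
    for (st in 1:8) {
      p_fix <- bundle$transitions[, si, st, dcol]
      calib[, si, st, ci] <- -log(pmax(1 - p_fix, 1e-12)) / r0
    }
  }

  fams <- names(bam_transition_families())
  fam_cells <- bam_transition_families()
  parf_years <- if (!is.null(parf_table)) dimnames(parf_table)$year else NULL

  counts <- array(0, dim = c(n_years, n_age, 2, 10),
                  dimnames = list(year = years, age = ages, sex = sexes,
                                  state = states))
  flows <- array(0, dim = c(n_years, n_age, 2, 10, 10),
                 dimnames = list(year = years, age = ages, sex = sexes,
                                 from = states, to = states))
  counts[1, , , ] <- bundle$population

  cur <- bundle$population
  Pbase <- bundle$transitions
  P <- Pbase  # death columns, affected cells and diagonals are refreshed
              # in place each year; all other cells never change
  for (yi in seq_len(n_years - 1)) {
    ychr <- as.character(years[yi])
    for (si in 1:2) for (ci in 1:2) {
      dcol <- if (ci == 1) s["death_cvd"] else s["death_noncvd"]
      r_y <- rates[b5, si, ci, ychr]
      for (st in 1:8)
        P[, si, st, dcol] <- 1 - exp(-r_y * calib[, si, st, ci])
    }
    if (!is.null(parf_table) && ychr %in% parf_years) {
      for (fi in seq_along(fams)) {
        ps <- attr(parf_table, "parf_scenario")[fi, , , ychr]
        pb <- attr(parf_table, "parf_baseline")[fi, , , ychr]
        fac <- (1 - pb) / (1 - ps)  # [band10, sex]
        cells <- fam_cells[[fi]]
        for (r in seq_len(nrow(cells))) for (si in 1:2) {
          i <- cells[r, 1]; j <- cells[r, 2]
          if (j %in% .DEAD)  # death cells were just refreshed from rates
            P[, si, i, j] <- pmin(P[, si, i, j] * fac[b10, si], 1)
          else
            P[, si, i, j] <- pmin(Pbase[, si, i, j] * fac[b10, si], 1)
        }
      }
    }
    for (i in .ALIVE) {
      off <- rowSums(matrix(P[, , i, -i], nrow = n_age * 2))
      stay <- 1 - off
      if (any(stay < -1e-9))
        stop("transition row exceeds probability 1 after modification ",
             "(year ", years[yi], ", state ", states[i], ")")
      P[, , i, i] <- pmax(stay, 0)
    }
    stepped <- step_year(cur, P,
                         entry_cohort = rep(entry_cohort[yi] / 2, 2),
                         entry_state = s[["free"]])
    flows[yi, , , , ] <- stepped$flows
    cur <- stepped$counts
    counts[yi + 1, , , ] <- cur
  }

  structure(list(counts = counts, flows = flows, years = years,
                 ages = ages, entry = entry_cohort,
                 scenario = if (is.null(parf_table)) "baseline" else "modified",
                 start_year = years[1]),
            class = "bam_projection")
}

#' Conservation error of a projection
#'
#' The model is closed apart from entrants: at every year, persons alive
#' plus cumulative deaths must equal the initial population plus cumulative
#' entrants.  Returns the maximum relative discrepancy over all years.
#'
#' @param proj a `bam_projection`.
#' @return scalar maximum relative conservation error.
#' @export
conservation_error <- function(proj) {
  tot_alive <- apply(proj$counts[, , , .ALIVE, drop = FALSE], 1, sum)
  tot_dead <- apply(proj$counts[, , , .DEAD, drop = FALSE], 1, sum)
  n_years <- length(proj$years)
  entries <- c(0, cumsum(proj$entry[seq_len(n_years - 1)]))
  expected <- tot_alive[1] + tot_dead[1] + entries
  max(abs((tot_alive + tot_dead) - expected) / expected)
}

#' @export
print.bam_projection <- function(x, ...) {
  ny <- length(x$years)
  cat("Ten-state open-cohort projection, ", x$years[1], "-", x$years[ny],
      " (", x$scenario, " transitions)\n", sep = "")
  alive0 <- sum(x$counts[1, , , .ALIVE])
  alive1 <- sum(x$counts[ny, , , .ALIVE])
  cat(sprintf("  alive: %s (%d) -> %s (%d)\n",
              format(round(alive0), big.mark = ","), x$years[1],
              format(round(alive1), big.mark = ","), x$years[ny]))
  cat(sprintf("  cumulative deaths: %s; conservation error %.2e\n",
              format(round(sum(x$counts[ny, , , .DEAD]) -
                             sum(x$counts[1, , , .DEAD])), big.mark = ","),
              conservation_error(x)))
  invisible(x)
}

#' @export
summary.bam_projection <- function(object, years = NULL, ...) {
  if (is.null(years))
    years <- intersect(c(2015, 2030, 2045, 2060), object$years)
  if (length(years) == 0) years <- range(object$years)
  rows <- lapply(years, function(y) {
    data.frame(
      year = y,
      alive_65plus = sum(object$counts[as.character(y),
                                       object$ages >= 65, , .ALIVE]),
      deaths = if (y < max(object$years))
        sum(object$flows[as.character(y), , , , .DEAD]) else NA_real_,
      incident_dementia = if (y < max(object$years))
        incident_cases(object, "dementia", y)$cases else NA_real_,
      incident_disability = if (y < max(object$years))
        incident_cases(object, "disability", y)$cases else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.bam_projection", "data.frame")
  out
}

#' @export
print.summary.bam_projection <- function(x, ...) {
  cat("Projection summary (population aged >= 65):\n")
  print.data.frame(format(x, big.mark = ",", digits = 3), row.names = FALSE)
  invisible(x)
}

#' Plot state occupancy through time
#'
#' Base-graphics view of the alive population aged 65+ by severity group.
#'
#' @param x a `bam_projection`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.bam_projection <- function(x, ...) {
  sel <- x$ages >= 65
  grp <- list(unimpaired = c(.S["free"], .S["cvd"]),
              cognitive_impairment = c(.S["ci"], .S["cvd_ci"]),
              disability = c(.S["dis"], .S["cvd_dis"]),
              dementia = c(.S["dem"], .S["cvd_dem"]))
  series <- sapply(grp, function(g)
    apply(x$counts[, sel, , g, drop = FALSE], 1, sum))
  graphics::matplot(x$years, series / 1e3, type = "l", lty = 1, lwd = 2,
                    xlab = "year", ylab = "persons aged 65+ (thousands)",
                    main = "Projected occupancy by severity group", ...)
  graphics::legend("topleft", legend = names(grp), lty = 1, lwd = 2,
                   col = seq_along(grp), bty = "n")
  invisible(x)
}
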