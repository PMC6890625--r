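#' Configuration for the synthetic input generator
#'
#' Bundles every tunable of the synthetic-data generator with validated
#' defaults.  The defaults describe a stylised England-and-Wales-like
#' population: roughly one million adults aged 35 and over, cause-specific
#' mortality declining log-linearly since 1990 (faster for CVD than for
#' non-CVD causes), a national type 2 diabetes prevalence of 8.6% in 2015
#' split over six duration categories, and per-transition relative risks on
#' the scale reported by meta-analyses of diabetes and cardiovascular,
#' cognitive and disability outcomes.
#'
#' @param seed integer; drives every random component of the bundle.
#' @param start_year first simulated calendar year (population census year).
#' @param end_year last simulated calendar year.
#' @param age_min,age_max closed age range; `age_max` is an open-ended
#'   terminal group (people remain at that age until death).
#' @param total_population persons aged `age_min`+ in `start_year`.
#' @param annual_entry_cohort persons entering at age `age_min` (disease
#'   free) each year.
#' @param mortality_decline_cvd,mortality_decline_noncvd per-year slopes of
#'   log mortality rates, must be <= 0.
#' @param mortality_noise_sd standard deviation of seeded Gaussian noise on
#'   the log mortality rates.
#' @param transition_noise_sd standard deviation of seeded log-normal jitter
#'   on the non-death transition probabilities.
#' @param baseline_diabetes_prevalence national total diabetes prevalence at
#'   the 2015 reference (proportion).
#' @param duration_multiplier relative-risk escalation per 5 additional
#'   years of diabetes duration (applied as `multiplier^k` for duration
#'   category `k` = 0..5).
#' @param rr_specs data frame with columns `transition`, `base_rr`,
#'   `log_se`: one row per affected transition family
#'   (see [bam_transition_families()]).
#'
#' @return object of class `synthetic_config` (a validated list).
#' @seealso [generate_inputs()]
#' @export
synthetic_config <- function(seed = 1L,
                             start_year = 2006L,
                             end_year = 2060L,
                             age_min = 35L,
                             age_max = 100L,
                             total_population = 1e6,
                             annual_entry_cohort = 14000,
                             mortality_decline_cvd = -0.035,
                             mortality_decline_noncvd = -0.012,
                             mortality_noise_sd = 0.03,
                             transition_noise_sd = 0.05,
                             baseline_diabetes_prevalence = 0.086,
                             duration_multiplier = 1.13,
                             rr_specs = default_rr_specs()) {
  cfg <- list(seed = as.integer(seed), start_year = as.integer(start_year),
              end_year = as.integer(end_year), age_min = as.integer(age_min),
              age_max = as.integer(age_max),
              total_population = total_population,
              annual_entry_cohort = annual_entry_cohort,
              mortality_decline_cvd = mortality_decline_cvd,
              mortality_decline_noncvd = mortality_decline_noncvd,
              mortality_noise_sd = mortality_noise_sd,
              transition_noise_sd = transition_noise_sd,
              baseline_diabetes_prevalence = baseline_diabetes_prevalence,
              duration_multiplier = duration_multiplier,
              rr_specs = rr_specs)
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid synthetic_config field '%s': %s", field, why),
         call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$seed)) bad("seed", "must be a single finite number")
  if (!num1(cfg$start_year) || !num1(cfg$end_year) ||
      cfg$end_year <= cfg$start_year)
    bad("end_year", "must be a year after start_year")
  if (cfg$age_min >= cfg$age_max) bad("age_max", "must exceed age_min")
  if (cfg$age_min != 35L || cfg$age_max != 100L)
    bad("age_range", "generator supports the 35-100+ range only")
  if (!num1(cfg$total_population) || cfg$total_population <= 0)
    bad("total_population", "must be positive")
  if (!num1(cfg$annual_entry_cohort) || cfg$annual_entry_cohort < 0)
    bad("annual_entry_cohort", "must be nonnegative")
  if (!num1(cfg$mortality_decline_cvd) || cfg$mortality_decline_cvd > 0)
    bad("mortality_decline_cvd", "must be <= 0 (declining log rates)")
  if (!num1(cfg$mortality_decline_noncvd) || cfg$mortality_decline_noncvd > 0)
    bad("mortality_decline_noncvd", "must be <= 0 (declining log rates)")
  if (!num1(cfg$mortality_noise_sd) || cfg$mortality_noise_sd < 0)
    bad("mortality_noise_sd", "must be >= 0")
  if (!num1(cfg$transition_noise_sd) || cfg$transition_noise_sd < 0)
    bad("transition_noise_sd", "must be >= 0")
  p <- cfg$baseline_diabetes_prevalence
  if (!num1(p) || p < 0 || p > 1)
    bad("baseline_diabetes_prevalence", "must be a proportion in [0,1]")
  if (!num1(cfg$duration_multiplier) || cfg$duration_multiplier <= 0)
    bad("duration_multiplier", "must be > 0")
  rs <- cfg$rr_specs
  need <- c("transition", "base_rr", "log_se")
  if (!is.data.frame(rs) || !all(need %in% names(rs)))
    bad("rr_specs", "must be a data frame with transition, base_rr, log_se")
  fams <- names(bam_transition_families())
  if (!setequal(rs$transition, fams))
    bad("rr_specs", paste("must cover exactly the families:",
                          paste(fams, collapse = ", ")))
  if (any(rs$base_rr <= 0) || any(rs$log_se < 0))
    bad("rr_specs", "base_rr must be > 0 and log_se >= 0")
  rec <- rs$base_rr[rs$transition == "disability_recovery"]
  oth <- rs$base_rr[rs$transition != "disability_recovery"]
  if (rec > 1) bad("rr_specs", "disability_recovery RR must be <= 1")
  if (any(oth < 1)) bad("rr_specs", "non-recovery RRs must be >= 1")
  invisible(cfg)
}

#' Default relative-risk specification
#'
#' Point estimates (vs no diabetes, BMI-adjusted scale) and log-scale
#' standard errors for the six affected transition families.  Magnitudes
#' follow the meta-analytic literature on diabetes and vascular, cognitive
#' and disability outcomes: roughly a doubling of CVD incidence, 1.5-1.8
#' for cause-specific death and disability, ~1.45 for cognitive decline,
#' and impeded (RR < 1) recovery from disability.
#'
#' @return data frame with columns `transition`, `base_rr`, `log_se`.
#' @export
default_rr_specs <- function() {
  data.frame(
    transition = c("cvd_incidence", "cognitive_incidence",
                   "disability_incidence", "disability_recovery",
                   "cvd_death", "noncvd_death"),
    base_rr = c(2.00, 1.45, 1.65, 0.85, 1.80, 1.50),
    log_se = c(0.06, 0.08, 0.07, 0.10, 0.07, 0.05),
    stringsAsFactors = FALSE
  )
}

.ilogit <- function(z) 1 / (1 + exp(-z))

# deterministic (noise-free) log mortality rate per band midpoint, sex, cause
.log_mortality_line <- function(mid, sex, cause, year, cfg) {
  if (cause == "cvd") {
    a <- -10.1 + 0.127 * (mid - 35)  # Gompertz-like in age
    if (sex == "female") a <- a + log(0.6)
    a + cfg$mortality_decline_cvd * (year - 1990)
  } else {
    a <- -6.9 + 0.083 * (mid - 35)
    if (sex == "female") a <- a + log(0.8)
    a + cfg$mortality_decline_noncvd * (year - 1990)
  }
}

# state-specific multipliers applied to the band death rate.  CVD states are
# far likelier to die of CVD; dementia and disability raise non-CVD death.
.death_factors <- function() {
  list(
    cvd = c(free = 0.40, cvd = 3.00, ci = 0.50, cvd_ci = 3.30,
            dis = 0.60, cvd_dis = 3.60, dem = 0.70, cvd_dem = 4.00),
    noncvd = c(free = 0.80, cvd = 1.00, ci = 1.10, cvd_ci = 1.30,
               dis = 1.60, cvd_dis = 1.80, dem = 2.20, cvd_dem = 2.40)
  )
}

#' Generate a complete synthetic input bundle
#'
#' Produces every input the projection pipeline needs, reproducibly from
#' the seed in `config`: an initial population by single year of age, sex
#' and state; a row-stochastic one-year transition probability set; a
#' 1990-2016 cause-specific mortality series declining log-linearly with
#' seeded noise; the 2014-reference diabetes duration-category prevalence
#' by 10-year age band and sex; and the relative-risk set.
#'
#' Structural guarantees: transition rows sum to 1 (to machine precision),
#' death states are absorbing, structurally forbidden cells are exactly 0,
#' combined one-year death probability is non-decreasing in age within each
#' sex and state, and the six duration-category prevalences sum to the
#' stratum total implied by `baseline_diabetes_prevalence`.
#'
#' @param config a [synthetic_config()].
#' @return object of class `input_bundle`: list with elements `config`,
#'   `population` (age x sex x state array of counts at `start_year`),
#'   `transitions` (age x sex x 10 x 10 array), `mortality` (data frame:
#'   year, age_band, sex, cause, rate), `duration_prevalence`
#'   (band x sex x 6 array), `rr_set` (data frame).
#' @export
generate_inputs <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)

  ages <- cfg$age_min:cfg$age_max
  n_age <- length(ages)
  sexes <- c("male", "female")
  states <- bam_states()

  # --- mortality series 1990..2016 -----------------------------------------
  bands <- age_bands_5y()
  mids <- .band5_midpoint(bands)
  years_obs <- 1990:2016
  grid <- expand.grid(year = years_obs, age_band = bands, sex = sexes,
                      cause = c("cvd", "noncvd"), stringsAsFactors = FALSE)
  log_line <- mapply(function(b, s, cs, y)
    .log_mortality_line(.band5_midpoint(b), s, cs, y, cfg),
    grid$age_band, grid$sex, grid$cause, grid$year)
  grid$rate <- exp(log_line + stats::rnorm(nrow(grid), 0,
                                           cfg$mortality_noise_sd))
  mortality <- grid[order(grid$cause, grid$sex, grid$age_band, grid$year), ]
  rownames(mortality) <- NULL

  # --- initial population ---------------------------------------------------
  w <- exp(-0.013 * (ages - 35)) * exp(-pmax(ages - 75, 0)^2 / 500)
  w <- w * exp(stats::rnorm(n_age, 0, 0.02))
  share_f <- pmin(0.5 + 0.002 * (ages - 35), 0.65)
  pop_age <- cfg$total_population * w / sum(w)

  prev_cvd <- .ilogit(-5.84 + 0.058 * ages)
  prev_ci <- .ilogit(-10.9 + 0.108 * ages)
  prev_dem <- .ilogit(-14.6 + 0.1435 * ages)
  prev_dis <- .ilogit(-9.44 + 0.100 * ages)
  sev_excess <- pmax(prev_ci + prev_dem + prev_dis - 0.95, 0)
  scl <- ifelse(sev_excess > 0,
                0.95 / (prev_ci + prev_dem + prev_dis), 1)
  prev_ci <- prev_ci * scl; prev_dem <- prev_dem * scl; prev_dis <- prev_dis * scl
  prev_unimp <- 1 - prev_ci - prev_dem - prev_dis

  population <- array(0, dim = c(n_age, 2, 10),
                      dimnames = list(age = ages, sex = sexes, state = states))
  sev <- cbind(prev_unimp, prev_ci, prev_dis, prev_dem)  # free, ci, dis, dem order
  for (si in 1:2) {
    n_sex <- pop_age * if (si == 2) share_f else (1 - share_f)
    population[, si, .S["free"]]    <- n_sex * (1 - prev_cvd) * sev[, 1]
    population[, si, .S["ci"]]      <- n_sex * (1 - prev_cvd) * sev[, 2]
    population[, si, .S["dis"]]     <- n_sex * (1 - prev_cvd) * sev[, 3]
    population[, si, .S["dem"]]     <- n_sex * (1 - prev_cvd) * sev[, 4]
    population[, si, .S["cvd"]]     <- n_sex * prev_cvd * sev[, 1]
    population[, si, .S["cvd_ci"]]  <- n_sex * prev_cvd * sev[, 2]
    population[, si, .S["cvd_dis"]] <- n_sex * prev_cvd * sev[, 3]
    population[, si, .S["cvd_dem"]] <- n_sex * prev_cvd * sev[, 4]
  }

  # --- transition probability set ------------------------------------------
  transitions <- .build_transitions(ages, cfg)

  # --- duration prevalence (2014/2015 reference) ---------------------------
  duration_prevalence <- .build_duration_prevalence(cfg)

  # --- relative risks -------------------------------------------------------
  rr_set <- cfg$rr_specs
  rr_set$duration_multiplier <- cfg$duration_multiplier

  bundle <- list(config = cfg, population = population,
                 transitions = transitions, mortality = mortality,
                 duration_prevalence = duration_prevalence, rr_set = rr_set)
  class(bundle) <- "input_bundle"
  bundle
}

# one-year transition array [age, sex, from, to]; rows sum to 1 exactly.
.build_transitions <- function(ages, cfg) {
  n_age <- length(ages)
  s <- .S
  P <- array(0, dim = c(n_age, 2, 10, 10),
             dimnames = list(age = ages, sex = c("male", "female"),
                             from = bam_states(), to = bam_states()))
  a <- ages
  df <- .death_factors()
  for (si in 1:2) {
    sex <- c("male", "female")[si]
    sex_mult <- if (si == 2) 0.75 else 1
    p_cvd <- .ilogit(-10.2 + 0.075 * a) * sex_mult
    p_ci  <- .ilogit(-11.5 + 0.100 * a)
    p_dem_ci  <- .ilogit(-9.5 + 0.075 * a)
    p_dem_dis <- 0.6 * p_dem_ci
    p_dis <- .ilogit(-11.0 + 0.085 * a)
    p_rec <- .ilogit(1.5 - 0.060 * a)

    jit <- function(p) {
      pmin(p * exp(stats::rnorm(n_age, 0, cfg$transition_noise_sd)), 0.45)
    }
    # morbidity cells (jittered)
    P[, si, s["free"], s["cvd"]] <- jit(p_cvd)
    P[, si, s["ci"],  s["cvd_ci"]] <- jit(p_cvd)
    P[, si, s["dis"], s["cvd_dis"]] <- jit(p_cvd)
    P[, si, s["dem"], s["cvd_dem"]] <- jit(p_cvd)
    P[, si, s["free"], s["ci"]] <- jit(p_ci)
    P[, si, s["cvd"],  s["cvd_ci"]] <- jit(1.3 * p_ci)
    P[, si, s["ci"],  s["dem"]] <- jit(p_dem_ci)
    P[, si, s["cvd_ci"], s["cvd_dem"]] <- jit(1.2 * p_dem_ci)
    P[, si, s["dis"], s["dem"]] <- jit(p_dem_dis)
    P[, si, s["cvd_dis"], s["cvd_dem"]] <- jit(1.2 * p_dem_dis)
    P[, si, s["free"], s["dis"]] <- jit(p_dis)
    P[, si, s["ci"],  s["dis"]] <- jit(1.8 * p_dis)
    P[, si, s["cvd"], s["cvd_dis"]] <- jit(1.5 * p_dis)
    P[, si, s["cvd_ci"], s["cvd_dis"]] <- jit(1.8 * 1.5 * p_dis)
    P[, si, s["dis"], s["free"]] <- jit(p_rec)
    P[, si, s["cvd_dis"], s["cvd"]] <- jit(0.8 * p_rec)

    # death cells (deterministic so age-monotonicity is built in)
    mid <- a  # single-year ages use their own age, not the band midpoint
    rate_cvd <- exp(.log_mortality_line(mid, sex, "cvd", cfg$start_year, cfg))
    rate_ncv <- exp(.log_mortality_line(mid, sex, "noncvd", cfg$start_year, cfg))
    for (st in bam_alive_states()) {
      P[, si, s[st], s["death_cvd"]] <-
        1 - exp(-rate_cvd * df$cvd[st])
      P[, si, s[st], s["death_noncvd"]] <-
        1 - exp(-rate_ncv * df$noncvd[st])
    }
  }
  # absorbing death states, then stay-probabilities as the residual
  P[, , s["death_cvd"], s["death_cvd"]] <- 1
  P[, , s["death_noncvd"], s["death_noncvd"]] <- 1
  for (i in .ALIVE) {
    off <- apply(P[, , i, -i, drop = FALSE], c(1, 2), sum)
    if (any(off >= 1))
      stop("synthetic transition rows exceed probability 1; ",
           "reduce transition_noise_sd")
    P[, , i, i] <- 1 - off
  }
  P
}

.build_duration_prevalence <- function(cfg) {
  bands <- age_bands_10y()
  cats <- duration_categories()
  # total diabetes prevalence by band (male shape), scaled to the configured
  # national prevalence relative to the 8.6% reference
  shape_m <- c(0.040, 0.075, 0.115, 0.150, 0.155, 0.130)
  scale <- cfg$baseline_diabetes_prevalence / 0.086
  share_young <- c(0.45, 0.30, 0.15, 0.06, 0.03, 0.01)
  share_old <- c(0.15, 0.18, 0.20, 0.17, 0.14, 0.16)
  dp <- array(0, dim = c(6, 2, 6),
              dimnames = list(age_band = bands, sex = c("male", "female"),
                              duration = cats))
  for (b in 1:6) {
    wmix <- (b - 1) / 5
    share <- (1 - wmix) * share_young + wmix * share_old
    share <- share / sum(share)
    dp[b, 1, ] <- shape_m[b] * scale * share
    dp[b, 2, ] <- 0.85 * shape_m[b] * scale * share
  }
  dp
}

#' Diabetes duration categories
#'
#' @return character vector of the six duration-category labels.
#' @export
duration_categories <- function() {
  c("<5", "5-9", "10-14", "15-19", "20-24", ">=25")
}

#' @export
print.input_bundle <- function(x, ...) {
  cat("Synthetic input bundle (seed ", x$config$seed, ")\n", sep = "")
  cat("  population : ", format(round(sum(x$population)), big.mark = ","),
      " persons aged ", x$config$age_min, "-", x$config$age_max,
      "+ in ", x$config$start_year, "\n", sep = "")
  cat("  transitions: ", paste(dim(x$transitions), collapse = " x "),
      " (age x sex x from x to)\n", sep = "")
  cat("  mortality  : ", nrow(x$mortality), " stratum-year rates, ",
      min(x$mortality$year), "-", max(x$mortality$year), "\n", sep = "")
  cat("  duration prevalence reference; national total ",
      format(x$config$baseline_diabetes_prevalence * 100), "%\n", sep = "")
  invisible(x)
}

# --- bundle I/O -------------------------------------------------------------

#' Write / read an input bundle as delimited text
#'
#' Serialises the bundle as a directory of long-format CSV tables
#' (`population.csv`, `transitions.csv`, `mortality.csv`,
#' `duration_prevalence.csv`, `rr.csv`) plus the configuration as JSON.
#' `read_input_bundle()` restores a bundle written this way.
#'
#' @param bundle an `input_bundle`.
#' @param dir directory (created if missing).
#' @return `write_input_bundle()` returns `dir` invisibly;
#'   `read_input_bundle()` returns the restored `input_bundle`.
#' @export
write_input_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "input_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- as.data.frame.table(bundle$population, responseName = "count",
                             stringsAsFactors = FALSE)
  pop$year <- bundle$config$start_year
  utils::write.csv(pop[, c("year", "age", "sex", "state", "count")],
                   file.path(dir, "population.csv"), row.names = FALSE)
  tr <- as.data.frame.table(bundle$transitions, responseName = "probability",
                            stringsAsFactors = FALSE)
  names(tr)[names(tr) == "from"] <- "from_state"
  names(tr)[names(tr) == "to"] <- "to_state"
  utils::write.csv(tr, file.path(dir, "transitions.csv"), row.names = FALSE)
  utils::write.csv(bundle$mortality, file.path(dir, "mortality.csv"),
                   row.names = FALSE)
  dp <- as.data.frame.table(bundle$duration_prevalence,
                            responseName = "prevalence",
                            stringsAsFactors = FALSE)
  names(dp)[names(dp) == "duration"] <- "duration_category"
  utils::write.csv(dp, file.path(dir, "duration_prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$rr_set, file.path(dir, "rr.csv"), row.names = FALSE)
  cfg <- bundle$config
  class(cfg) <- NULL
  cfg$rr_specs <- NULL  # stored separately in rr.csv
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_input_bundle
#' @export
read_input_bundle <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  rr <- utils::read.csv(file.path(dir, "rr.csv"), stringsAsFactors = FALSE)
  cfg <- synthetic_config(
    seed = cfgl$seed, start_year = cfgl$start_year, end_year = cfgl$end_year,
    age_min = cfgl$age_min, age_max = cfgl$age_max,
    total_population = cfgl$total_population,
    annual_entry_cohort = cfgl$annual_entry_cohort,
    mortality_decline_cvd = cfgl$mortality_decline_cvd,
    mortality_decline_noncvd = cfgl$mortality_decline_noncvd,
    mortality_noise_sd = cfgl$mortality_noise_sd,
    transition_noise_sd = cfgl$transition_noise_sd,
    baseline_diabetes_prevalence = cfgl$baseline_diabetes_prevalence,
    duration_multiplier = cfgl$duration_multiplier[1],
    rr_specs = rr[, c("transition", "base_rr", "log_se")])

  ages <- cfg$age_min:cfg$age_max
  sexes <- c("male", "female")
  states <- bam_states()
  pop <- utils::read.csv(file.path(dir, "population.csv"),
                         stringsAsFactors = FALSE)
  population <- array(0, dim = c(length(ages), 2, 10),
                      dimnames = list(age = ages, sex = sexes, state = states))
  population[cbind(match(pop$age, ages), match(pop$sex, sexes),
                   match(pop$state, states))] <- pop$count
  tr <- utils::read.csv(file.path(dir, "transitions.csv"),
                        stringsAsFactors = FALSE)
  transitions <- array(0, dim = c(length(ages), 2, 10, 10),
                       dimnames = list(age = ages, sex = sexes,
                                       from = states, to = states))
  transitions[cbind(match(tr$age, ages), match(tr$sex, sexes),
                    match(tr$from_state, states),
                    match(tr$to_state, states))] <- tr$probability
  mortality <- utils::read.csv(file.path(dir, "mortality.csv"),
                               stringsAsFactors = FALSE)
  dp <- utils::read.csv(file.path(dir, "duration_prevalence.csv"),
                        stringsAsFactors = FALSE)
  duration_prevalence <- array(
    0, dim = c(6, 2, 6),
    dimnames = list(age_band = age_bands_10y(), sex = sexes,
                    duration = duration_categories()))
  duration_prevalence[cbind(match(dp$age_band, age_bands_10y()),
                            match(dp$sex, sexes),
                            match(dp$duration_category,
                                  duration_categories()))] <- dp$prevalence
  rr$duration_multiplier <- cfg$duration_multiplier
  bundle <- list(config = cfg, population = population,
                 transitions = transitions, mortality = mortality,
                 duration_prevalence = duration_prevalence,
                 rr_set = rr)
  class(bundle) <- "input_bundle"
  bundle
}
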