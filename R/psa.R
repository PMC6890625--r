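#' Specification of the probabilistic sensitivity analysis
#'
#' Defines the sampling distributions for the Monte Carlo uncertainty
#' analysis.  Transition probabilities and duration prevalences are drawn
#' from beta distributions moment-matched to their point value and an
#' effective sample size (`shape1 = p * ess`, `shape2 = (1-p) * ess`, so
#' the sampling SD is `sqrt(p(1-p)/(ess+1))`); relative risks are drawn
#' log-normally around their point estimate with the published log-scale
#' standard error.  An infinite effective sample size, or a zero
#' `rr_se_scale`, makes the corresponding family degenerate (no
#' perturbation).
#'
#' @param n_iterations number of Monte Carlo draws (default 1000).
#' @param seed integer seed; the same seed reproduces the same draw
#'   sequence, and draw `k` is reproducible in isolation.
#' @param tp_ess effective sample size of the transition-probability betas
#'   (default 2000; `Inf` = degenerate).
#' @param prev_ess effective sample size of the duration-prevalence betas
#'   (default 2000; `Inf` = degenerate).
#' @param rr_se_scale multiplier on the log-RR standard errors (default 1;
#'   0 = degenerate).
#' @return object of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 1000L, seed = 1L, tp_ess = 2000,
                     prev_ess = 2000, rr_se_scale = 1) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (tp_ess <= 0 || prev_ess <= 0)
    stop("effective sample sizes must be positive (use Inf for degenerate)")
  if (rr_se_scale < 0) stop("rr_se_scale must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), tp_ess = tp_ess,
                 prev_ess = prev_ess, rr_se_scale = rr_se_scale),
            class = "psa_spec")
}

# beta draw moment-matched to mean p with effective sample size ess;
# p = 0 and p = 1 are fixed points, ess = Inf is degenerate
.beta_perturb <- function(p, ess) {
  if (!is.finite(ess)) return(p)
  out <- p
  idx <- which(p > 0 & p < 1)
  if (length(idx))
    out[idx] <- stats::rbeta(length(idx), p[idx] * ess, (1 - p[idx]) * ess)
  out
}

#' Draw one perturbed input set
#'
#' Applies the `psa_spec` distributions to a bundle: every structurally
#' permitted off-diagonal transition probability, every duration-category
#' prevalence, and every base relative risk is resampled around its point
#' value.  Transition rows are renormalised (the stay-probability absorbs
#' the residual; rows whose off-diagonal mass exceeds 1 are rescaled) so
#' the set remains row-stochastic, and death states stay absorbing.
#'
#' Draw `draw_index` under a given spec is fully reproducible: the RNG is
#' seeded from `(seed, draw_index)` only.
#'
#' @param bundle an [generate_inputs()] bundle (the point estimates).
#' @param spec a [psa_spec()].
#' @param draw_index positive integer identifying the draw.
#' @return a perturbed `input_bundle`.
#' @export
sample_inputs <- function(bundle, spec, draw_index) {
  stopifnot(inherits(bundle, "input_bundle"), inherits(spec, "psa_spec"))
  set.seed((abs(spec$seed) * 69091 + draw_index * 101) %% 2147483629L)
  out <- bundle

  P <- bundle$transitions
  n_age <- dim(P)[1]
  for (si in 1:2) for (i in .ALIVE) {
    for (j in setdiff(1:10, i)) {
      p <- P[, si, i, j]
      if (any(p > 0)) P[, si, i, j] <- .beta_perturb(p, spec$tp_ess)
    }
    off <- rowSums(array(P[, si, i, -i], dim = c(n_age, 9)))
    over <- off > 1
    if (any(over)) {
      scl <- ifelse(over, 1 / off, 1)
      for (j in setdiff(1:10, i)) P[, si, i, j] <- P[, si, i, j] * scl
      off <- pmin(off, 1)
    }
    P[, si, i, i] <- 1 - off
  }
  out$transitions <- P

  dp <- bundle$duration_prevalence
  dp[] <- .beta_perturb(as.vector(dp), spec$prev_ess)
  out$duration_prevalence <- dp

  rr <- bundle$rr_set
  if (spec$rr_se_scale > 0)
    rr$base_rr <- exp(stats::rnorm(nrow(rr), log(rr$base_rr),
                                   rr$log_se * spec$rr_se_scale))
  out$rr_set <- rr
  out
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Repeats the whole pipeline (duration evolution, PARF table, baseline and
#' scenario cohort runs, outcome extraction) for `n_iterations` perturbed
#' input sets and summarises every output quantity with percentile 95%
#' uncertainty intervals (2.5th and 97.5th empirical percentiles).  Within
#' each draw the scenario and the baseline share the same perturbed inputs
#' (common random numbers), so the uncertainty on scenario-vs-baseline
#' differences reflects parameter uncertainty rather than between-arm
#' Monte Carlo noise.  The point estimate column is the pipeline run at the
#' unperturbed inputs.
#'
#' Reported quantities, per reporting year and for the population aged
#' 65+: cumulative deaths, dementia and disability cases avoided
#' (baseline - scenario, negative = additional burden), cumulative
#' life-years gained, and the difference in the percentage of life spent
#' with disability (scenario - baseline).
#'
#' @param bundle an [generate_inputs()] bundle.
#' @param scenario a [diabetes_scenario()] or scenario name.
#' @param spec a [psa_spec()].
#' @param baseline_scenario reference trajectory (default `"baseline"`).
#' @param report_years years to summarise (default 2030, 2045, 2060).
#' @param projected_mortality optional precomputed mortality projection
#'   (mortality trends are not resampled).
#' @param reference_year see [project_scenario()].
#' @param keep_draws retain the draw-level matrix in the result
#'   (default TRUE).
#' @return object of class `psa_result`: data frame with columns
#'   `quantity`, `year`, `point`, `ui_low`, `ui_high`, `n_iterations`,
#'   `seed`; draw-level values in `attr(, "draws")` when kept.
#' @export
run_psa <- function(bundle, scenario, spec,
                    baseline_scenario = diabetes_scenario("baseline"),
                    report_years = c(2030, 2045, 2060),
                    projected_mortality = NULL, reference_year = 2015,
                    keep_draws = TRUE) {
  stopifnot(inherits(bundle, "input_bundle"), inherits(spec, "psa_spec"))
  if (is.character(scenario)) scenario <- diabetes_scenario(scenario)
  if (is.null(projected_mortality))
    projected_mortality <- project_mortality(bundle$mortality,
                                             horizon_year = bundle$config$end_year)

  eval_draw <- function(b) {
    res <- suppressWarnings(
      project_scenario(b, scenario, baseline_scenario,
                       projected_mortality = projected_mortality,
                       reference_year = reference_year))
    cmp <- compare_scenarios(res$scenario, res$baseline,
                             from_year = reference_year)
    ly <- life_years(res$scenario, res$baseline, from_year = reference_year)
    cmp <- cmp[cmp$sex == "all", ]
    ly <- ly[ly$sex == "all", ]
    vals <- c()
    for (y in report_years) {
      # cumulative through y: flows exist up to the penultimate year, the
      # census (life-years) up to the final year
      yc <- min(y, max(cmp$year))
      yl <- min(y, max(ly$year))
      ci <- cmp[cmp$year == yc, ]
      li <- ly[ly$year == yl, ]
      vals <- c(vals, stats::setNames(
        c(ci$avoided[ci$measure == "deaths"],
          ci$avoided[ci$measure == "dementia"],
          ci$avoided[ci$measure == "disability"],
          li$lyg,
          li$pct_disability_scenario - li$pct_disability_baseline),
        paste(c("deaths_avoided", "dementia_cases_avoided",
                "disability_cases_avoided", "life_years_gained",
                "pct_life_disability_diff"), y, sep = "@")))
    }
    vals
  }

  point <- eval_draw(bundle)
  draws <- matrix(NA_real_, nrow = spec$n_iterations, ncol = length(point),
                  dimnames = list(NULL, names(point)))
  for (k in seq_len(spec$n_iterations)) {
    bk <- sample_inputs(bundle, spec, k)
    v <- tryCatch(eval_draw(bk), error = function(e)
      stop("PSA draw ", k, " failed: ", conditionMessage(e), call. = FALSE))
    draws[k, ] <- v
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  nm <- do.call(rbind, strsplit(names(point), "@", fixed = TRUE))
  res <- data.frame(quantity = nm[, 1], year = as.integer(nm[, 2]),
                    point = unname(point), ui_low = qs[1, ],
                    ui_high = qs[2, ], n_iterations = spec$n_iterations,
                    seed = spec$seed)
  rownames(res) <- NULL
  if (keep_draws) attr(res, "draws") <- draws
  class(res) <- c("psa_result", "data.frame")
  res
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis: ", x$n_iterations[1],
      " iterations (seed ", x$seed[1], ")\n", sep = "")
  for (y in unique(x$year)) {
    cat("  year ", y, ":\n", sep = "")
    sub <- x[x$year == y, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("    %-26s %12.1f  (95%% UI %.1f to %.1f)\n",
                  sub$quantity[i], sub$point[i], sub$ui_low[i],
                  sub$ui_high[i]))
  }
  invisible(x)
}
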