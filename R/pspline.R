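#' Penalized B-spline smoother for an annual log-rate series
#'
#' Fits the Eilers-Marx P-spline: a cubic B-spline basis on equally spaced
#' knots with a difference penalty on adjacent coefficients,
#' \deqn{\min_a \|y - Ba\|^2 + \lambda \|D_d a\|^2,}
#' where \eqn{D_d} is the order-`penalty_order` difference matrix.  With an
#' order-2 penalty the null space is the straight line, so as
#' `penalty_weight` grows the fit shrinks towards the least-squares line,
#' and data lying exactly on a line are reproduced exactly at any penalty
#' weight.
#'
#' When `penalty_weight` is `NULL` it is selected per series by minimising
#' generalised cross-validation, \eqn{n \cdot RSS / (n - ED)^2}, over a log
#' grid; if the search degenerates (e.g. effective dimension ~ n at every
#' grid point) a fixed fallback weight of 10 is used.
#'
#' @param year numeric vector of strictly increasing observation years.
#' @param log_rate numeric vector of log rates, same length.
#' @param basis_dim number of B-spline basis functions (default 10).
#' @param penalty_order difference-penalty order (default 2).
#' @param penalty_weight nonnegative smoothing parameter, or `NULL` for GCV
#'   selection.
#' @return object of class `pspline_fit` with the knots, coefficients,
#'   chosen penalty weight, fitted values and boundary derivative;
#'   evaluable anywhere via [predict.pspline_fit()].
#' @export
fit_pspline <- function(year, log_rate, basis_dim = 10L, penalty_order = 2L,
                        penalty_weight = NULL) {
  if (length(year) != length(log_rate))
    stop("year and log_rate must have equal length")
  if (any(diff(year) <= 0)) stop("years must be strictly increasing")
  if (any(!is.finite(log_rate)))
    stop("log_rate contains non-finite values (nonpositive rate upstream?)")
  n <- length(year)
  if (n < penalty_order + 2)
    stop("too few observations: need at least penalty_order + 2 points")
  basis_dim <- max(as.integer(basis_dim), penalty_order + 2L)
  deg <- 3L
  ndx <- basis_dim - deg
  xl <- min(year); xr <- max(year)
  dx <- (xr - xl) / ndx
  knots <- seq(xl - deg * dx, xr + deg * dx, by = dx)
  B <- splines::splineDesign(knots, year, ord = deg + 1L)
  D <- diff(diag(basis_dim), differences = penalty_order)
  BtB <- crossprod(B)
  DtD <- crossprod(D)

  # augmented least squares solved by QR: far better conditioned than the
  # normal equations when the penalty weight is extreme
  zeros <- rep(0, nrow(D))
  solve_for <- function(lam)
    qr.coef(qr(rbind(B, sqrt(lam) * D)), c(log_rate, zeros))

  if (is.null(penalty_weight)) {
    lams <- 10^seq(-3, 8, by = 0.5)
    gcv <- vapply(lams, function(lam) {
      a <- try(solve_for(lam), silent = TRUE)
      if (inherits(a, "try-error")) return(Inf)
      fit <- drop(B %*% a)
      ed <- sum(diag(solve(BtB + lam * DtD, BtB)))
      rss <- sum((log_rate - fit)^2)
      if (n - ed < 0.5) return(Inf)
      n * rss / (n - ed)^2
    }, numeric(1))
    penalty_weight <- if (all(!is.finite(gcv))) 10 else lams[which.min(gcv)]
  }
  if (penalty_weight < 0) stop("penalty_weight must be nonnegative")
  coef <- drop(solve_for(penalty_weight))
  fitted <- drop(B %*% coef)

  structure(list(knots = knots, coef = coef, degree = deg,
                 basis_dim = basis_dim, penalty_order = penalty_order,
                 penalty_weight = penalty_weight,
                 year = year, log_rate = log_rate, fitted = fitted,
                 xl = xl, xr = xr),
            class = "pspline_fit")
}

# evaluate the smooth (and optionally its derivative) strictly inside the
# observed range
.pspline_eval <- function(fit, x, deriv = 0L) {
  B <- splines::splineDesign(fit$knots, x, ord = fit$degree + 1L,
                             derivs = rep(deriv, length(x)))
  drop(B %*% fit$coef)
}

#' Evaluate a fitted P-spline, extrapolating linearly beyond the data
#'
#' Inside the observed year range the B-spline smooth is evaluated
#' directly.  Beyond either boundary the log rate continues linearly from
#' the boundary value with the boundary derivative of the smooth — the
#' natural continuation of an order-2 difference penalty.
#'
#' @param object a `pspline_fit`.
#' @param newdata numeric vector of years (any range).
#' @param ... unused.
#' @return numeric vector of smoothed/extrapolated log rates.
#' @export
predict.pspline_fit <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  out <- numeric(length(x))
  inside <- x >= object$xl & x <= object$xr
  if (any(inside)) out[inside] <- .pspline_eval(object, x[inside])
  if (any(x > object$xr)) {
    f_r <- .pspline_eval(object, object$xr)
    s_r <- .pspline_eval(object, object$xr, deriv = 1L)
    out[x > object$xr] <- f_r + s_r * (x[x > object$xr] - object$xr)
  }
  if (any(x < object$xl)) {
    f_l <- .pspline_eval(object, object$xl)
    s_l <- .pspline_eval(object, object$xl, deriv = 1L)
    out[x < object$xl] <- f_l + s_l * (x[x < object$xl] - object$xl)
  }
  out
}

#' @export
print.pspline_fit <- function(x, ...) {
  cat("P-spline fit: ", length(x$year), " years (", x$xl, "-", x$xr, "), ",
      x$basis_dim, " cubic basis functions, order-", x$penalty_order,
      " penalty, weight ", format(x$penalty_weight, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Extrapolate a fitted log-rate smooth to a future horizon
#'
#' Thin wrapper over [predict.pspline_fit()] that returns positive rates
#' (not log rates) for the years after the last observed year, erroring if
#' the horizon does not extend beyond the data.
#'
#' @param fit a `pspline_fit` on log rates.
#' @param horizon_year last calendar year to project to.
#' @return data frame with columns `year` and `rate` for
#'   `(last observed year + 1) : horizon_year`.
#' @export
extrapolate_mortality <- function(fit, horizon_year) {
  if (horizon_year <= fit$xr)
    stop("horizon_year must be after the last observed year (", fit$xr, ")")
  yrs <- (fit$xr + 1):horizon_year
  data.frame(year = yrs, rate = exp(predict(fit, yrs)))
}

#' Project a complete mortality series to a horizon
#'
#' Fits one P-spline per (age band, sex, cause) stratum to the log mortality
#' rates and extends each smooth to `horizon_year` by linear continuation on
#' the log scale.  The output covers every observed year (smoothed) and
#' every projection year, for every stratum; rates are strictly positive by
#' construction.
#'
#' @param mortality data frame with columns `year`, `age_band`, `sex`,
#'   `cause`, `rate` forming a complete rectangular grid.
#' @param horizon_year last projection year (default 2060).
#' @param basis_dim,penalty_order,penalty_weight passed to [fit_pspline()].
#' @return object of class `projected_mortality`: data frame (`year`,
#'   `age_band`, `sex`, `cause`, `rate`) with the per-stratum smoothing
#'   metadata in `attr(, "smoothing")`.
#' @export
project_mortality <- function(mortality, horizon_year = 2060,
                              basis_dim = 10L, penalty_order = 2L,
                              penalty_weight = NULL) {
  need <- c("year", "age_band", "sex", "cause", "rate")
  if (!all(need %in% names(mortality)))
    stop("mortality must have columns: ", paste(need, collapse = ", "))
  if (any(mortality$rate <= 0)) stop("mortality rates must be positive")
  strata <- unique(mortality[, c("age_band", "sex", "cause")])
  years_obs <- sort(unique(mortality$year))
  # grid completeness
  cnt <- stats::aggregate(rate ~ age_band + sex + cause, mortality, length)
  if (any(cnt$rate != length(years_obs))) {
    bad <- cnt[cnt$rate != length(years_obs), ]
    stop("incomplete mortality grid for strata: ",
         paste(bad$age_band, bad$sex, bad$cause, collapse = "; "))
  }
  if (horizon_year <= max(years_obs))
    stop("horizon_year must be after the last observed year")

  out <- vector("list", nrow(strata))
  meta <- strata
  meta$basis_dim <- basis_dim
  meta$penalty_order <- penalty_order
  meta$penalty_weight <- NA_real_
  all_years <- min(years_obs):horizon_year
  for (k in seq_len(nrow(strata))) {
    sel <- mortality$age_band == strata$age_band[k] &
      mortality$sex == strata$sex[k] & mortality$cause == strata$cause[k]
    d <- mortality[sel, ]
    d <- d[order(d$year), ]
    fit <- fit_pspline(d$year, log(d$rate), basis_dim = basis_dim,
                       penalty_order = penalty_order,
                       penalty_weight = penalty_weight)
    meta$penalty_weight[k] <- fit$penalty_weight
    out[[k]] <- data.frame(year = all_years,
                           age_band = strata$age_band[k],
                           sex = strata$sex[k], cause = strata$cause[k],
                           rate = exp(predict(fit, all_years)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "smoothing") <- meta
  attr(res, "observed_years") <- years_obs
  class(res) <- c("projected_mortality", "data.frame")
  res
}
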