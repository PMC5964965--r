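# Transport-activity parameter extraction: Hill dose-response fits,
# initial-rate extraction from single efflux traces, and the
# calibration-based EC50 imputation used for compounds too slow (or too
# fast) for a full dose-response series.

#' Potency transform log10(1/EC50)
#'
#' The response modelled throughout the QSAR stage. Base-10 logarithm,
#' consistent with log P conventions and the magnitude of the fitted
#' parabola coefficients.
#'
#' @param ec50 Positive EC50 value(s), mol% carrier/lipid.
#' @return `-log10(ec50)`, dimensionless.
#' @examples
#' log_potency(0.00312)  # 2.5058
#' @export
log_potency <- function(ec50) {
  if (!is.numeric(ec50) || any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop("ec50 must be positive and finite", call. = FALSE)
  }
  -log10(ec50)
}

# Deterministic multi-start nlsLM wrapper: runs every start, keeps all
# converged fits, returns the one with lowest SSE (caller breaks ties).
.multistart_nls <- function(formula, data, starts, lower = NULL,
                            upper = NULL) {
  fits <- list()
  for (st in starts) {
    npar <- length(st)
    f <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st,
        lower = rep(if (is.null(lower)) -Inf else lower, length.out = npar),
        upper = rep(if (is.null(upper)) Inf else upper, length.out = npar),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  fits
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `y = ymax * x^n / (ec50^n + x^n)` to chloride
#' efflux at assay end (300 s) versus carrier loading. By default `ymax`
#' is fixed at 100%: detergent lysis defines complete release, so the
#' fitted EC50 is the loading producing 50% efflux. Pass `ymax = NULL` to
#' fit the plateau as a third parameter.
#'
#' Optimisation uses 8 deterministic starts with EC50 on a log-spaced grid
#' spanning the loading range (Hill slope started at 1); among converged
#' starts the fit with lowest residual sum of squares wins, ties broken by
#' lower EC50. Parameters are optimised on the log scale so positivity is
#' structural.
#'
#' @param loadings Carrier loadings, mol% compound/lipid (positive).
#' @param responses Chloride efflux at 300 s, % (non-negative).
#' @param ymax Fixed maximal release in %, or `NULL` to estimate it.
#' @return A `hill_fit` list: `ec50`, `hill_n`, `ymax`, `ymax_fixed`,
#'   `residual_sse`, `n_obs`.
#' @examples
#' d <- simulate_dose_response(0.01, 1.2, 10^seq(-3, -0.5, length.out = 8))
#' fit_hill(d$loading_molpct, d$efflux_pct)$ec50  # 0.01
#' @export
fit_hill <- function(loadings, responses, ymax = 100) {
  loadings <- as.numeric(loadings)
  responses <- as.numeric(responses)
  if (length(loadings) != length(responses)) {
    stop("loadings and responses must have equal length", call. = FALSE)
  }
  if (any(!is.finite(loadings)) || any(loadings <= 0)) {
    stop("loadings must be positive", call. = FALSE)
  }
  if (any(!is.finite(responses)) || any(responses < 0)) {
    stop("responses must be non-negative", call. = FALSE)
  }
  if (length(unique(loadings)) < 4L) {
    stop("need at least 4 distinct loadings", call. = FALSE)
  }
  if (diff(range(responses)) == 0) {
    stop("fit error: responses are constant, no dose-response information",
         call. = FALSE)
  }
  dat <- data.frame(x = loadings, y = responses)
  ec50_grid <- exp(seq(log(min(loadings) / 3), log(max(loadings) * 3),
                       length.out = 8L))
  fit_ymax <- is.null(ymax)
  if (fit_ymax) {
    form <- y ~ exp(lymax) * x^exp(ln) / (exp(le)^exp(ln) + x^exp(ln))
    starts <- lapply(ec50_grid, function(e) {
      list(le = log(e), ln = 0, lymax = log(max(max(responses), 1)))
    })
  } else {
    form <- substitute(y ~ YM * x^exp(ln) / (exp(le)^exp(ln) + x^exp(ln)),
                       list(YM = ymax))
    starts <- lapply(ec50_grid, function(e) list(le = log(e), ln = 0))
  }
  fits <- .multistart_nls(stats::as.formula(form), dat, starts)
  if (!length(fits)) {
    stop("fit error: Hill fit did not converge from any start",
         call. = FALSE)
  }
  sse <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  ec <- vapply(fits, function(f) exp(coef(f)[["le"]]), numeric(1))
  best <- order(sse, ec)[1L]
  cf <- coef(fits[[best]])
  structure(list(
    ec50 = exp(cf[["le"]]),
    hill_n = exp(cf[["ln"]]),
    ymax = if (fit_ymax) exp(cf[["lymax"]]) else ymax,
    ymax_fixed = !fit_ymax,
    residual_sse = sse[best],
    n_obs = length(loadings)), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: EC50 = %.4g mol%%, n = %.3g, ymax = %.4g%%%s (SSE %.3g, n = %d)\n",
    x$ec50, x$hill_n, x$ymax, if (x$ymax_fixed) " [fixed]" else "",
    x$residual_sse, x$n_obs))
  invisible(x)
}

#' Fit the asymptotic efflux-trace model and extract the initial rate
#'
#' Fits `y = a - b * c^x` (chloride release y, %, versus time x, s) by
#' nonlinear least squares, with `b > 0` and `c` constrained to (0, 1)
#' through the smooth reparameterisation `c = exp(-exp(theta))`. The
#' initial rate of chloride release is the closed form
#' `k_ini = -b * ln(c)` in % per second, the slope of the curve at t = 0.
#'
#' @param times Time points in seconds, strictly increasing, >= 5 points.
#' @param efflux Chloride release in % at each time point.
#' @return An `asymptotic_fit` list: `a` (plateau, %), `b` (amplitude, %),
#'   `c` (decay base per second), `kini` (% s^-1), `residual_sse`,
#'   `n_obs`.
#' @examples
#' tr <- simulate_trace(a = 100, b = 100, c = 0.99)
#' fit_kini(tr$time_s, tr$efflux_pct)$kini  # 1.00503
#' @export
fit_kini <- function(times, efflux) {
  times <- as.numeric(times)
  efflux <- as.numeric(efflux)
  if (length(times) != length(efflux)) {
    stop("times and efflux must have equal length", call. = FALSE)
  }
  if (length(times) < 5L) stop("need at least 5 points", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (diff(range(efflux)) == 0) {
    stop("efflux trace is constant", call. = FALSE)
  }
  dat <- data.frame(x = times, y = efflux)
  a0 <- max(efflux)
  b0 <- max(a0 - min(efflux), 1e-3)
  # starts span decay rates -log(c) from ~1e-4 to 1 per second
  rate_grid <- exp(seq(log(1e-4), log(1), length.out = 8L))
  starts <- lapply(rate_grid, function(k) {
    list(a = a0, lb = log(b0), th = log(k))
  })
  fits <- .multistart_nls(y ~ a - exp(lb) * exp(-exp(th) * x), dat, starts)
  if (!length(fits)) {
    stop("fit error: asymptotic fit did not converge from any start",
         call. = FALSE)
  }
  sse <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- which.min(sse)
  cf <- coef(fits[[best]])
  b <- exp(cf[["lb"]])
  cc <- exp(-exp(cf[["th"]]))
  structure(list(a = cf[["a"]], b = b, c = cc,
                 kini = -b * log(cc),
                 residual_sse = sse[best],
                 n_obs = length(times)), class = "asymptotic_fit")
}

#' @export
print.asymptotic_fit <- function(x, ...) {
  cat(sprintf(
    "Asymptotic trace fit: y = %.4g - %.4g * %.6g^t; k_ini = %.5g %% s^-1\n",
    x$a, x$b, x$c, x$kini))
  invisible(x)
}

#' Impute EC50 from the initial rate via a calibration regression
#'
#' For a compound whose dose-response could not be measured, predicts EC50
#' from its initial chloride-release rate using a calibration built on
#' compounds with both quantities measured. The default form regresses
#' log10(EC50) on log10(k_ini) by ordinary least squares (potency and rate
#' both span orders of magnitude); semi-log and linear forms are
#' selectable.
#'
#' @param calibration A `compound_table`; rows with measured (non-imputed)
#'   `ec50_molpct` and `kini_pct_per_s` are used.
#' @param kini Query initial rate(s), % s^-1, positive.
#' @param form Calibration form: `"loglog"` (default), `"semilog"`
#'   (log10 EC50 on k_ini), or `"linear"`.
#' @return An `ec50_imputation` list: `ec50` (predicted, mol%), `slope`,
#'   `intercept`, `r` (calibration correlation), `n_calibration`, `form`.
#' @examples
#' tab <- load_compound_table("table1")
#' impute_ec50_from_kini(tab[1:42, ], kini = 0.186)$ec50  # ~0.0616
#' @export
impute_ec50_from_kini <- function(calibration, kini, form = "loglog") {
  stopifnot(inherits(calibration, "compound_table"))
  form <- match.arg(form, c("loglog", "semilog", "linear"))
  if (any(!is.finite(kini)) || any(kini <= 0)) {
    stop("kini must be positive", call. = FALSE)
  }
  ok <- !is.na(calibration$ec50_molpct) &
    !is.na(calibration$kini_pct_per_s) & !calibration$ec50_imputed
  e <- calibration$ec50_molpct[ok]
  k <- calibration$kini_pct_per_s[ok]
  if (sum(ok) < 3L) {
    stop("need at least 3 calibration records with measured ec50 and kini",
         call. = FALSE)
  }
  tx <- switch(form, loglog = log10(k), semilog = k, linear = k)
  ty <- switch(form, loglog = log10(e), semilog = log10(e), linear = e)
  f <- lm.fit(cbind(1, tx), ty)
  b <- coef(f)
  qx <- switch(form, loglog = log10(kini), semilog = kini, linear = kini)
  pred <- b[1] + b[2] * qx
  structure(list(
    ec50 = unname(if (form == "linear") pred else 10^pred),
    slope = unname(b[2]), intercept = unname(b[1]),
    r = cor(tx, ty), n_calibration = sum(ok), form = form),
    class = "ec50_imputation")
}

#' @export
print.ec50_imputation <- function(x, ...) {
  cat(sprintf(
    "EC50 imputation (%s, n = %d, r = %.3f): predicted %s mol%%\n",
    x$form, x$n_calibration, x$r,
    paste(signif(x$ec50, 4), collapse = ", ")))
  invisible(x)
}
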