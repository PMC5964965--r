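# Stratified bootstrap validation of QSAR model coefficients.
#
# The compound library is heavily weighted towards mid-range
# lipophilicity, with a handful of high-leverage compounds at the extremes
# that anchor the curvature of the activity parabola. Plain case
# resampling can drop those points entirely; resampling within log P
# strata (low / mid / high), preserving each stratum's size, guarantees
# every resample keeps representation of the extremes.

#' Define lipophilicity strata
#'
#' @param variable Column to stratify on (default `"alogps"`).
#' @param boundaries Strictly ascending cut points; the default
#'   `c(2.5, 5)` separates the sparse low and high log P tails from the
#'   densely populated mid range.
#' @return A `strata_definition` list.
#' @export
strata_definition <- function(variable = "alogps", boundaries = c(2.5, 5)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly ascending", call. = FALSE)
  }
  structure(list(variable = variable, boundaries = boundaries),
            class = "strata_definition")
}

#' Assign compounds to lipophilicity strata
#'
#' Half-open binning: `[-Inf, b1), [b1, b2), ..., [bk, Inf)`. With the
#' default two boundaries the strata are labelled `low`, `mid`, `high`;
#' a value exactly on a boundary falls in the upper bin.
#'
#' @param table A `compound_table` (or `data.frame` with the
#'   stratification column).
#' @param strata A `strata_definition`.
#' @return A factor of stratum labels, one per record. Warns if fewer than
#'   2 strata are non-empty.
#' @examples
#' s <- assign_strata(load_compound_table("table1"))
#' table(s)
#' @export
assign_strata <- function(table, strata = strata_definition()) {
  stopifnot(inherits(strata, "strata_definition"))
  v <- table[[strata$variable]]
  if (is.null(v)) {
    stop(sprintf("stratification variable '%s' not found", strata$variable),
         call. = FALSE)
  }
  if (anyNA(v)) {
    stop("missing values in stratification variable", call. = FALSE)
  }
  k <- length(strata$boundaries) + 1L
  labels <- if (k == 3L) c("low", "mid", "high") else
    paste0("stratum_", seq_len(k))
  out <- cut(v, breaks = c(-Inf, strata$boundaries, Inf), right = FALSE,
             labels = labels)
  if (sum(table(out) > 0) < 2L) {
    warning("fewer than 2 non-empty strata; stratification is inert")
  }
  out
}

#' Stratified bootstrap confidence intervals for model coefficients
#'
#' Resamples records with replacement within each stratum, preserving the
#' original stratum sizes, refits the OLS model on each resample, and
#' returns percentile bounds (2.5% / 97.5% at the default level) for every
#' coefficient. Resamples whose design is rank-deficient are redrawn
#' (counted; capped at 10x the resample budget). Fully reproducible given
#' `seed`: one RNG stream, strata drawn in fixed (factor-level) order.
#'
#' @param table A `compound_table` or `data.frame`.
#' @param terms Model terms as in [fit_ols()].
#' @param strata A `strata_definition`.
#' @param n_resamples Number of bootstrap resamples (default 999).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param response As in [fit_ols()].
#' @param level Confidence level for the percentile bounds.
#' @param keep_indices Also return the resampled row indices (one integer
#'   vector per resample); off by default to keep the result light.
#' @return A `bootstrap_result` list: `ci` (matrix of percentile bounds,
#'   intercept first), `point` (full-data coefficients), `draws`
#'   (`n_resamples` x coefficients matrix), `n_resamples`, `seed`,
#'   `strata`, `stratum_sizes`, `n_redrawn`, and `indices` when requested.
#' @export
stratified_bootstrap <- function(table, terms,
                                 strata = strata_definition(),
                                 n_resamples = 999, seed = NULL,
                                 response = NULL, level = 0.95,
                                 keep_indices = FALSE) {
  stopifnot(n_resamples >= 1)
  full <- fit_ols(table, terms, response = response)
  y <- full$response
  X1 <- cbind(1, .resolve_design(table, terms))
  p <- ncol(X1)
  lab <- assign_strata(table, strata)
  idx_by_stratum <- split(seq_along(y), lab, drop = TRUE)
  if (any(lengths(idx_by_stratum) == 0L)) {
    idx_by_stratum <- idx_by_stratum[lengths(idx_by_stratum) > 0L]
  }
  draws <- matrix(NA_real_, n_resamples, p,
                  dimnames = list(NULL, c("(Intercept)", terms)))
  indices <- if (keep_indices) vector("list", n_resamples) else NULL
  n_redrawn <- 0L
  max_draws <- 10L * n_resamples
  with_seed(seed, {
    i <- 1L
    total <- 0L
    while (i <= n_resamples) {
      total <- total + 1L
      if (total > max_draws) {
        stop("too many rank-deficient resamples; check the design",
             call. = FALSE)
      }
      idx <- unlist(lapply(idx_by_stratum, function(ii) {
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }), use.names = FALSE)
      f <- .ols_core(X1[idx, , drop = FALSE], y[idx])
      if (f$rank < p) { n_redrawn <- n_redrawn + 1L; next }
      draws[i, ] <- f$coef
      if (keep_indices) indices[[i]] <- idx
      i <- i + 1L
    }
  })
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2, quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("ci_low", "ci_high")
  structure(list(ci = ci,
                 point = c(`(Intercept)` = full$intercept,
                           full$coefficients),
                 draws = draws,
                 n_resamples = n_resamples, seed = seed,
                 strata = strata,
                 stratum_sizes = lengths(idx_by_stratum),
                 level = level,
                 n_redrawn = n_redrawn,
                 indices = indices),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Stratified bootstrap: %d resamples, strata on %s at (%s), sizes %s\n",
    x$n_resamples, x$strata$variable,
    paste(x$strata$boundaries, collapse = ", "),
    paste(x$stratum_sizes, collapse = "/")))
  print(round(cbind(point = x$point, x$ci), digits))
  invisible(x)
}
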