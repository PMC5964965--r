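# OLS engine with analytic confidence intervals, exhaustive all-subsets
# model enumeration, and parabola utilities.
#
# Term naming: a term "<name>-sq" that is not itself a column of the data
# is derived on demand as the square of column "<name>", so model
# specifications stay purely name-based (e.g. c("alogps", "alogps-sq")).

# Resolve term names to a numeric design matrix (no intercept column).
.resolve_design <- function(data, terms) {
  if (anyDuplicated(terms)) stop("duplicate terms in model spec",
                                 call. = FALSE)
  cols <- lapply(terms, function(tm) {
    if (tm %in% names(data)) {
      x <- data[[tm]]
    } else if (grepl("-sq$", tm) && sub("-sq$", "", tm) %in% names(data)) {
      x <- data[[sub("-sq$", "", tm)]]^2
    } else {
      stop(sprintf("term '%s' not found in data", tm), call. = FALSE)
    }
    if (!is.numeric(x)) {
      stop(sprintf("term '%s' is not numeric", tm), call. = FALSE)
    }
    as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

# Resolve the response: numeric vector, column name, or (for a compound
# table) the default potency transform log10(1/EC50).
.resolve_response <- function(data, response) {
  if (is.numeric(response)) return(as.numeric(response))
  if (is.character(response)) {
    if (!response %in% names(data)) {
      stop(sprintf("response column '%s' not found", response),
           call. = FALSE)
    }
    return(as.numeric(data[[response]]))
  }
  if (inherits(data, "compound_table")) {
    return(log_potency(data$ec50_molpct))
  }
  stop("response must be a numeric vector or column name", call. = FALSE)
}

# Fast OLS on a design with intercept; returns coefficients, sse, rank
# info. Shared by fit_ols, enumeration and the bootstrap inner loop.
.ols_core <- function(X1, y) {
  f <- lm.fit(X1, y)
  list(coef = f$coefficients, rank = f$rank, qr = f$qr,
       sse = sum(f$residuals^2), residuals = f$residuals,
       fitted = f$fitted.values)
}

#' Ordinary least squares fit with analytic confidence intervals
#'
#' Fits `response ~ intercept + terms` by QR-based least squares and
#' reports the coefficient of determination (1 - SSE/SST on the fitted
#' data) and 95% confidence bounds from the t distribution with
#' `n_obs - #terms - 1` degrees of freedom.
#'
#' @param data A `compound_table`, `descriptor_matrix`, or any
#'   `data.frame` holding the term columns.
#' @param terms Character vector of term names; `"<name>-sq"` derives the
#'   square of column `<name>` on demand.
#' @param response Numeric vector, column name, or `NULL`: for a
#'   `compound_table`, `NULL` means the potency transform
#'   `log10(1/ec50_molpct)`.
#' @param level Confidence level (default 0.95).
#' @return A `model_fit` list: `terms`, `intercept`, `coefficients`
#'   (named, excluding the intercept), `r_squared`, `ci` (matrix of
#'   lower/upper bounds, intercept first), `se`, `sigma`, `df_residual`,
#'   `n_obs`, `fitted`, `residuals`.
#' @examples
#' tab <- load_compound_table("table1")
#' fit_ols(tab, c("alogps", "alogps-sq"))
#' @export
fit_ols <- function(data, terms, response = NULL, level = 0.95) {
  y <- .resolve_response(data, response)
  X <- .resolve_design(data, terms)
  n <- length(y)
  if (nrow(X) != n) stop("response length must match data rows",
                         call. = FALSE)
  p <- ncol(X) + 1L
  if (n <= p) {
    stop("need n_obs > number of terms + 1", call. = FALSE)
  }
  X1 <- cbind(`(Intercept)` = 1, X)
  f <- .ols_core(X1, y)
  if (f$rank < p) {
    aliased <- colnames(X1)[f$qr$pivot[(f$rank + 1L):p]]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  dfres <- n - p
  sigma2 <- f$sse / dfres
  R <- qr.R(f$qr)
  piv <- f$qr$pivot
  Rinv <- backsolve(R, diag(p))
  xtx_inv_perm <- tcrossprod(Rinv)
  xtx_inv <- matrix(0, p, p)
  xtx_inv[piv, piv] <- xtx_inv_perm
  se <- sqrt(diag(xtx_inv) * sigma2)
  tcrit <- qt(1 - (1 - level) / 2, dfres)
  cf <- f$coef
  ci <- cbind(ci_low = cf - tcrit * se, ci_high = cf + tcrit * se)
  sst <- sum((y - mean(y))^2)
  structure(list(
    terms = terms,
    intercept = unname(cf[1]),
    coefficients = cf[-1],
    r_squared = 1 - f$sse / sst,
    ci = ci, se = setNames(se, names(cf)),
    sigma = sqrt(sigma2), df_residual = dfres, n_obs = n,
    level = level,
    fitted = f$fitted, residuals = f$residuals,
    response = y), class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("OLS fit: %d terms, n = %d, R^2 = %.4f\n",
              length(x$terms), x$n_obs, x$r_squared))
  tab <- cbind(estimate = c(x$intercept, x$coefficients), x$ci)
  print(round(tab, digits))
  invisible(x)
}

#' Exhaustive all-subsets model enumeration
#'
#' Fits every subset of candidate descriptors of size 1 to `max_terms`
#' against the response and ranks the models by R-squared, descending,
#' with deterministic ties broken by the lexicographic term-name string.
#' Rank-deficient subsets (e.g. containing duplicated columns) are
#' skipped and counted.
#'
#' @param y Numeric response vector.
#' @param matrix A cleaned `descriptor_matrix` (all-numeric).
#' @param max_terms Maximum model size (>= 1).
#' @param candidate_subset Optional character vector restricting the
#'   candidate columns (all must exist in `matrix`).
#' @param top_k Number of top models to keep (default all).
#' @return A `model_ranking`: list with `table` (`data.frame` of `rank`,
#'   `terms`, `n_terms`, `r_squared`) and `fits` (the corresponding
#'   `model_fit` objects for the kept models).
#' @export
enumerate_models <- function(y, matrix, max_terms = 3,
                             candidate_subset = NULL, top_k = Inf) {
  stopifnot(is.data.frame(matrix), max_terms >= 1)
  cands <- if (is.null(candidate_subset)) names(matrix) else candidate_subset
  missing <- setdiff(cands, names(matrix))
  if (length(missing)) {
    stop(sprintf("candidate descriptor(s) not in matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cands <- sort(cands)
  subsets <- list()
  for (k in seq_len(min(max_terms, length(cands)))) {
    cmb <- combn(cands, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  rows <- list()
  fits <- list()
  n_skipped <- 0L
  for (s in subsets) {
    f <- tryCatch(fit_ols(matrix, s, response = y),
                  error = function(e) NULL)
    if (is.null(f)) { n_skipped <- n_skipped + 1L; next }
    key <- paste(s, collapse = "+")
    rows[[length(rows) + 1L]] <- data.frame(
      terms = key, n_terms = length(s), r_squared = f$r_squared,
      stringsAsFactors = FALSE)
    fits[[key]] <- f
  }
  if (!length(rows)) stop("no fittable models", call. = FALSE)
  tab <- do.call(rbind, rows)
  ord <- order(-tab$r_squared, tab$terms)
  tab <- tab[ord, , drop = FALSE]
  keep <- seq_len(min(top_k, nrow(tab)))
  tab <- tab[keep, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab[c("rank", "terms", "n_terms", "r_squared")],
                 fits = fits[tab$terms],
                 n_skipped = n_skipped),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, n = 10, ...) {
  cat(sprintf("All-subsets enumeration: %d models ranked by R^2%s\n",
              nrow(x$table),
              if (x$n_skipped) sprintf(" (%d rank-deficient skipped)",
                                       x$n_skipped) else ""))
  print(utils::head(x$table, n))
  invisible(x)
}

#' Optimum log P of a fitted activity parabola
#'
#' For a model containing a linear term and its square (named
#' `"<name>"` and `"<name>-sq"`), returns the vertex `-b1 / (2 * b2)` of
#' the parabola: the lipophilicity at which predicted transport activity
#' peaks. Requires a negative curvature (interior maximum).
#'
#' @param fit A `model_fit`.
#' @return The optimum of the quadratic variable (e.g. log P units).
#' @examples
#' tab <- load_compound_table("table1")
#' optimum_logp(fit_ols(tab, c("alogps", "alogps-sq")))  # ~4.53
#' @export
optimum_logp <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  terms <- names(fit$coefficients)
  sq <- terms[grepl("-sq$", terms) & sub("-sq$", "", terms) %in% terms]
  if (length(sq) != 1L) {
    stop("fit must contain exactly one linear + squared term pair",
         call. = FALSE)
  }
  lin <- sub("-sq$", "", sq)
  b1 <- fit$coefficients[[lin]]
  b2 <- fit$coefficients[[sq]]
  if (b2 >= 0) stop("no interior maximum: squared coefficient >= 0",
                    call. = FALSE)
  -b1 / (2 * b2)
}
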