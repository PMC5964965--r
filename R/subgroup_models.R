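# Structural-subgroup analysis.
#
# Compounds share a bipyrrole core and are classified by three backbone
# positions: the ring substituent R4 (OMe or OBn), the enamine substituent
# R5 (NH or NH-Ph, with rare other moieties left unclassified), and the
# R-group class R6 (alkyl, halogen, O-R', ...). The key scientific
# question is whether the parabolic activity-lipophilicity envelope is a
# property of the membrane (shared curvature) while substituent series
# merely shift its height/position (group intercepts).

.valid_r4 <- c("OMe", "OBn")
.valid_r5 <- c("NH", "NH-Ph")

#' Classify compounds into structural subgroups
#'
#' Builds the composite label `R4.R5.R6` for every record whose
#' annotations are complete and whose R4/R5 fall in the recognised sets
#' (`OMe`/`OBn` and `NH`/`NH-Ph`). Other records (e.g. an `NH-CH2-Ph` or
#' `NH-py` enamine, or missing annotations) land in an explicit
#' unclassified bucket rather than erroring.
#'
#' @param table A `compound_table` with `r4`, `r5`, `r6_class` columns.
#' @return A `data.frame`: `compound_id`, `r4`, `r5`, `r6_class`,
#'   `composite` (NA when unclassified), `classified` (logical).
#' @export
classify_subgroups <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  ok <- !is.na(table$r4) & !is.na(table$r5) & !is.na(table$r6_class) &
    table$r4 %in% .valid_r4 & table$r5 %in% .valid_r5
  composite <- ifelse(ok, paste(table$r4, table$r5, table$r6_class,
                                sep = "."), NA_character_)
  data.frame(compound_id = table$compound_id,
             r4 = table$r4, r5 = table$r5, r6_class = table$r6_class,
             composite = composite, classified = ok,
             stringsAsFactors = FALSE)
}

# Normalise a labels argument: classify_subgroups() output, factor, or
# character vector aligned with the table rows. Returns a factor with NA
# for unclassified rows.
.as_group_factor <- function(table, labels) {
  if (is.data.frame(labels) && "composite" %in% names(labels)) {
    g <- labels$composite
  } else {
    g <- as.character(labels)
  }
  if (length(g) != nrow(table)) {
    stop("labels must align with table rows", call. = FALSE)
  }
  factor(g)
}

#' Fit independent quadratic activity models per subgroup
#'
#' For each subgroup of at least `min_group_size` compounds, fits
#' `log10(1/EC50) ~ alogps + alogps^2` by OLS, independently of the other
#' groups. Smaller groups are reported as skipped — a two-point group
#' cannot constrain a parabola.
#'
#' @param table A `compound_table`.
#' @param labels Subgroup labels ([classify_subgroups()] output, or a
#'   factor/character vector aligned with the table rows; NA =
#'   unclassified).
#' @param min_group_size Minimum compounds per fitted group (default 3).
#' @param response As in [fit_ols()].
#' @return A `group_quadratics` list: `fits` (named list of `model_fit`),
#'   `skipped` (named integer vector of undersized group sizes),
#'   `n_unclassified`.
#' @export
fit_group_quadratics <- function(table, labels, min_group_size = 3,
                                 response = NULL) {
  g <- .as_group_factor(table, labels)
  y <- .resolve_response(table, response)
  fits <- list()
  skipped <- integer()
  for (lev in levels(g)) {
    rows <- which(!is.na(g) & g == lev)
    if (length(rows) < min_group_size) {
      skipped[lev] <- length(rows)
      next
    }
    fits[[lev]] <- fit_ols(table[rows, , drop = FALSE],
                           c("alogps", "alogps-sq"),
                           response = y[rows])
  }
  structure(list(fits = fits, skipped = skipped,
                 n_unclassified = sum(is.na(g))),
            class = "group_quadratics")
}

#' @export
print.group_quadratics <- function(x, ...) {
  cat(sprintf("Per-group quadratic fits: %d fitted, %d skipped (<min size), %d unclassified\n",
              length(x$fits), length(x$skipped), x$n_unclassified))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %s: Y = %.4g + %.4g x %+.4g x^2 (R^2 %.3f, n = %d)\n",
                nm, f$intercept, f$coefficients[[1]], f$coefficients[[2]],
                f$r_squared, f$n_obs))
  }
  invisible(x)
}

# Profile REML criterion for the random-intercept model at variance ratio
# lambda = sigma_u^2 / sigma^2. V = I + lambda Z Z', beta GLS, sigma^2
# profiled out. Returns the criterion and the fit components.
.reml_at_lambda <- function(lambda, X, y, Z) {
  n <- nrow(X); p <- ncol(X)
  V <- diag(n) + lambda * tcrossprod(Z)
  cV <- chol(V)
  Vi <- chol2inv(cV)
  B <- crossprod(X, Vi %*% X)
  beta <- solve(B, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  q <- drop(crossprod(r, Vi %*% r))
  crit <- 2 * sum(log(diag(cV))) + determinant(B)$modulus[1] +
    (n - p) * log(q)
  list(crit = crit, beta = drop(beta), q = q, Vi = Vi, r = drop(r))
}

#' Shared-curvature subgroup model
#'
#' Fits `log10(1/EC50) = a + b*ALOGPs + c*ALOGPs^2` with a single
#' curvature pair `(b, c)` across all groups and group-specific intercept
#' shifts — the model formalising "the parabola is a property of the
#' membrane, the substituent series shifts it".
#'
#' Two estimation modes:
#' \describe{
#'   \item{`fixed_offsets`}{OLS with group-indicator intercepts under a
#'     sum-to-zero constraint, so the global intercept is the cross-group
#'     mean and offsets are deviations from it.}
#'   \item{`random_intercept`}{Gaussian random-intercept model estimated
#'     by restricted maximum likelihood, profiling the variance ratio
#'     `lambda = sigma_u^2 / sigma^2` over a log-spaced grid
#'     (1e-8 to 1e4) followed by golden-section refinement
#'     ([stats::optimize()]) — deterministic. Offsets are returned as the
#'     conditional means (BLUPs) of the group effects.}
#' }
#'
#' @param table A `compound_table`.
#' @param labels Subgroup labels as in [fit_group_quadratics()];
#'   unclassified (NA) rows are dropped.
#' @param mode `"fixed_offsets"` or `"random_intercept"`.
#' @param response As in [fit_ols()].
#' @return A `shared_curvature_fit` list: `beta_linear`, `beta_quad`,
#'   `global_intercept`, `group_offsets` (named), `offset_variance`
#'   (`sigma_u^2`; NA for fixed offsets), `sigma2` (residual variance),
#'   `mode`, `lambda` (variance ratio, random mode), `n_obs`, `groups`,
#'   `profile` (grid of the REML criterion, random mode).
#' @export
fit_shared_curvature <- function(table, labels,
                                 mode = c("fixed_offsets",
                                          "random_intercept"),
                                 response = NULL) {
  mode <- match.arg(mode)
  g <- .as_group_factor(table, labels)
  keep <- which(!is.na(g))
  if (!length(keep)) stop("no classified records", call. = FALSE)
  g <- droplevels(g[keep])
  tab <- table[keep, , drop = FALSE]
  y <- .resolve_response(table, response)[keep]
  x <- tab$alogps
  X <- cbind(`(Intercept)` = 1, alogps = x, `alogps-sq` = x^2)
  k <- nlevels(g)

  if (k == 1L) {
    f <- fit_ols(tab, c("alogps", "alogps-sq"), response = y)
    return(structure(list(
      beta_linear = f$coefficients[["alogps"]],
      beta_quad = f$coefficients[["alogps-sq"]],
      global_intercept = f$intercept,
      group_offsets = setNames(0, levels(g)),
      offset_variance = if (mode == "random_intercept") 0 else NA_real_,
      sigma2 = f$sigma^2, mode = mode, lambda = NA_real_,
      n_obs = nrow(tab), groups = levels(g), profile = NULL),
      class = "shared_curvature_fit"))
  }

  if (mode == "fixed_offsets") {
    # sum-to-zero indicator coding: columns for levels 1..k-1, level k
    # carries -1 in each
    C <- matrix(0, nrow(tab), k - 1L)
    gi <- as.integer(g)
    for (j in seq_len(k - 1L)) C[gi == j, j] <- 1
    C[gi == k, ] <- -1
    X1 <- cbind(X, C)
    f <- .ols_core(X1, y)
    if (f$rank < ncol(X1)) {
      stop("rank-deficient subgroup design", call. = FALSE)
    }
    off <- f$coef[-(1:3)]
    offsets <- setNames(c(off, -sum(off)), levels(g))
    dfres <- nrow(tab) - ncol(X1)
    return(structure(list(
      beta_linear = unname(f$coef[2]), beta_quad = unname(f$coef[3]),
      global_intercept = unname(f$coef[1]),
      group_offsets = offsets,
      offset_variance = NA_real_,
      sigma2 = f$sse / dfres, mode = mode, lambda = NA_real_,
      n_obs = nrow(tab), groups = levels(g), profile = NULL),
      class = "shared_curvature_fit"))
  }

  # random_intercept: profile REML over the variance ratio
  if (min(table(g)) < 2L || k < 2L) {
    stop("random_intercept mode needs >= 2 groups with >= 2 points each",
         call. = FALSE)
  }
  Z <- matrix(0, nrow(tab), k)
  Z[cbind(seq_len(nrow(tab)), as.integer(g))] <- 1
  grid <- 10^seq(-8, 4, length.out = 61)
  crit <- vapply(grid, function(l) .reml_at_lambda(l, X, y, Z)$crit,
                 numeric(1))
  if (any(!is.finite(crit))) {
    stop("REML criterion not finite on the profile grid; search trace: ",
         paste(signif(crit, 4), collapse = ", "), call. = FALSE)
  }
  i0 <- which.min(crit)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- optimize(function(ll) .reml_at_lambda(exp(ll), X, y, Z)$crit,
                  lower = log(lo), upper = log(hi),
                  tol = .Machine$double.eps^0.5)
  lambda <- exp(opt$minimum)
  fit <- .reml_at_lambda(lambda, X, y, Z)
  n <- nrow(tab); p <- ncol(X)
  sigma2 <- fit$q / (n - p)
  u <- lambda * drop(crossprod(Z, fit$Vi %*% fit$r))
  structure(list(
    beta_linear = unname(fit$beta[2]), beta_quad = unname(fit$beta[3]),
    global_intercept = unname(fit$beta[1]),
    group_offsets = setNames(u, levels(g)),
    offset_variance = sigma2 * lambda,
    sigma2 = sigma2, mode = mode, lambda = lambda,
    n_obs = n, groups = levels(g),
    profile = data.frame(lambda = grid, reml_criterion = crit)),
    class = "shared_curvature_fit")
}

#' @export
print.shared_curvature_fit <- function(x, ...) {
  cat(sprintf(
    "Shared-curvature fit (%s): Y = %.4g %+.4g ALOGPs %+.4g ALOGPs^2\n",
    x$mode, x$global_intercept, x$beta_linear, x$beta_quad))
  cat("Group offsets:\n")
  print(round(x$group_offsets, 4))
  if (x$mode == "random_intercept") {
    cat(sprintf("offset variance %.4g, residual variance %.4g\n",
                x$offset_variance, x$sigma2))
  }
  invisible(x)
}
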