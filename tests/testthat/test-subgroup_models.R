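make_annotated <- function() {
  tab <- load_compound_table("table1")
  # synthetic annotation pattern (the real assignments are not packaged)
  tab$r4 <- rep(c("OMe", "OBn"), length.out = 43)
  tab$r5 <- rep(c("NH", "NH-Ph"), length.out = 43)
  tab$r6_class <- "alkyl"
  tab$r5[19] <- "NH-CH2-Ph"
  tab$r5[38] <- "NH-py"
  tab$r4[5] <- NA
  tab
}

test_that("subgroup classification composes labels and buckets the rest", {
  tab <- make_annotated()
  lab <- classify_subgroups(tab)
  expect_equal(lab$composite[1], "OMe.NH.alkyl")
  expect_equal(lab$composite[2], "OBn.NH-Ph.alkyl")
  expect_false(lab$classified[19])  # NH-CH2-Ph enamine
  expect_false(lab$classified[38])  # NH-py enamine
  expect_false(lab$classified[5])   # missing ring annotation
  expect_true(all(is.na(lab$composite[!lab$classified])))
  expect_equal(sum(!lab$classified), 3L)
})

test_that("per-group quadratics skip undersized groups and recover exact fits", {
  x <- c(2, 3, 4, 5, 6)
  y <- 0.17 + 1.09 * x - 0.146 * x^2
  tab <- quad_table(c(x, 1.0, 7.0), c(y, 0.3, 0.4))
  g <- c(rep("OMe.NH-Ph.alkyl", 5), rep("tiny", 2))
  res <- fit_group_quadratics(tab, g)
  expect_named(res$skipped, "tiny")
  expect_equal(unname(res$skipped), 2L)
  f <- res$fits[["OMe.NH-Ph.alkyl"]]
  expect_equal(f$intercept, 0.17, tolerance = 1e-8)
  expect_equal(unname(f$coefficients), c(1.09, -0.146), tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("per-group fits equal independent OLS on each subset", {
  lib <- simulate_library(n_compounds = 30,
                          group_offsets = c(A = -0.4, B = 0.4),
                          noise_sd = 0.2, seed = 8)
  tab <- lib$table
  res <- fit_group_quadratics(tab, tab$group, min_group_size = 3)
  for (lev in names(res$fits)) {
    sub <- tab[tab$group == lev, , drop = FALSE]
    direct <- fit_ols(sub, c("alogps", "alogps-sq"))
    expect_equal(res$fits[[lev]]$coefficients, direct$coefficients,
                 tolerance = 1e-12)
    expect_equal(res$fits[[lev]]$r_squared, direct$r_squared,
                 tolerance = 1e-12)
  }
})

test_that("group vertices shift when groups are built with shifted optima", {
  x <- seq(1.5, 6.5, length.out = 10)
  yA <- 1 - 0.2 * (x - 3)^2
  yB <- 1 - 0.2 * (x - 5)^2
  tab <- quad_table(c(x, x), c(yA, yB))
  res <- fit_group_quadratics(tab, rep(c("A", "B"), each = 10))
  vA <- optimum_logp(res$fits$A)
  vB <- optimum_logp(res$fits$B)
  expect_equal(vA, 3, tolerance = 1e-6)
  expect_equal(vB, 5, tolerance = 1e-6)
})

test_that("a single group collapses the shared-curvature model to OLS", {
  lib <- simulate_library(n_compounds = 20, noise_sd = 0.2, seed = 21)
  tab <- lib$table
  direct <- fit_ols(tab, c("alogps", "alogps-sq"))
  for (mode in c("fixed_offsets", "random_intercept")) {
    f <- fit_shared_curvature(tab, rep("only", 20), mode = mode)
    expect_equal(f$beta_linear, direct$coefficients[["alogps"]],
                 tolerance = 1e-12)
    expect_equal(f$beta_quad, direct$coefficients[["alogps-sq"]],
                 tolerance = 1e-12)
    expect_equal(unname(f$group_offsets), 0)
  }
})

test_that("shared-curvature fits recover planted group offsets", {
  lib <- simulate_library(n_compounds = 60,
                          group_offsets = c(A = -0.5, B = 0, C = 0.5),
                          noise_sd = 0.1, seed = 42)
  tab <- lib$table
  for (mode in c("fixed_offsets", "random_intercept")) {
    f <- fit_shared_curvature(tab, tab$group, mode = mode)
    off <- f$group_offsets[c("A", "B", "C")]
    expect_true(all(abs(off - c(-0.5, 0, 0.5)) < 0.15), label = mode)
    expect_lt(abs(f$beta_linear - 1.2) / 1.2, 0.10)
    expect_lt(abs(f$beta_quad - (-0.13)) / 0.13, 0.10)
  }
  # sum-to-zero identification of the fixed offsets
  ff <- fit_shared_curvature(tab, tab$group, mode = "fixed_offsets")
  expect_equal(sum(ff$group_offsets), 0, tolerance = 1e-10)
})

test_that("REML profile matches lme4 and is unimodal on clean data", {
  lib <- simulate_library(n_compounds = 60,
                          group_offsets = c(A = -0.5, B = 0, C = 0.5),
                          noise_sd = 0.1, seed = 42)
  tab <- lib$table
  f <- fit_shared_curvature(tab, tab$group, mode = "random_intercept")
  d <- data.frame(y = log_potency(tab$ec50_molpct), x = tab$alogps,
                  g = tab$group)
  lm4 <- lme4::lmer(y ~ x + I(x^2) + (1 | g), data = d, REML = TRUE)
  fe <- lme4::fixef(lm4)
  expect_equal(f$global_intercept, unname(fe[1]), tolerance = 1e-5)
  expect_equal(f$beta_linear, unname(fe[2]), tolerance = 1e-5)
  expect_equal(f$beta_quad, unname(fe[3]), tolerance = 1e-5)
  expect_equal(f$offset_variance,
               unname(unlist(lme4::VarCorr(lm4))), tolerance = 1e-4)
  expect_equal(f$sigma2, lme4::getME(lm4, "sigma")^2, tolerance = 1e-4)
  expect_equal(unname(f$group_offsets),
               unname(unlist(lme4::ranef(lm4)$g)), tolerance = 1e-4)

  # profiled REML criterion has a single interior minimum on the grid
  crit <- f$profile$reml_criterion
  expect_equal(sum(diff(sign(diff(crit))) != 0), 1)
  expect_true(which.min(crit) > 1 && which.min(crit) < length(crit))
})

test_that("offset variance vanishes as group differences vanish", {
  lib <- simulate_library(n_compounds = 60,
                          group_offsets = c(A = 0, B = 0, C = 0),
                          noise_sd = 0.1, seed = 77)
  tab <- lib$table
  f <- fit_shared_curvature(tab, tab$group, mode = "random_intercept")
  pooled <- fit_ols(tab, c("alogps", "alogps-sq"))
  expect_lt(f$offset_variance, 0.01)
  expect_equal(f$beta_linear, pooled$coefficients[["alogps"]],
               tolerance = 0.02)
  expect_equal(f$beta_quad, pooled$coefficients[["alogps-sq"]],
               tolerance = 0.02)
})
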