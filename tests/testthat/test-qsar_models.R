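test_that("fit_ols agrees with the normal-equations oracle", {
  set.seed(71)
  for (case in 1:20) {
    n <- sample(10:30, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- rnorm(n)
    df <- as.data.frame(X)
    f <- fit_ols(df, colnames(X), response = y)
    or <- ols_oracle(X, y)
    expect_equal(unname(c(f$intercept, f$coefficients)), unname(or$beta),
                 tolerance = 1e-10)
    expect_equal(f$r_squared, or$r_squared, tolerance = 1e-10)
    expect_equal(unname(f$se), unname(or$se), tolerance = 1e-10)
  }
})

test_that("t-based intervals match the standard linear-model machinery", {
  tab <- load_compound_table("table1")
  f <- fit_ols(tab, c("alogps", "alogps-sq"))
  lmfit <- stats::lm(y ~ x + I(x^2),
                     data = data.frame(y = log_potency(tab$ec50_molpct),
                                       x = tab$alogps))
  expect_equal(unname(c(f$intercept, f$coefficients)),
               unname(coef(lmfit)), tolerance = 1e-12)
  expect_equal(unname(f$ci), unname(stats::confint(lmfit)),
               tolerance = 1e-12)
  expect_equal(f$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)
})

test_that("exact relationships and degenerate designs behave", {
  df <- data.frame(x = 1:10)
  f <- fit_ols(df, "x", response = 2 + 3 * df$x)
  expect_equal(f$r_squared, 1)
  expect_lt(max(abs(f$residuals)), 1e-10)

  df2 <- data.frame(a = rnorm(10), b = 0)
  df2$b <- df2$a  # duplicated column
  expect_error(fit_ols(df2, c("a", "b"), response = rnorm(10)),
               "collinear.*b")
  expect_error(fit_ols(df[1:2, , drop = FALSE], "x", response = 1:2),
               "n_obs")
  expect_error(fit_ols(df, c("x", "x"), response = rnorm(10)),
               "duplicate")
  expect_error(fit_ols(df, "missing_term", response = rnorm(10)),
               "not found")
})

test_that("squared terms are derived on demand by name", {
  tab <- load_compound_table("table1")
  f <- fit_ols(tab, c("alogps", "alogps-sq"))
  manual <- data.frame(a = tab$alogps, asq = tab$alogps^2)
  f2 <- fit_ols(manual, c("a", "asq"),
                response = log_potency(tab$ec50_molpct))
  expect_equal(unname(f$coefficients), unname(f2$coefficients),
               tolerance = 1e-12)
})

test_that("enumeration matches a brute-force all-subsets oracle", {
  lib <- simulate_library(seed = 5)
  y <- log_potency(lib$table$ec50_molpct)
  desc <- lib$descriptors
  desc$alogps_sq <- desc$alogps^2  # 7 candidate columns
  rk <- enumerate_models(y, desc, max_terms = 3)
  or <- enumerate_oracle(y, desc, max_terms = 3)
  expect_equal(nrow(rk$table), nrow(or))
  expect_identical(rk$table$terms, or$terms)
  expect_equal(rk$table$r_squared, or$r_squared, tolerance = 1e-10)

  # adding a term never decreases the best R^2 at each model size
  best_by_k <- tapply(rk$table$r_squared, rk$table$n_terms, max)
  expect_true(all(diff(best_by_k) >= -1e-12))
})

test_that("enumeration ranking is stable under column permutation", {
  lib <- simulate_library(seed = 9)
  y <- log_potency(lib$table$ec50_molpct)
  desc <- lib$descriptors
  rk1 <- enumerate_models(y, desc, max_terms = 2)
  rk2 <- enumerate_models(y, desc[, rev(names(desc))], max_terms = 2)
  expect_identical(rk1$table, rk2$table)
})

test_that("tied duplicate descriptors rank adjacently in name order", {
  lib <- simulate_library(seed = 13, n_decoys = 3)
  y <- log_potency(lib$table$ec50_molpct)
  desc <- lib$descriptors
  desc$decoy_01b <- desc$decoy_01
  rk <- enumerate_models(y, desc, max_terms = 2)
  i1 <- which(rk$table$terms == "decoy_01")
  i2 <- which(rk$table$terms == "decoy_01b")
  expect_equal(rk$table$r_squared[i1], rk$table$r_squared[i2])
  expect_equal(i2, i1 + 1L)
  expect_gte(rk$n_skipped, 1L)  # the {decoy_01, decoy_01b} subset

  expect_error(enumerate_models(y, desc, candidate_subset = "nope"),
               "not in matrix")
})

test_that("top_k and single-subset enumeration behave", {
  tab <- load_compound_table("table1")
  y <- log_potency(tab$ec50_molpct)
  desc <- descriptor_matrix(data.frame(alogps = tab$alogps,
                                       `alogps-sq` = tab$alogps^2,
                                       check.names = FALSE),
                            tab$compound_id)
  rk <- enumerate_models(y, desc, max_terms = 2)
  expect_equal(nrow(rk$table), 3L)
  top <- rk$fits[[rk$table$terms[1]]]
  full <- fit_ols(tab, c("alogps", "alogps-sq"))
  expect_equal(top$r_squared, full$r_squared, tolerance = 1e-12)
  rk1 <- enumerate_models(y, desc, max_terms = 2, top_k = 1)
  expect_equal(nrow(rk1$table), 1L)
})

test_that("parabola vertex gives the optimum log P", {
  # vertex of the printed whole-dataset coefficients
  expect_equal(-1.203 / (2 * -0.133), 4.5226, tolerance = 1e-4)

  x <- seq(0, 6, by = 0.5)
  tab <- quad_table(x, 2 - 0.25 * (x - 3)^2)  # symmetric about 3
  f <- fit_ols(tab, c("alogps", "alogps-sq"))
  expect_equal(optimum_logp(f), 3, tolerance = 1e-6)

  tab_up <- quad_table(x, 1 + 0.1 * (x - 3)^2)
  f_up <- fit_ols(tab_up, c("alogps", "alogps-sq"))
  expect_error(optimum_logp(f_up), "no interior maximum")
  f_lin <- fit_ols(tab, "alogps")
  expect_error(optimum_logp(f_lin), "pair")
})
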