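# Shared oracles and fixture builders, independent of the package's own
# fitting paths.

# Normal-equations OLS: explicit (X'X)^-1 X'y with an intercept column.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  xtx_inv <- solve(t(X1) %*% X1)
  beta <- drop(xtx_inv %*% t(X1) %*% y)
  res <- y - drop(X1 %*% beta)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (length(y) - ncol(X1))
  list(beta = beta, r_squared = 1 - sse / sst,
       se = sqrt(diag(xtx_inv) * sigma2),
       df = length(y) - ncol(X1))
}

# Direct covariance/variance Pearson correlation.
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Build a compound_table in code from log P and log-potency vectors.
quad_table <- function(logp, y, group = NULL) {
  tab <- data.frame(
    compound_id = sprintf("C%03d", seq_along(logp)),
    ec50_molpct = 10^(-y),
    hill_n = 1, kini_pct_per_s = 1,
    alogps = logp, rt_min = NA_real_,
    r4 = NA_character_, r5 = NA_character_, r6_class = NA_character_,
    ec50_imputed = FALSE, stringsAsFactors = FALSE)
  if (!is.null(group)) tab$group <- group
  class(tab) <- c("compound_table", "data.frame")
  tab
}

# Brute-force all-subsets enumeration via lm(), ranked by R^2 then terms.
enumerate_oracle <- function(y, mat, max_terms) {
  cands <- sort(names(mat))
  rows <- list()
  for (k in seq_len(max_terms)) {
    for (s in utils::combn(cands, k, simplify = FALSE)) {
      X <- as.matrix(mat[s])
      if (qr(cbind(1, X))$rank < k + 1L) next
      r2 <- summary(stats::lm(y ~ X))$r.squared
      rows[[length(rows) + 1L]] <- data.frame(
        terms = paste(s, collapse = "+"), r_squared = r2,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$r_squared, out$terms), , drop = FALSE]
}
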