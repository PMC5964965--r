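test_that("cleaning removes incomplete, non-numeric and invariant columns", {
  m <- descriptor_matrix(data.frame(
    A = c(1, 2, 3), B = c(1, NA, 3), C = c(0.5, 0.7, 0.2),
    const = c(5, 5, 5), words = c("x", "y", "z"),
    as_text = c("1.5", "2.5", "3.5"),
    stringsAsFactors = FALSE), c("c1", "c2", "c3"))
  out <- clean_descriptors(m)
  expect_identical(out$report$removed_incomplete, "B")
  expect_identical(out$report$removed_nonnumeric, "words")
  expect_identical(out$report$removed_low_variation, "const")
  expect_setequal(out$report$retained, c("A", "C", "as_text"))
  # numeric-as-text column is parsed and kept numeric
  expect_equal(out$matrix$as_text, c(1.5, 2.5, 3.5))
  # the four report lists partition the input names
  all_names <- unlist(out$report, use.names = FALSE)
  expect_setequal(all_names, names(m))
  expect_equal(length(all_names), ncol(m))
})

test_that("variation threshold is relative to the column mean", {
  m <- descriptor_matrix(data.frame(
    tight = 1000 + c(-1e-6, 0, 1e-6),      # sd/|mean| ~ 1e-9
    loose = 1000 + c(-1, 0, 1)),
    c("c1", "c2", "c3"))
  out <- clean_descriptors(m, variation_threshold = 1e-8)
  expect_identical(out$report$removed_low_variation, "tight")
  expect_identical(out$report$retained, "loose")
  # threshold 0 keeps everything non-constant
  out0 <- clean_descriptors(m, variation_threshold = 0)
  expect_setequal(out0$report$retained, c("tight", "loose"))
})

test_that("cleaning is idempotent and errors when nothing survives", {
  lib <- simulate_library(seed = 3)
  once <- clean_descriptors(lib$descriptors)
  twice <- clean_descriptors(once$matrix)
  expect_identical(names(twice$matrix), names(once$matrix))
  expect_length(twice$report$removed_incomplete, 0)
  expect_length(twice$report$removed_low_variation, 0)

  bad <- descriptor_matrix(data.frame(a = c(1, 1), b = c(NA, 2)),
                           c("c1", "c2"))
  expect_error(clean_descriptors(bad), "no descriptors retained")
})

test_that("a 506-column matrix with 176 planted defects reduces to 330", {
  set.seed(2024)
  n <- 43
  cols <- list()
  for (i in 1:330) cols[[sprintf("good_%03d", i)]] <- rnorm(n, 10, 3)
  for (i in 1:80) {
    x <- rnorm(n); x[sample(n, 1 + i %% 5)] <- NA
    cols[[sprintf("miss_%03d", i)]] <- x
  }
  for (i in 1:50) cols[[sprintf("const_%03d", i)]] <- rep(i * 1.5, n)
  for (i in 1:46) cols[[sprintf("text_%03d", i)]] <-
    sample(letters, n, replace = TRUE)
  m <- descriptor_matrix(as.data.frame(cols), sprintf("c%02d", 1:n))
  expect_equal(ncol(m), 506L)
  out <- clean_descriptors(m)
  expect_equal(length(out$report$retained), 330L)
  expect_equal(length(out$report$removed_incomplete), 80L)
  expect_equal(length(out$report$removed_nonnumeric), 46L)
  expect_equal(length(out$report$removed_low_variation), 50L)
})

test_that("lipophilicity ranking orders candidates by |r| with rt", {
  tab <- load_compound_table("table1")
  cand <- descriptor_matrix(
    data.frame(self = tab$rt_min,
               anti = -tab$rt_min,
               alogps = tab$alogps,
               noise = sin(seq_len(43) * 2.3) * 10),
    tab$compound_id)
  rk <- rank_lipophilicity_descriptors(tab, cand)
  # perfect positive and negative correlations tie at |r| = 1,
  # broken by name: "anti" < "self"
  expect_equal(rk$descriptor[1:2], c("anti", "self"))
  expect_equal(rk$r[1:2], c(-1, 1))
  # pairwise-complete Pearson equals the direct formula oracle
  r_or <- pearson_oracle(tab$alogps, tab$rt_min)
  expect_equal(rk$r[rk$descriptor == "alogps"], r_or, tolerance = 1e-12)
  expect_equal(rk$n[rk$descriptor == "alogps"], 39)
  expect_gt(abs(r_or), 0.85)  # computed log P tracks measured RT closely
  expect_equal(rk$descriptor[4], "noise")
})

test_that("ranking is invariant under affine rescaling of a candidate", {
  tab <- load_compound_table("table1")
  c1 <- descriptor_matrix(data.frame(a = tab$alogps), tab$compound_id)
  c2 <- descriptor_matrix(data.frame(a = -3.7 * tab$alogps + 12),
                          tab$compound_id)
  r1 <- rank_lipophilicity_descriptors(tab, c1)$r
  r2 <- rank_lipophilicity_descriptors(tab, c2)$r
  expect_equal(abs(r1), abs(r2), tolerance = 1e-12)

  few <- tab[1:4, ]
  few$rt_min <- c(1, NA, NA, 2)
  expect_error(
    rank_lipophilicity_descriptors(
      few, descriptor_matrix(data.frame(a = few$alogps),
                             few$compound_id)),
    "fewer than 3")
})
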