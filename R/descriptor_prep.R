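# Descriptor-matrix cleaning and lipophilicity-descriptor screening.

#' Clean a descriptor matrix
#'
#' Applies the three removal rules, in order: (1) descriptors with any
#' missing value; (2) descriptors that cannot be parsed as numeric
#' (character columns that parse completely are converted and kept);
#' (3) descriptors with little or no variation, defined as sample standard
#' deviation `<= variation_threshold * |mean|` — exactly constant columns
#' are removed regardless of the threshold. The default threshold 1e-8 is
#' effectively "constant only": what counts as negligible variation is a
#' modelling choice, so it is exposed rather than hard-coded.
#'
#' @param matrix A `descriptor_matrix` (or plain `data.frame`).
#' @param variation_threshold Relative variation cut-off, dimensionless.
#' @return A list with `matrix` (cleaned, all-numeric `descriptor_matrix`)
#'   and `report` (a `cleaning_report`: character vectors
#'   `removed_incomplete`, `removed_nonnumeric`, `removed_low_variation`,
#'   `retained`, which partition the input descriptor names).
#' @export
clean_descriptors <- function(matrix, variation_threshold = 1e-8) {
  if (!is.data.frame(matrix) || ncol(matrix) == 0L || nrow(matrix) == 0L) {
    stop("descriptor matrix must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(variation_threshold >= 0)
  nms <- names(matrix)
  incomplete <- nms[vapply(matrix, anyNA, logical(1))]
  rest <- setdiff(nms, incomplete)

  nonnumeric <- character()
  values <- list()
  for (col in rest) {
    x <- matrix[[col]]
    if (is.numeric(x)) {
      values[[col]] <- as.numeric(x)
    } else if (is.logical(x)) {
      values[[col]] <- as.numeric(x)
    } else {
      parsed <- suppressWarnings(as.numeric(as.character(x)))
      if (anyNA(parsed)) nonnumeric <- c(nonnumeric, col)
      else values[[col]] <- parsed
    }
  }
  rest <- setdiff(rest, nonnumeric)

  low_var <- character()
  for (col in rest) {
    x <- values[[col]]
    s <- sd(x)
    if (s == 0 || s <= variation_threshold * abs(mean(x))) {
      low_var <- c(low_var, col)
    }
  }
  retained <- setdiff(rest, low_var)
  if (!length(retained)) stop("no descriptors retained", call. = FALSE)

  cleaned <- descriptor_matrix(
    as.data.frame(values[retained], check.names = FALSE,
                  optional = TRUE),
    rownames(matrix))
  report <- structure(list(removed_incomplete = incomplete,
                           removed_nonnumeric = nonnumeric,
                           removed_low_variation = low_var,
                           retained = retained),
                      class = "cleaning_report")
  list(matrix = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "Descriptor cleaning: %d retained (%d incomplete, %d non-numeric, %d low-variation removed)\n",
    length(x$retained), length(x$removed_incomplete),
    length(x$removed_nonnumeric), length(x$removed_low_variation)))
  invisible(x)
}

#' Rank candidate lipophilicity descriptors against measured retention time
#'
#' Reverse-phase HPLC retention time is an experimental lipophilicity
#' proxy; computed log P descriptors are screened by their Pearson
#' correlation with it. Correlations are computed pairwise-complete
#' (compounds with missing retention time are dropped per descriptor) and
#' ranked by |r| descending, ties broken by descriptor name.
#'
#' @param table A `compound_table` supplying `rt_min`.
#' @param candidates A `descriptor_matrix` of numeric candidate columns,
#'   rows aligned with (or named by) the table's compounds.
#' @return A `data.frame` with columns `descriptor`, `r`, `n` (complete
#'   pairs), ordered best first.
#' @export
rank_lipophilicity_descriptors <- function(table, candidates) {
  stopifnot(inherits(table, "compound_table"), is.data.frame(candidates))
  rt <- table$rt_min
  if (!is.null(rownames(candidates)) &&
      all(table$compound_id %in% rownames(candidates))) {
    candidates <- candidates[table$compound_id, , drop = FALSE]
  } else if (nrow(candidates) != nrow(table)) {
    stop("candidate rows must match the compound table", call. = FALSE)
  }
  res <- lapply(names(candidates), function(col) {
    x <- as.numeric(candidates[[col]])
    ok <- !is.na(x) & !is.na(rt)
    if (sum(ok) < 3L) {
      stop(sprintf("descriptor '%s': fewer than 3 complete pairs with rt",
                   col), call. = FALSE)
    }
    data.frame(descriptor = col, r = cor(x[ok], rt[ok]), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$r), out$descriptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
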