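# Compound-table and descriptor-matrix I/O.
#
# The canonical compound schema is one row per compound:
#   compound_id, ec50_molpct, hill_n, kini_pct_per_s, alogps, rt_min,
#   r4, r5, r6_class, ec50_imputed
# EC50 is the carrier loading (mol% relative to POPC) giving 50% chloride
# efflux at 300 s; k_ini the initial release rate in % s^-1; alogps a
# software-predicted octanol-water log P; rt_min the reverse-phase HPLC
# retention time ("n.d." in the source table parses to NA). r4/r5/r6_class
# are optional substituent annotations (ring, enamine, R-group class).

.required_compound_cols <- c("compound_id", "ec50_molpct", "hill_n",
                             "kini_pct_per_s", "alogps", "rt_min")
.numeric_compound_cols <- c("ec50_molpct", "hill_n", "kini_pct_per_s",
                            "alogps", "rt_min")

.parse_numeric_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable numeric value '%s' at row %d",
                 col, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Load a compound table
#'
#' Reads a compound CSV in the canonical schema (see
#' [write_compound_table()]) and returns a validated `compound_table`.
#' The packaged 43-compound transport dataset (EC50, Hill n, initial rate,
#' ALOGPs, retention time) is available as the fixture `"table1"`.
#'
#' Missing values may be written as an empty cell, `NA`, or `n.d.`; all
#' parse to `NA`. The `ec50_imputed` flag marks EC50 values that were not
#' measured directly but inferred from the initial-rate calibration
#' (compound 43 in the packaged dataset); it defaults to `FALSE` when the
#' column is absent.
#'
#' @param source Path to a CSV file, or the fixture name `"table1"`.
#' @return A `compound_table`: a `data.frame` with the canonical columns,
#'   numeric measurement columns, logical `ec50_imputed`, and a
#'   `provenance` attribute.
#' @examples
#' tab <- load_compound_table("table1")
#' nrow(tab)            # 43
#' sum(is.na(tab$rt_min))  # 4 compounds without retention time
#' @export
load_compound_table <- function(source = "table1") {
  provenance <- source
  if (identical(source, "table1")) {
    source <- system.file("extdata", "table1_compounds.csv",
                          package = "tambja", mustWork = TRUE)
    provenance <- "packaged 43-compound transport dataset (table1)"
  }
  if (!file.exists(source)) {
    stop(sprintf("compound table not found: '%s'", source), call. = FALSE)
  }
  raw <- tryCatch(
    read.csv(source, colClasses = "character",
             na.strings = c("", "NA", "n.d."), check.names = FALSE),
    error = function(e) {
      stop(sprintf("schema error reading '%s': %s", source,
                   conditionMessage(e)), call. = FALSE)
    })
  missing_cols <- setdiff(.required_compound_cols, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab <- data.frame(compound_id = as.character(raw$compound_id),
                    stringsAsFactors = FALSE)
  for (col in .numeric_compound_cols) {
    tab[[col]] <- .parse_numeric_col(raw[[col]], col)
  }
  for (col in c("r4", "r5", "r6_class")) {
    tab[[col]] <- if (col %in% names(raw)) as.character(raw[[col]]) else
      NA_character_
  }
  tab$ec50_imputed <- if ("ec50_imputed" %in% names(raw)) {
    flag <- toupper(trimws(raw$ec50_imputed)) %in% c("TRUE", "T", "1")
    flag
  } else rep(FALSE, nrow(tab))
  attr(tab, "provenance") <- provenance
  class(tab) <- c("compound_table", "data.frame")
  tab
}

#' Write a compound table
#'
#' Inverse of [load_compound_table()]: writes the canonical CSV schema with
#' missing values as empty cells and numeric values at full (round-trip)
#' precision, so `load_compound_table(write_compound_table(tab, f))`
#' reproduces `tab` exactly, including missingness and imputation flags.
#'
#' @param table A `compound_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path) {
  stopifnot(inherits(table, "compound_table"))
  out <- data.frame(compound_id = table$compound_id,
                    stringsAsFactors = FALSE)
  for (col in .numeric_compound_cols) out[[col]] <- fmt_num(table[[col]])
  for (col in c("r4", "r5", "r6_class")) out[[col]] <- table[[col]]
  out$ec50_imputed <- ifelse(table$ec50_imputed, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a compound table
#'
#' Checks the record-level invariants of the compound schema (positive
#' EC50, k_ini and Hill n where present; unique compound identifiers) and
#' reports violations rather than raising errors.
#'
#' @param table A `compound_table`.
#' @return A `data.frame` with columns `compound_id`, `field`, `message`;
#'   zero rows for a valid table.
#' @examples
#' nrow(validate_table(load_compound_table("table1")))  # 0
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  v <- list()
  add <- function(id, field, message) {
    v[[length(v) + 1L]] <<- data.frame(compound_id = id, field = field,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  dup <- table$compound_id[duplicated(table$compound_id)]
  for (id in unique(dup)) add(id, "compound_id", "duplicate id")
  for (i in seq_len(nrow(table))) {
    id <- table$compound_id[i]
    if (is.na(table$ec50_molpct[i])) add(id, "ec50_molpct", "ec50 missing")
    else if (table$ec50_molpct[i] <= 0) add(id, "ec50_molpct",
                                            "ec50 must be positive")
    if (!is.na(table$kini_pct_per_s[i]) && table$kini_pct_per_s[i] <= 0) {
      add(id, "kini_pct_per_s", "kini must be positive")
    }
    if (!is.na(table$hill_n[i]) && table$hill_n[i] <= 0) {
      add(id, "hill_n", "hill_n must be positive")
    }
  }
  if (!length(v)) {
    return(data.frame(compound_id = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Construct a descriptor matrix
#'
#' A descriptor matrix is a `data.frame` of one row per compound (row names
#' are the compound ids) and one column per molecular descriptor. Columns
#' may be non-numeric or contain missing values on input; such columns are
#' handled by [clean_descriptors()].
#'
#' @param values A `data.frame` of descriptor columns.
#' @param compound_ids Character vector of compound labels, one per row.
#' @return A `descriptor_matrix` (a classed `data.frame`).
#' @export
descriptor_matrix <- function(values, compound_ids = rownames(values)) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (is.null(compound_ids)) {
    stop("compound_ids required (or set as rownames)", call. = FALSE)
  }
  if (length(compound_ids) != nrow(values)) {
    stop("row count must equal compound count", call. = FALSE)
  }
  if (anyDuplicated(names(values))) {
    stop("descriptor names must be unique", call. = FALSE)
  }
  rownames(values) <- as.character(compound_ids)
  class(values) <- c("descriptor_matrix", "data.frame")
  values
}

#' Load a descriptor matrix from CSV
#'
#' Expects a `compound_id` column followed by one column per descriptor.
#'
#' @param path CSV path.
#' @return A `descriptor_matrix`.
#' @export
load_descriptor_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("descriptor matrix not found: '%s'", path), call. = FALSE)
  }
  raw <- read.csv(path, na.strings = c("", "NA"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(raw)) {
    stop("schema error: missing required column(s): compound_id",
         call. = FALSE)
  }
  ids <- as.character(raw$compound_id)
  descriptor_matrix(raw[setdiff(names(raw), "compound_id")], ids)
}

#' Write a descriptor matrix to CSV
#'
#' @param matrix A `descriptor_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(matrix, path) {
  out <- cbind(data.frame(compound_id = rownames(matrix),
                          stringsAsFactors = FALSE),
               as.data.frame(matrix))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
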