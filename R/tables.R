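#' Read a delimited sample table
#'
#' Reads a tab- or comma-delimited text file with a header row into a typed
#' sample table. Cells equal to `NA` (or empty) are treated as missing.
#' Each non-id column is tagged with a kind (`biomarker`, `covariate` or
#' `exposure`) used downstream to route columns to the right pre-processing.
#'
#' @param path Path to the delimited file.
#' @param column_kinds Named character vector mapping column names to one of
#'   `"biomarker"`, `"covariate"`, `"exposure"`. Columns not named here get
#'   kind `NA`.
#' @param id_col Name of the sample-identifier column (default
#'   `"sample_id"`).
#' @return A `sample_table`: list with `data` (tibble, id column first) and
#'   `kinds` (tibble of `column`, `kind`).
#' @export
read_sample_table <- function(path, column_kinds = character(), id_col = "sample_id") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, na = c("NA", ""),
                            show_col_types = FALSE, progress = FALSE)
  if (!id_col %in% names(data)) {
    stop_input("sample-id column '%s' not found in %s", id_col, path)
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    stop_input("duplicate sample id '%s'", ids[duplicated(ids)][1])
  }
  bad_kind <- setdiff(column_kinds, c("biomarker", "covariate", "exposure"))
  if (length(bad_kind)) stop_input("unknown column kind '%s'", bad_kind[1])
  unknown_col <- setdiff(names(column_kinds), names(data))
  if (length(unknown_col)) stop_input("column_kinds names column '%s' not in table",
                                      unknown_col[1])
  data[[id_col]] <- ids
  data <- dplyr::relocate(data, dplyr::all_of(id_col))
  other <- setdiff(names(data), id_col)
  kinds <- tibble::tibble(
    column = other,
    kind = unname(column_kinds[other])
  )
  structure(list(data = data, kinds = kinds, id_col = id_col),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples, %d columns\n", nrow(x$data),
              nrow(x$kinds)))
  print(x$kinds)
  invisible(x)
}

summary_stat_schema <- c(
  chrom = "CHR", pos = "POS", id = "ID", a1 = "A1", a2 = "A2", af = "AF",
  n = "N", stat = "STAT", beta = "BETA", se = "SE", dir = "DIR", p = "P",
  kind = "KIND", stratum = "STRATUM"
)

#' Write per-variant summary statistics
#'
#' Writes the fixed tab-delimited schema (`CHR POS ID A1 A2 AF N STAT BETA
#' SE DIR P KIND STRATUM`). Numeric fields survive a write/read roundtrip to
#' full double precision; p-values near the 1e-300 floor are preserved.
#'
#' @param stats Tibble with (lower-case) summary-stat columns as produced by
#'   [run_scan()] or [meta_analyze()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  missing_cols <- setdiff(names(summary_stat_schema), names(stats))
  if (length(missing_cols)) {
    stop_input("summary stats lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- stats[names(summary_stat_schema)]
  names(out) <- unname(summary_stat_schema)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_summary_stats()]
#'
#' @param path Path to the tab-delimited file.
#' @return Tibble with lower-case summary-stat columns.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  cols <- readr::cols(
    CHR = readr::col_character(), POS = readr::col_integer(),
    ID = readr::col_character(), A1 = readr::col_character(),
    A2 = readr::col_character(), AF = readr::col_double(),
    N = readr::col_integer(), STAT = readr::col_double(),
    BETA = readr::col_double(), SE = readr::col_double(),
    DIR = readr::col_integer(), P = readr::col_double(),
    KIND = readr::col_character(), STRATUM = readr::col_character()
  )
  raw <- readr::read_tsv(path, col_types = cols, progress = FALSE)
  missing_cols <- setdiff(unname(summary_stat_schema), names(raw))
  if (length(missing_cols)) {
    stop_input("%s lacks column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  out <- raw[unname(summary_stat_schema)]
  names(out) <- names(summary_stat_schema)
  tibble::as_tibble(out)
}
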