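# Canonical column schema for the four JADER-style tables.  All values are
# read as character; typing happens in merge_tables().
.jader_schema <- list(
  demo = list(required = c("case_id", "sex", "age", "reporting_year"),
              optional = "revision"),
  drug = list(required = c("case_id", "drug_name", "involvement", "start_date"),
              optional = character()),
  reac = list(required = c("case_id", "term", "onset_date", "outcome"),
              optional = character()),
  hist = list(required = c("case_id", "condition"),
              optional = character())
)

.table_kinds <- names(.jader_schema)

#' Describe the on-disk dialect of a JADER-style table
#'
#' A dialect declares how the four delimited tables are written: field
#' delimiter, character encoding, whether a header line is present, and how
#' file column headers map onto the canonical column names
#' (`case_id`, `sex`, `age`, `reporting_year`, optionally `revision` for the
#' demographics table; `drug_name`, `involvement`, `start_date` for the drug
#' table; `term`, `onset_date`, `outcome` for the adverse-event table;
#' `condition` for the history table).
#'
#' @param delimiter Single-character field separator. Default `","`.
#' @param encoding Character encoding of the file, e.g. `"UTF-8"` or
#'   `"CP932"`. Undecodable bytes raise an error naming the offending line.
#' @param header Logical; is the first line a header? If `FALSE`, the
#'   `column_map` entry for each table kind must be a character vector of
#'   canonical column names in file order.
#' @param column_map `NULL` (file headers are already canonical) or a named
#'   list with one entry per table kind. With `header = TRUE` each entry is a
#'   named character vector mapping file header to canonical name; with
#'   `header = FALSE` it is an unnamed character vector of canonical names in
#'   file order.
#' @return An object of class `table_dialect`.
#' @seealso [jader_dialect()] for the preset matching real JADER downloads.
#' @export
table_dialect <- function(delimiter = ",", encoding = "UTF-8", header = TRUE,
                          column_map = NULL) {
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L,
            is.character(encoding), is.logical(header))
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .table_kinds)
    if (length(bad))
      stop("unknown table kind in column_map: ", paste(bad, collapse = ", "))
  }
  structure(list(delimiter = delimiter, encoding = encoding,
                 header = header, column_map = column_map),
            class = "table_dialect")
}

#' Dialect preset for files as distributed by the PMDA
#'
#' Real JADER extracts are comma-separated, Shift-JIS ("CP932") encoded CSV
#' files with Japanese column headers. This preset maps those headers onto
#' the canonical names, including the report-revision counter used for
#' de-duplication.
#'
#' @return A `table_dialect`.
#' @export
jader_dialect <- function() {
  table_dialect(
    delimiter = ",", encoding = "CP932", header = TRUE,
    column_map = list(
      demo = c("識別番号" = "case_id",
               "報告回数" = "revision",
               "性別" = "sex",
               "年齢" = "age",
               "報告年度" = "reporting_year"),
      drug = c("識別番号" = "case_id",
               "医薬品（一般名）" = "drug_name",
               "医薬品の関与" = "involvement",
               "投与開始日" = "start_date"),
      reac = c("識別番号" = "case_id",
               "有害事象" = "term",
               "発現日" = "onset_date",
               "転帰" = "outcome"),
      hist = c("識別番号" = "case_id",
               "原疾患等" = "condition")
    )
  )
}
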