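# Reading, merging, de-duplicating and filtering the four-table layout.

pv_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pvsignal_error")))
}

#' Read one JADER-style table
#'
#' Reads a delimited text file into a validated raw table. All fields are
#' kept as character strings; empty strings are preserved as the missing
#' marker. Row order is preserved.
#'
#' @param path Path to the file.
#' @param kind One of `"demo"`, `"drug"`, `"reac"`, `"hist"`.
#' @param dialect A [table_dialect()].
#' @return A data frame of character columns in canonical names with class
#'   `jader_table` and attribute `table_kind`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' paths <- write_tables(generate_reports(synthetic_config(n_reports = 20))$tables, dir)
#' demo <- read_jader_table(paths[["demo"]], "demo")
#' head(demo)
#' @export
read_jader_table <- function(path, kind, dialect = table_dialect()) {
  kind <- match.arg(kind, .table_kinds)
  if (!file.exists(path)) pv_error(paste0("file not found: ", path), "pvsignal_io_error")
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "bytes"
  lines <- strsplit(txt, "\r\n|\n|\r")[[1L]]
  conv <- iconv(lines, from = dialect$encoding, to = "UTF-8")
  bad <- which(is.na(conv) & nzchar(lines))
  if (length(bad))
    pv_error(paste0("cannot decode line ", bad[1L], " of ", path,
                    " as ", dialect$encoding), "pvsignal_encoding_error")
  conv <- conv[!(is.na(conv) & !nzchar(lines))]
  df <- utils::read.csv(text = paste(conv, collapse = "\n"),
                        sep = dialect$delimiter, header = dialect$header,
                        colClasses = "character", check.names = FALSE,
                        na.strings = character(), blank.lines.skip = TRUE)

  map <- dialect$column_map[[kind]]
  if (dialect$header) {
    if (!is.null(map)) {
      hit <- match(names(df), names(map))
      names(df)[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
    }
  } else {
    if (is.null(map))
      pv_error(paste0("dialect declares no header and no column names for '",
                      kind, "' table"), "pvsignal_schema_error")
    if (length(map) != ncol(df))
      pv_error(paste0("'", kind, "' table has ", ncol(df),
                      " columns but dialect declares ", length(map)),
               "pvsignal_schema_error")
    names(df) <- unname(map)
  }

  schema <- .jader_schema[[kind]]
  missing_cols <- setdiff(schema$required, names(df))
  if (length(missing_cols))
    pv_error(paste0("'", kind, "' table is missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "pvsignal_schema_error")
  keep <- c(schema$required, intersect(schema$optional, names(df)))
  df <- df[, keep, drop = FALSE]
  empty_id <- which(!nzchar(trimws(df$case_id)))
  if (length(empty_id))
    pv_error(paste0("empty case_id in '", kind, "' table, data row ",
                    empty_id[1L]), "pvsignal_schema_error")
  rownames(df) <- NULL
  structure(df, table_kind = kind, class = c("jader_table", "data.frame"))
}

.as_jader_table <- function(df, kind) {
  structure(df, table_kind = kind, class = c("jader_table", "data.frame"))
}

.check_kind <- function(x, kind) {
  if (!identical(attr(x, "table_kind"), kind))
    pv_error(paste0("expected a '", kind, "' table, got '",
                    attr(x, "table_kind") %||% class(x)[1L], "'"),
             "pvsignal_schema_error")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- value parsers (accept both canonical English and JADER Japanese values)

.parse_sex <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m", "男性", "男")] <- "male"
  out[x %in% c("female", "f", "女性", "女")] <- "female"
  out
}

.parse_age_band <- function(x) {
  x <- trimws(x)
  out <- rep("unknown", length(x))
  band <- grepl("^[0-9]+s$", x)
  out[band] <- x[band]
  jp <- grepl("^[0-9]+歳代$", x)
  out[jp] <- paste0(sub("歳代$", "", x[jp]), "s")
  num <- grepl("^[0-9]+(\\.[0-9]+)?$", x)
  out[num] <- paste0(10L * (as.integer(as.numeric(x[num])) %/% 10L), "s")
  dec <- suppressWarnings(as.integer(sub("s$", "", out)))
  out[!is.na(dec) & dec > 120L] <- "unknown"
  out
}

.band_decade <- function(band) {
  suppressWarnings(as.integer(sub("s$", "", band)))
}

.parse_year <- function(x) {
  m <- regmatches(x, regexpr("[0-9]{4}", x))
  y <- rep(NA_integer_, length(x))
  y[nzchar(x) & lengths(regmatches(x, gregexpr("[0-9]{4}", x))) > 0] <-
    suppressWarnings(as.integer(unlist(m)))
  y[!is.na(y) & (y < 1980L | y > 2100L)] <- NA_integer_
  y
}

.parse_date <- function(x) {
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  f8 <- grepl("^[0-9]{8}$", x)
  out[f8] <- as.Date(x[f8], format = "%Y%m%d")
  fd <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out[fd] <- as.Date(x[fd], format = "%Y-%m-%d")
  fs <- grepl("^[0-9]{4}/[0-9]{2}/[0-9]{2}$", x)
  out[fs] <- as.Date(x[fs], format = "%Y/%m/%d")
  out   # partial dates (year or year-month only) stay missing
}

.parse_involvement <- function(x) {
  x0 <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x0 %in% c("suspected", "suspected drug", "被疑薬")] <- "suspected"
  out[x0 %in% c("concomitant", "concomitant drug", "併用薬")] <- "concomitant"
  out[x0 %in% c("interaction", "相互作用")] <- "interaction"
  if (anyNA(out))
    pv_error(paste0("unrecognized drug involvement code: '",
                    x[which(is.na(out))[1L]], "'"), "pvsignal_value_error")
  out
}

#' Merge the four tables into a de-duplicated report set
#'
#' Integrates demographics, drug history, adverse events and medical history
#' by case identifier. One report is kept per distinct `case_id` appearing in
#' the demographics table: when several demographics rows share a `case_id`,
#' the row with the highest `revision` marker wins (latest report version);
#' without a revision column, the last occurrence in file order wins. Rows in
#' the child tables whose `case_id` has no demographics row are dropped and
#' counted as orphans. Within a report, drug and event rows keep their file
#' order.
#'
#' @param demo,drug,reac,hist Tables read by [read_jader_table()] (or built
#'   by [generate_reports()]).
#' @param quiet Suppress the orphan/duplicate log messages.
#' @return A `report_set`: a list of four typed data frames (`demo`, `drugs`,
#'   `events`, `conditions`) keyed by `case_id`, with attributes
#'   `n_duplicates` (resolved demographics duplicates) and `n_orphans`
#'   (dropped child rows).
#' @export
merge_tables <- function(demo, drug, reac, hist, quiet = FALSE) {
  demo <- .check_kind(demo, "demo"); drug <- .check_kind(drug, "drug")
  reac <- .check_kind(reac, "reac"); hist <- .check_kind(hist, "hist")

  # de-duplicate demographics: highest revision, ties/no revision -> last row
  n0 <- nrow(demo)
  if (n0 > 0L) {
    rev <- if ("revision" %in% names(demo))
      suppressWarnings(as.numeric(demo$revision)) else rep(NA_real_, n0)
    rev[is.na(rev)] <- -Inf
    ord <- order(match(demo$case_id, unique(demo$case_id)), rev, seq_len(n0))
    demo <- demo[ord, , drop = FALSE]
    keep <- !duplicated(demo$case_id, fromLast = TRUE)
    demo <- demo[keep, , drop = FALSE]
  }
  n_dup <- n0 - nrow(demo)

  ids <- demo$case_id
  demo_out <- data.frame(
    case_id = ids,
    sex = .parse_sex(demo$sex),
    age_band = .parse_age_band(demo$age),
    reporting_year = .parse_year(demo$reporting_year),
    stringsAsFactors = FALSE
  )

  n_orph <- 0L
  take <- function(child) {
    drop <- !(child$case_id %in% ids)
    n_orph <<- n_orph + sum(drop)
    child[!drop, , drop = FALSE]
  }
  drug <- take(drug); reac <- take(reac); hist <- take(hist)

  empty_term <- !nzchar(trimws(reac$term))
  if (any(empty_term))
    pv_error(paste0("empty adverse-event term for case ",
                    reac$case_id[which(empty_term)[1L]]),
             "pvsignal_value_error")

  drugs_out <- data.frame(
    case_id = drug$case_id,
    drug_name = trimws(drug$drug_name),
    involvement = .parse_involvement(drug$involvement),
    start_date = .parse_date(drug$start_date),
    stringsAsFactors = FALSE
  )
  events_out <- data.frame(
    case_id = reac$case_id,
    term = trimws(reac$term),
    onset_date = .parse_date(reac$onset_date),
    outcome = trimws(reac$outcome),
    stringsAsFactors = FALSE
  )
  cond_out <- data.frame(
    case_id = hist$case_id,
    condition = trimws(hist$condition),
    stringsAsFactors = FALSE
  )
  rownames(demo_out) <- rownames(drugs_out) <- rownames(events_out) <-
    rownames(cond_out) <- NULL

  if (!quiet && (n_dup > 0L || n_orph > 0L))
    message("merge_tables: resolved ", n_dup, " duplicate demographics row(s), ",
            "dropped ", n_orph, " orphan child row(s)")

  structure(list(demo = demo_out, drugs = drugs_out, events = events_out,
                 conditions = cond_out),
            n_duplicates = n_dup, n_orphans = n_orph,
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat("report_set with", nrow(x$demo), "reports\n")
  cat("  drug rows:     ", nrow(x$drugs), "\n")
  cat("  event rows:    ", nrow(x$events), "\n")
  cat("  condition rows:", nrow(x$conditions), "\n")
  ex <- attr(x, "n_excluded")
  if (!is.null(ex)) cat("  excluded (unknown sex/age):", ex, "\n")
  invisible(x)
}

#' Number of reports in a report set
#' @param x A `report_set`.
#' @return Integer count of reports.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "report_set"))
  nrow(x$demo)
}

.subset_report_set <- function(x, keep_ids) {
  out <- list(
    demo = x$demo[x$demo$case_id %in% keep_ids, , drop = FALSE],
    drugs = x$drugs[x$drugs$case_id %in% keep_ids, , drop = FALSE],
    events = x$events[x$events$case_id %in% keep_ids, , drop = FALSE],
    conditions = x$conditions[x$conditions$case_id %in% keep_ids, , drop = FALSE]
  )
  for (nm in names(out)) rownames(out[[nm]]) <- NULL
  attributes(out) <- c(attributes(out),
                       attributes(x)[setdiff(names(attributes(x)), c("names", "class"))])
  class(out) <- "report_set"
  out
}

#' Exclude reports with unknown sex or unknown age
#'
#' Reports whose sex or age band could not be established are removed from
#' the analysis population. The number of exclusions is attached as the
#' `n_excluded` attribute of the result.
#'
#' @param records A `report_set` from [merge_tables()].
#' @return A filtered `report_set`.
#' @export
filter_valid <- function(records) {
  stopifnot(inherits(records, "report_set"))
  ok <- records$demo$sex != "unknown" & records$demo$age_band != "unknown"
  out <- .subset_report_set(records, records$demo$case_id[ok])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Serialize a report set as one long inspection table
#'
#' Writes a tab-separated file with one row per (case_id, entity): the
#' demographics row plus one row per drug, event and condition entry.
#'
#' @param records A `report_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_set <- function(records, path) {
  stopifnot(inherits(records, "report_set"))
  fmt <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  rows <- rbind(
    data.frame(case_id = records$demo$case_id, entity = "report",
               value1 = records$demo$sex, value2 = records$demo$age_band,
               value3 = as.character(records$demo$reporting_year),
               stringsAsFactors = FALSE),
    data.frame(case_id = records$drugs$case_id, entity = "drug",
               value1 = records$drugs$drug_name,
               value2 = records$drugs$involvement,
               value3 = fmt(records$drugs$start_date), stringsAsFactors = FALSE),
    data.frame(case_id = records$events$case_id, entity = "event",
               value1 = records$events$term,
               value2 = fmt(records$events$onset_date),
               value3 = records$events$outcome, stringsAsFactors = FALSE),
    data.frame(case_id = records$conditions$case_id, entity = "condition",
               value1 = records$conditions$condition, value2 = "", value3 = "",
               stringsAsFactors = FALSE)
  )
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
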