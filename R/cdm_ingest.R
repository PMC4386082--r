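## Ingest of the minimal OMOP-CDM-like event tables.
##
## Five comma-delimited tables with a header row are understood:
##   condition_occurrence: patient_id, phenotype_code, event_date
##   drug_exposure:        patient_id, drug_code, event_date
##   procedure_occurrence: patient_id, procedure_code, code_system, event_date
##   fee_schedule:         procedure_code, rate_per_minute, typical_minutes
##   reference_standard:   phenotype_code, label
## Dates are ISO 8601 by default. Rows failing validation are rejected with a
## logged count (attribute "n_rejected"), never silently dropped.

.required_columns <- list(
  conditions   = c("patient_id", "phenotype_code", "event_date"),
  drugs        = c("patient_id", "drug_code", "event_date"),
  procedures   = c("patient_id", "procedure_code", "code_system", "event_date"),
  fee_schedule = c("procedure_code", "rate_per_minute", "typical_minutes"),
  reference    = c("phenotype_code", "label")
)

.log_msg <- function(quiet, ...) if (!quiet) message(...)

#' Read one CDM-like event table
#'
#' Validates the header and every row. Invalid rows (unparseable date, empty
#' code, unknown `code_system`, negative fee fields, label outside
#' mild/severe) are rejected and logged with their row numbers; a missing
#' required column is a hard error naming the column.
#'
#' @param path path to a delimited text file with a header row.
#' @param type one of `"conditions"`, `"drugs"`, `"procedures"`,
#'   `"fee_schedule"`, `"reference"`.
#' @param sep field delimiter (default comma).
#' @param date_format date format string (default ISO 8601, `"%Y-%m-%d"`).
#' @param quiet suppress log messages.
#' @return A `data.frame` with the table's canonical columns; dates are
#'   `Date`, codes are character. Attribute `"n_rejected"` carries the count
#'   of rejected rows.
#' @export
read_event_table <- function(path, type, sep = ",", date_format = "%Y-%m-%d",
                             quiet = FALSE) {
  type <- match.arg(type, names(.required_columns))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE, stringsAsFactors = FALSE)
  validate_event_table(df, type, date_format = date_format, quiet = quiet,
                       source = path)
}

#' Validate an in-memory event table
#'
#' Same contract as [read_event_table()] for tables already in R.
#' @param df data.frame to validate.
#' @inheritParams read_event_table
#' @param source label used in log messages.
#' @return validated data.frame with attribute `"n_rejected"`.
#' @export
validate_event_table <- function(df, type, date_format = "%Y-%m-%d",
                                 quiet = FALSE, source = "table") {
  type <- match.arg(type, names(.required_columns))
  req <- .required_columns[[type]]
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column '", missing_cols[[1L]], "' in ", source,
         " (", type, ")")
  df <- df[, req, drop = FALSE]
  n0 <- nrow(df)
  bad <- rep(FALSE, n0)

  code_col <- intersect(c("phenotype_code", "drug_code", "procedure_code"),
                        req)[1]
  if (!is.na(code_col)) {
    df[[code_col]] <- as.character(df[[code_col]])
    bad <- bad | is.na(df[[code_col]]) | !nzchar(trimws(df[[code_col]]))
  }
  if ("patient_id" %in% req) {
    df$patient_id <- as.character(df$patient_id)
    bad <- bad | is.na(df$patient_id) | !nzchar(trimws(df$patient_id))
  }
  if ("event_date" %in% req) {
    parsed <- as.Date(as.character(df$event_date), format = date_format)
    bad_date <- is.na(parsed)
    if (any(bad_date & !bad))
      .log_msg(quiet, "rejecting ", sum(bad_date & !bad),
               " row(s) with unparseable date in ", source, " (rows ",
               paste(utils::head(which(bad_date & !bad), 10L),
                     collapse = ", "), ")")
    bad <- bad | bad_date
    df$event_date <- parsed
  }
  if ("code_system" %in% req) {
    df$code_system <- as.character(df$code_system)
    bad_sys <- !(df$code_system %in% c("HCPCS", "ICD9PROC"))
    if (any(bad_sys & !bad))
      .log_msg(quiet, "rejecting ", sum(bad_sys & !bad),
               " row(s) with unknown code_system in ", source)
    bad <- bad | bad_sys
  }
  if (type == "fee_schedule") {
    df$rate_per_minute <- suppressWarnings(as.numeric(df$rate_per_minute))
    df$typical_minutes <- suppressWarnings(as.numeric(df$typical_minutes))
    bad_fee <- !is.finite(df$rate_per_minute) | df$rate_per_minute < 0 |
      !is.finite(df$typical_minutes) | df$typical_minutes < 0
    if (any(bad_fee & !bad))
      .log_msg(quiet, "rejecting ", sum(bad_fee & !bad),
               " row(s) with invalid fee fields in ", source)
    bad <- bad | bad_fee
  }
  if (type == "reference") {
    df$label <- as.character(df$label)
    bad_lab <- !(df$label %in% c("mild", "severe"))
    if (any(bad_lab & !bad))
      .log_msg(quiet, "rejecting ", sum(bad_lab & !bad),
               " row(s) with label outside {mild, severe} in ", source)
    bad <- bad | bad_lab
    dup <- duplicated(df$phenotype_code)
    if (any(dup & !bad))
      .log_msg(quiet, "rejecting ", sum(dup & !bad),
               " duplicated phenotype_code row(s) in ", source)
    bad <- bad | dup
  }

  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Load the full set of event tables
#'
#' @param paths named list or character vector with elements `conditions`,
#'   `drugs`, `procedures`, `fee_schedule` and optionally `reference`.
#' @inheritParams read_event_table
#' @return named list of validated tables (class `"event_tables"`), with a
#'   `rejected` element counting rejected rows per table.
#' @export
load_event_tables <- function(paths, sep = ",", date_format = "%Y-%m-%d",
                              quiet = FALSE) {
  needed <- c("conditions", "drugs", "procedures", "fee_schedule")
  if (!all(needed %in% names(paths)))
    stop("paths must name: ", paste(needed, collapse = ", "))
  types <- intersect(names(.required_columns), names(paths))
  tabs <- lapply(types, function(ty)
    read_event_table(paths[[ty]], ty, sep = sep, date_format = date_format,
                     quiet = quiet))
  names(tabs) <- types
  tabs$rejected <- vapply(tabs[types], function(t)
    as.integer(attr(t, "n_rejected")), integer(1))
  class(tabs) <- "event_tables"
  tabs
}

#' Write event tables back to delimited text
#'
#' Dates are written in ISO 8601 so a written table reloads identically.
#'
#' @param tables list as returned by [load_event_tables()] or
#'   [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_event_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(conditions = "condition_occurrence.csv",
             drugs = "drug_exposure.csv",
             procedures = "procedure_occurrence.csv",
             fee_schedule = "fee_schedule.csv",
             reference = "reference_standard.csv",
             truth = "truth_labels.csv")
  written <- character(0)
  for (nm in names(files)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(dir, files[[nm]])
    df <- tables[[nm]]
    if ("event_date" %in% names(df)) df$event_date <- format(df$event_date)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Phenotype prevalence from the condition table
#'
#' Prevalence of a phenotype is the fraction of patients carrying at least
#' one event of its code. The denominator defaults to the number of distinct
#' patients appearing in the condition table; supply `n_patients` to use an
#' external cohort size instead.
#'
#' @param conditions condition event table.
#' @param n_patients optional external denominator (> 0).
#' @return named numeric vector of prevalence fractions, one per code.
#' @export
compute_prevalence <- function(conditions, n_patients = NULL) {
  if (is.null(conditions) || nrow(conditions) == 0L)
    stop("condition table is empty")
  dt <- data.table::as.data.table(conditions)
  denom <- if (is.null(n_patients)) {
    data.table::uniqueN(dt$patient_id)
  } else {
    stopifnot(is.numeric(n_patients), n_patients > 0)
    n_patients
  }
  counts <- dt[, list(n = data.table::uniqueN(patient_id)),
               by = phenotype_code]
  stats::setNames(counts$n / denom, counts$phenotype_code)
}

#' Filter phenotypes by prevalence
#'
#' Retains codes with prevalence greater than or equal to the threshold
#' (inclusive).
#'
#' @param prevalence named vector from [compute_prevalence()].
#' @param threshold prevalence fraction in \[0, 1\] (default 0.0001).
#' @return character vector of retained phenotype codes.
#' @export
filter_by_prevalence <- function(prevalence, threshold = 1e-4) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  names(prevalence)[prevalence >= threshold]
}
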