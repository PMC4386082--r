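## The five phenotype-level severity measures.
##
## Each measure is a patient-level quantity averaged across all carriers of a
## phenotype (a carrier = a patient with >= 1 condition event of the code):
##   treatment_time   first-to-last condition-event span of the code, in days
##   n_comorbidities  distinct other condition codes over the whole record
##   n_medications    distinct drug codes over the whole record
##   n_procedures     procedure events (both code systems, repeats count)
##   cost             sum over HCPCS procedure events of
##                    rate_per_minute x typical_minutes from the fee schedule
## ICD9PROC events carry no cost; HCPCS codes absent from the fee schedule
## contribute 0 and are logged.

.carriers <- function(conditions, phenotype_code) {
  rows <- conditions$phenotype_code == phenotype_code
  if (!any(rows)) stop("unknown phenotype code: ", phenotype_code)
  unique(conditions$patient_id[rows])
}

.aggregate_fn <- function(aggregate = c("mean", "median", "max")) {
  switch(match.arg(aggregate), mean = mean, median = stats::median, max = max)
}

#' Condition treatment time of a phenotype
#'
#' Per carrier, the span in whole days between the first and last condition
#' event of the code (a single event gives 0); aggregated across carriers.
#'
#' @param conditions condition event table.
#' @param phenotype_code the index phenotype.
#' @param aggregate carrier-level aggregation, `"mean"` (default),
#'   `"median"` or `"max"`.
#' @return treatment time in days.
#' @export
treatment_time <- function(conditions, phenotype_code,
                           aggregate = "mean") {
  rows <- conditions[conditions$phenotype_code == phenotype_code, ,
                     drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown phenotype code: ", phenotype_code)
  spans <- tapply(as.numeric(rows$event_date), rows$patient_id,
                  function(d) max(d) - min(d))
  .aggregate_fn(aggregate)(as.numeric(spans))
}

#' Comorbidity burden of a phenotype
#'
#' Per carrier, the number of distinct condition codes on the patient's
#' record excluding the index code; mean across carriers.
#'
#' @inheritParams treatment_time
#' @return mean comorbidity count.
#' @export
comorbidity_count <- function(conditions, phenotype_code) {
  carriers <- .carriers(conditions, phenotype_code)
  per <- vapply(carriers, function(p) {
    codes <- unique(conditions$phenotype_code[conditions$patient_id == p])
    length(setdiff(codes, phenotype_code))
  }, numeric(1))
  mean(per)
}

#' Medication burden of a phenotype
#'
#' Per carrier, the number of distinct drug codes on the patient's record
#' (carriers with no drug rows contribute 0); mean across carriers.
#'
#' @inheritParams treatment_time
#' @param drugs drug exposure table.
#' @return mean medication count.
#' @export
medication_count <- function(conditions, drugs, phenotype_code) {
  carriers <- .carriers(conditions, phenotype_code)
  per <- vapply(carriers, function(p)
    length(unique(drugs$drug_code[drugs$patient_id == p])), numeric(1))
  mean(per)
}

#' Procedure burden of a phenotype
#'
#' Per carrier, the number of procedure events on the record (both HCPCS and
#' ICD9PROC; repeated events count each time); mean across carriers.
#'
#' @inheritParams treatment_time
#' @param procedures procedure occurrence table.
#' @return mean procedure event count.
#' @export
procedure_count <- function(conditions, procedures, phenotype_code) {
  carriers <- .carriers(conditions, phenotype_code)
  per <- vapply(carriers, function(p)
    sum(procedures$patient_id == p), numeric(1))
  mean(per)
}

#' Treatment cost of a phenotype
#'
#' Per carrier, the summed billable amount of the patient's HCPCS procedure
#' events, each priced as rate_per_minute x typical_minutes from the fee
#' schedule; mean across carriers. ICD9PROC events contribute no cost, and
#' HCPCS codes missing from the fee schedule contribute 0 with a logged
#' count (real fee schedules are incomplete).
#'
#' @inheritParams procedure_count
#' @param fee_schedule fee schedule table.
#' @param quiet suppress the fee-miss log message.
#' @return mean cost per carrier (currency units of the fee schedule).
#' @export
phenotype_cost <- function(conditions, procedures, fee_schedule,
                           phenotype_code, quiet = FALSE) {
  carriers <- .carriers(conditions, phenotype_code)
  fee <- stats::setNames(
    fee_schedule$rate_per_minute * fee_schedule$typical_minutes,
    fee_schedule$procedure_code)
  hc <- procedures[procedures$code_system == "HCPCS", , drop = FALSE]
  miss <- sum(hc$patient_id %in% carriers & !(hc$procedure_code %in% names(fee)))
  if (miss > 0)
    .log_msg(quiet, miss, " HCPCS event(s) without fee-schedule entry for ",
             phenotype_code, "; contributing 0")
  per <- vapply(carriers, function(p) {
    ev <- hc$procedure_code[hc$patient_id == p]
    sum(fee[ev], na.rm = TRUE)
  }, numeric(1))
  mean(per)
}

#' Build the severity profile table
#'
#' Computes all five measures, prevalence and carrier counts for a set of
#' retained phenotype codes in one vectorized pass. Equivalent to calling
#' the five per-phenotype measure functions code by code.
#'
#' @param tables named list with `conditions`, `drugs`, `procedures` and
#'   `fee_schedule` elements ([load_event_tables()] or [generate_cohort()]
#'   output).
#' @param codes character vector of retained phenotype codes (e.g. from
#'   [filter_by_prevalence()]); must all occur in the condition table.
#' @param aggregate carrier-level aggregation for treatment time (the other
#'   measures are always means, matching their definitions).
#' @param n_patients optional external prevalence denominator.
#' @param quiet suppress fee-miss logging.
#' @return `data.frame` with one row per code (sorted by code):
#'   phenotype_code, n_patients, prevalence, treatment_time,
#'   n_comorbidities, n_medications, n_procedures, cost.
#' @export
build_profiles <- function(tables, codes, aggregate = "mean",
                           n_patients = NULL, quiet = FALSE) {
  if (length(codes) == 0L)
    return(data.frame(phenotype_code = character(0), n_patients = integer(0),
                      prevalence = numeric(0), treatment_time = numeric(0),
                      n_comorbidities = numeric(0), n_medications = numeric(0),
                      n_procedures = numeric(0), cost = numeric(0)))
  codes <- sort(unique(as.character(codes)))
  cond <- data.table::as.data.table(tables$conditions)
  if (!all(codes %in% cond$phenotype_code))
    stop("unknown phenotype code(s): ",
         paste(utils::head(setdiff(codes, cond$phenotype_code), 5),
               collapse = ", "))
  agg <- .aggregate_fn(aggregate)

  denom <- if (is.null(n_patients)) data.table::uniqueN(cond$patient_id)
           else n_patients

  # per-(code, patient) treatment span, for retained codes only
  pairs <- cond[phenotype_code %in% codes,
                list(span = as.numeric(max(event_date) - min(event_date))),
                by = list(phenotype_code, patient_id)]

  # patient-level quantities shared by all of a patient's phenotypes
  pat_codes <- cond[, list(n_codes = data.table::uniqueN(phenotype_code)),
                    by = patient_id]
  drugs <- data.table::as.data.table(tables$drugs)
  pat_drugs <- if (nrow(drugs)) {
    drugs[, list(n_drugs = data.table::uniqueN(drug_code)), by = patient_id]
  } else data.table::data.table(patient_id = character(0), n_drugs = integer(0))
  proc <- data.table::as.data.table(tables$procedures)
  pat_proc <- if (nrow(proc)) {
    proc[, list(n_proc = .N), by = patient_id]
  } else data.table::data.table(patient_id = character(0), n_proc = integer(0))

  fees <- data.table::as.data.table(tables$fee_schedule)
  pat_cost <- if (nrow(proc)) {
    hc <- proc[code_system == "HCPCS"]
    hc[, fee := fees$rate_per_minute[match(procedure_code,
                                           fees$procedure_code)] *
          fees$typical_minutes[match(procedure_code, fees$procedure_code)]]
    n_miss <- sum(is.na(hc$fee))
    if (n_miss > 0)
      .log_msg(quiet, n_miss,
               " HCPCS event(s) without fee-schedule entry; contributing 0")
    hc[, list(cost = sum(fee, na.rm = TRUE)), by = patient_id]
  } else data.table::data.table(patient_id = character(0), cost = numeric(0))

  pairs <- merge(pairs, pat_codes, by = "patient_id", all.x = TRUE)
  pairs <- merge(pairs, pat_drugs, by = "patient_id", all.x = TRUE)
  pairs <- merge(pairs, pat_proc, by = "patient_id", all.x = TRUE)
  pairs <- merge(pairs, pat_cost, by = "patient_id", all.x = TRUE)
  for (cc in c("n_drugs", "n_proc", "cost"))
    data.table::set(pairs, which(is.na(pairs[[cc]])), cc, 0)

  prof <- pairs[, list(
    n_patients = .N,
    prevalence = .N / denom,
    treatment_time = agg(span),
    n_comorbidities = mean(n_codes - 1),
    n_medications = mean(n_drugs),
    n_procedures = mean(n_proc),
    cost = mean(cost)
  ), by = phenotype_code]
  data.table::setorder(prof, phenotype_code)
  out <- as.data.frame(prof)
  out <- out[, c("phenotype_code", "n_patients", "prevalence",
                 "treatment_time", "n_comorbidities", "n_medications",
                 "n_procedures", "cost")]
  rownames(out) <- NULL
  out
}
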