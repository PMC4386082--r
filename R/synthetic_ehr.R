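## Synthetic EHR cohort generator.
##
## Emulates the statistical structure the severity method assumes: each
## phenotype carries a latent mild/severe class; carriers of severe
## phenotypes accrue more medications, comorbidity codes and procedures
## (overdispersed negative-binomial counts scaled by a per-measure effect
## size) and longer treatment spans (log-normal); a chronic-mild subgroup
## receives severe-scale treatment times while staying mild on every other
## measure — the confounder the multi-measure design is meant to defeat.
## Cost is driven through the fee schedule: severe phenotypes draw
## procedures preferentially from a high-fee code tier, a fraction of HCPCS
## codes is missing from the fee schedule and a fraction of events is
## ICD9PROC, so cost tracks procedure burden only imperfectly. Severe
## phenotypes are prevalence-enriched by default (inpatient-style
## selection). A reference standard with a fixed mild:severe ratio is
## emitted alongside full truth labels.

#' Generator configuration
#'
#' Defaults define the standard validation cohort: 2000 patients, 500
#' phenotypes, 30% severe, all per-measure effect sizes 3, 10% of mild
#' phenotypes chronic, a reference standard covering 25% of phenotypes at a
#' 372:144 mild:severe ratio.
#'
#' @param n_patients number of patients.
#' @param n_phenotypes number of index phenotypes.
#' @param severe_fraction probability a phenotype is latently severe.
#' @param effect_sizes named multiplicative severity factors (all >= 1) for
#'   cost, treatment_time, comorbidities, medications, procedures.
#' @param chronic_mild_fraction fraction of mild phenotypes given
#'   severe-scale treatment times (chronic confounders).
#' @param reference_fraction fraction of phenotypes emitted to the
#'   generated reference standard.
#' @param reference_ratio mild:severe composition of the reference standard
#'   (default 372:144).
#' @param mean_carriers expected carriers per phenotype.
#' @param min_carriers lower bound on carriers per phenotype.
#' @param severe_prevalence_enrichment prevalence multiplier for severe
#'   phenotypes (inpatient-style enrichment; 1 disables).
#' @param base_medications,base_comorbidities,base_procedures mild-class
#'   per-carrier means of the count contributions.
#' @param base_span_days mild-class median treatment span in days.
#' @param span_sdlog log-normal sd of treatment spans.
#' @param dispersion negative-binomial size parameter of the counts.
#' @param phenotype_sdlog sd (log scale) of the per-phenotype random effect.
#' @param n_drug_codes,n_filler_codes,n_hcpcs_codes,n_icd9_codes vocabulary
#'   sizes for drugs, comorbidity filler conditions and procedures.
#' @param fee_missing_fraction fraction of HCPCS codes absent from the
#'   emitted fee schedule.
#' @param icd9_fraction fraction of procedure events coded ICD9PROC.
#' @param pool_crossover probability a procedure event draws from the other
#'   class's fee tier.
#' @param study_start first possible event date.
#' @param study_days length of the observation window in days.
#' @param seed master seed for the generation.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 2000L, n_phenotypes = 500L,
                             severe_fraction = 0.3,
                             effect_sizes = c(cost = 3, treatment_time = 3,
                                              comorbidities = 3,
                                              medications = 3,
                                              procedures = 3),
                             chronic_mild_fraction = 0.1,
                             reference_fraction = 0.25,
                             reference_ratio = c(mild = 372, severe = 144),
                             mean_carriers = 10,
                             min_carriers = 2L,
                             severe_prevalence_enrichment = 1.5,
                             base_medications = 3,
                             base_comorbidities = 2,
                             base_procedures = 3,
                             base_span_days = 45,
                             span_sdlog = 0.4,
                             dispersion = 8,
                             phenotype_sdlog = 0.1,
                             n_drug_codes = 5000L,
                             n_filler_codes = 300L,
                             n_hcpcs_codes = 400L,
                             n_icd9_codes = 100L,
                             fee_missing_fraction = 0.15,
                             icd9_fraction = 0.2,
                             pool_crossover = 0.2,
                             study_start = as.Date("2008-01-01"),
                             study_days = 3650L,
                             seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$n_phenotypes >= 1,
            cfg$severe_fraction >= 0, cfg$severe_fraction <= 1,
            cfg$chronic_mild_fraction >= 0, cfg$chronic_mild_fraction <= 1,
            cfg$reference_fraction >= 0, cfg$reference_fraction <= 1,
            all(cfg$effect_sizes >= 1))
  class(cfg) <- "generator_config"
  cfg
}

# sample n carriers per phenotype; retry bound guards infeasible configs
.sample_carriers <- function(n_patients, n_carr) {
  lapply(n_carr, function(k) sample.int(n_patients, k))
}

#' Generate a synthetic cohort
#'
#' Draws event tables, a fee schedule, a reference standard and full truth
#' labels under a [generator_config()]. Generation is fully deterministic
#' given the config seed.
#'
#' @param config a [generator_config()].
#' @return named list: `conditions`, `drugs`, `procedures`, `fee_schedule`,
#'   `reference`, `truth` (phenotype_code, label, chronic), `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  np <- cfg$n_phenotypes

  severe <- rbinom(np, 1L, cfg$severe_fraction) == 1L
  # both classes must exist for the method to be meaningful
  if (!any(severe)) severe[1L] <- TRUE
  if (all(severe)) severe[1L] <- FALSE
  chronic <- !severe & runif(np) < cfg$chronic_mild_fraction
  phen_codes <- sprintf("SCT%06d", seq_len(np))
  phi <- rlnorm(np, 0, cfg$phenotype_sdlog)  # phenotype random effect

  ef <- cfg$effect_sizes
  mu_med <- cfg$base_medications * ifelse(severe, ef[["medications"]], 1) * phi
  mu_com <- cfg$base_comorbidities * ifelse(severe, ef[["comorbidities"]], 1) * phi
  mu_proc <- cfg$base_procedures * ifelse(severe, ef[["procedures"]], 1) * phi
  span_med <- cfg$base_span_days *
    ifelse(severe | chronic, ef[["treatment_time"]], 1) * phi

  # carriers: binomial around a log-normal per-phenotype prevalence,
  # severe-enriched, bounded below so every phenotype has >= min_carriers
  prev <- pmin(1, cfg$mean_carriers / cfg$n_patients * rlnorm(np, 0, 0.3) *
                 ifelse(severe, cfg$severe_prevalence_enrichment, 1))
  n_carr <- pmin(cfg$n_patients,
                 pmax(cfg$min_carriers, rbinom(np, cfg$n_patients, prev)))
  carriers <- .sample_carriers(cfg$n_patients, n_carr)

  pair_phen <- rep.int(seq_len(np), n_carr)
  pair_pat <- unlist(carriers, use.names = FALSE)
  n_pairs <- length(pair_phen)

  n_med <- rnbinom(n_pairs, size = cfg$dispersion, mu = mu_med[pair_phen])
  n_com <- rnbinom(n_pairs, size = cfg$dispersion, mu = mu_com[pair_phen])
  n_prc <- rnbinom(n_pairs, size = cfg$dispersion, mu = mu_proc[pair_phen])
  span <- round(rlnorm(n_pairs, log(span_med[pair_phen]), cfg$span_sdlog))
  d0 <- sample.int(cfg$study_days, n_pairs, replace = TRUE) - 1L

  pid <- sprintf("P%05d", pair_pat)
  date0 <- cfg$study_start + d0

  ## condition events: index code at first and (when span >= 1) last day,
  ## plus comorbidity filler codes drawn from a shared pool
  two <- span >= 1
  cond_idx <- data.frame(
    patient_id = c(pid, pid[two]),
    phenotype_code = c(phen_codes[pair_phen], phen_codes[pair_phen[two]]),
    event_date = c(date0, date0[two] + span[two]))

  filler_codes <- sprintf("SCF%04d", seq_len(cfg$n_filler_codes))
  n_com_cap <- pmin(n_com, cfg$n_filler_codes)
  tot_f <- sum(n_com_cap)
  f_pair <- rep.int(seq_len(n_pairs), n_com_cap)
  f_codes <- unlist(lapply(which(n_com_cap > 0), function(i)
    sample(filler_codes, n_com_cap[i])), use.names = FALSE)
  cond_fill <- data.frame(
    patient_id = pid[f_pair],
    phenotype_code = f_codes,
    event_date = date0[f_pair] +
      floor(runif(tot_f) * (span[f_pair] + 1)))
  conditions <- rbind(cond_idx, cond_fill)

  ## drug exposures: distinct drug codes per pair from a global pool
  drug_codes <- sprintf("RX%05d", seq_len(cfg$n_drug_codes))
  d_pair <- rep.int(seq_len(n_pairs), n_med)
  d_codes <- unlist(lapply(which(n_med > 0), function(i)
    sample(drug_codes, min(n_med[i], cfg$n_drug_codes))), use.names = FALSE)
  drugs <- data.frame(
    patient_id = pid[d_pair],
    drug_code = d_codes,
    event_date = date0[d_pair] +
      floor(runif(length(d_pair)) * (span[d_pair] + 1)))

  ## fee schedule over two tiers; the high tier's rates scale with the cost
  ## effect size so severe phenotypes accrue dearer procedures
  hcpcs <- sprintf("HC%05d", seq_len(cfg$n_hcpcs_codes))
  half <- cfg$n_hcpcs_codes %/% 2
  tier_high <- c(rep(FALSE, cfg$n_hcpcs_codes - half), rep(TRUE, half))
  rate <- rlnorm(cfg$n_hcpcs_codes, log(1), 0.5) *
    ifelse(tier_high, ef[["cost"]], 1)
  minutes <- pmax(5, round(rlnorm(cfg$n_hcpcs_codes, log(20), 0.4)))
  fee_known <- runif(cfg$n_hcpcs_codes) >= cfg$fee_missing_fraction
  fee_schedule <- data.frame(procedure_code = hcpcs[fee_known],
                             rate_per_minute = round(rate[fee_known], 4),
                             typical_minutes = minutes[fee_known])
  icd9 <- sprintf("IP%04d", seq_len(cfg$n_icd9_codes))

  p_pair <- rep.int(seq_len(n_pairs), n_prc)
  n_ev <- length(p_pair)
  is_icd <- runif(n_ev) < cfg$icd9_fraction
  use_high <- xor(severe[pair_phen[p_pair]],
                  runif(n_ev) < cfg$pool_crossover)
  p_code <- character(n_ev)
  p_code[is_icd] <- sample(icd9, sum(is_icd), replace = TRUE)
  hi <- !is_icd & use_high
  lo <- !is_icd & !use_high
  p_code[hi] <- sample(hcpcs[tier_high], sum(hi), replace = TRUE)
  p_code[lo] <- sample(hcpcs[!tier_high], sum(lo), replace = TRUE)
  procedures <- data.frame(
    patient_id = pid[p_pair],
    procedure_code = p_code,
    code_system = ifelse(is_icd, "ICD9PROC", "HCPCS"),
    event_date = date0[p_pair] + floor(runif(n_ev) * (span[p_pair] + 1)))

  truth <- data.frame(phenotype_code = phen_codes,
                      label = ifelse(severe, "severe", "mild"),
                      chronic = chronic)

  ## reference standard: stratified sample at the configured mild:severe
  ## ratio, labels taken from truth (curated-reference idealization)
  n_ref <- round(cfg$reference_fraction * np)
  rr <- cfg$reference_ratio / sum(cfg$reference_ratio)
  n_ref_sev <- min(round(n_ref * rr[["severe"]]), sum(severe))
  n_ref_mld <- min(n_ref - n_ref_sev, sum(!severe))
  ref_codes <- c(sample(phen_codes[severe], n_ref_sev),
                 sample(phen_codes[!severe], n_ref_mld))
  reference <- truth[truth$phenotype_code %in% ref_codes,
                     c("phenotype_code", "label")]
  rownames(reference) <- NULL

  list(conditions = conditions, drugs = drugs, procedures = procedures,
       fee_schedule = fee_schedule, reference = reference, truth = truth,
       config = cfg)
}

#' A tiny hand-checkable worked cohort
#'
#' Three phenotypes over three patients, constructed so every severity
#' measure can be verified by hand: `PHEN_A` has spans 10 and 0 days across
#' two carriers, `PHEN_B` is a single-event phenotype (treatment time 0),
#' and `PHEN_C`'s cost rests partly on an ICD9PROC event (no cost) and a
#' cheap HCPCS code. The expected profile table ships as
#' `severity_profiles_golden.csv` in the package's `extdata`.
#'
#' @return named list shaped like [generate_cohort()] output (without
#'   `reference`/`truth`).
#' @export
worked_fixture <- function() {
  d <- function(x) as.Date(x)
  conditions <- data.frame(
    patient_id = c("P1", "P1", "P2", "P1", "P2", "P3", "P3"),
    phenotype_code = c("PHEN_A", "PHEN_A", "PHEN_A", "PHEN_B",
                       "PHEN_C", "PHEN_C", "PHEN_C"),
    event_date = d(c("2010-01-01", "2010-01-11", "2010-03-01", "2010-02-01",
                     "2010-04-01", "2010-04-05", "2010-04-15")))
  drugs <- data.frame(
    patient_id = c("P1", "P1", "P2"),
    drug_code = c("RX_d1", "RX_d2", "RX_d1"),
    event_date = d(c("2010-01-02", "2010-01-03", "2010-03-02")))
  procedures <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3"),
    procedure_code = c("HC_h1", "HC_h1", "IP_i1", "HC_h2"),
    code_system = c("HCPCS", "HCPCS", "ICD9PROC", "HCPCS"),
    event_date = d(c("2010-01-02", "2010-01-03", "2010-03-02", "2010-04-06")))
  fee_schedule <- data.frame(
    procedure_code = c("HC_h1", "HC_h2"),
    rate_per_minute = c(2.0, 1.0),
    typical_minutes = c(30, 10))
  list(conditions = conditions, drugs = drugs, procedures = procedures,
       fee_schedule = fee_schedule)
}
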