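## E-PSI: the EHR-phenotype severity index.
##
## Each of the five measures is turned into a proportion of its maximum over
## all phenotypes in the supplied profile table; E-PSI is the mean of the
## five proportions, so it lives in [0, 1] and the phenotype attaining a
## measure's maximum has proportion exactly 1 for it.

#' Compute E-PSI scores
#'
#' For measure m and phenotype x, proportion_m(x) = m(x) / max over all
#' phenotypes of m. E-PSI(x) is the mean of the five proportions (cost,
#' treatment time, comorbidities, medications, procedures). If a measure is
#' zero for every phenotype its proportion is defined as 0 (degenerate
#' inputs must not divide by zero). `average = FALSE` returns the raw sum of
#' the five ratios instead of their mean.
#'
#' @param profiles severity profile table from [build_profiles()].
#' @param average divide the sum of proportions by five (default TRUE).
#' @return `data.frame`: phenotype_code, prop_cost, prop_treatment_time,
#'   prop_comorbidities, prop_medications, prop_procedures, epsi.
#' @export
compute_epsi <- function(profiles, average = TRUE) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    stop("profile table is empty")
  m <- as.matrix(profiles[, .measure_cols, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0))
    stop("measures must be finite and non-negative")
  maxes <- apply(m, 2, max)
  props <- sweep(m, 2, ifelse(maxes > 0, maxes, 1), "/")
  props[, maxes == 0] <- 0
  epsi <- if (average) rowMeans(props) else rowSums(props)
  out <- data.frame(phenotype_code = profiles$phenotype_code,
                    prop_cost = props[, "cost"],
                    prop_treatment_time = props[, "treatment_time"],
                    prop_comorbidities = props[, "n_comorbidities"],
                    prop_medications = props[, "n_medications"],
                    prop_procedures = props[, "n_procedures"],
                    epsi = epsi)
  rownames(out) <- NULL
  out
}

#' Rank phenotypes by a severity measure or by E-PSI
#'
#' Descending order with ties broken lexicographically by phenotype code, so
#' rankings are deterministic.
#'
#' @param x a data.frame containing `phenotype_code` and the ranking column
#'   (a profile table, an E-PSI score table, or their merge).
#' @param by one of `"cost"`, `"treatment_time"`, `"n_comorbidities"`,
#'   `"n_medications"`, `"n_procedures"`, `"epsi"`.
#' @param top_k number of codes to return (default all).
#' @return character vector of phenotype codes, most severe first.
#' @export
rank_phenotypes <- function(x, by, top_k = Inf) {
  valid <- c(.measure_cols, "epsi")
  if (!(is.character(by) && length(by) == 1L && by %in% valid))
    stop("unknown measure name '", paste(by, collapse = ","),
         "'; expected one of: ", paste(valid, collapse = ", "))
  if (!(by %in% names(x)))
    stop("column '", by, "' not present; merge profiles with E-PSI scores ",
         "to rank by '", by, "'")
  ord <- order(-x[[by]], x$phenotype_code)
  codes <- x$phenotype_code[ord]
  utils::head(codes, n = if (is.finite(top_k)) top_k else length(codes))
}
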