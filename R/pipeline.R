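## End-to-end orchestration: ingest -> prevalence filter -> profiles ->
## E-PSI -> unsupervised forest -> scaling -> classification -> evaluation,
## with every artifact written to an output directory and a machine-readable
## run report. Any stage failure aborts with the stage name.

#' Pipeline run configuration
#'
#' @param prevalence_threshold minimum phenotype prevalence (default 0.0001).
#' @param n_trees forest size (default 1000).
#' @param k anchor neighbors for classification (default 15).
#' @param seed master seed for contrast sampling and tree training.
#' @param aggregate treatment-time carrier aggregation (`"mean"`,
#'   `"median"`, `"max"`).
#' @param epsi_average divide the E-PSI ratio sum by five (default TRUE).
#' @param n_patients optional external prevalence denominator.
#' @param quiet suppress log messages.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(prevalence_threshold = 1e-4, n_trees = 1000L,
                       k = 15L, seed = 42L, aggregate = "mean",
                       epsi_average = TRUE, n_patients = NULL,
                       quiet = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full severity pipeline
#'
#' Executes every stage on in-memory event tables and, when `output_dir` is
#' given, writes `severity_profiles.csv`, `epsi_scores.csv`,
#' `embedding.csv`, `importance.csv`, `classification.csv`,
#' `evaluation.json` and `run_report.json`. When the tables carry no
#' reference standard, classification and evaluation are skipped and the
#' measures and E-PSI are still produced.
#'
#' @param tables named list with `conditions`, `drugs`, `procedures`,
#'   `fee_schedule` and optionally `reference` ([load_event_tables()] or
#'   [generate_cohort()] output).
#' @param config a [run_config()].
#' @param output_dir optional output directory.
#' @return the run report (list), invisibly carrying all computed artifacts
#'   in its `artifacts` element.
#' @export
run_pipeline <- function(tables, config = run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  q <- isTRUE(config$quiet)

  prev <- .stage("prevalence", compute_prevalence(tables$conditions,
                                                  config$n_patients))
  retained <- .stage("filter",
                     filter_by_prevalence(prev, config$prevalence_threshold))
  .log_msg(q, "retained ", length(retained), " of ", length(prev),
           " phenotypes at prevalence >= ", config$prevalence_threshold)
  profiles <- .stage("profiles",
                     build_profiles(tables, retained,
                                    aggregate = config$aggregate,
                                    n_patients = config$n_patients,
                                    quiet = q))
  scores <- .stage("epsi", compute_epsi(profiles,
                                        average = config$epsi_average))
  feats <- .stage("features", feature_matrix(profiles, scores))
  model <- .stage("forest",
                  fit_unsupervised_forest(feats, n_trees = config$n_trees,
                                          seed = config$seed))
  embedding <- .stage("scaling", scale_proximity(model, 2L, quiet = q))

  have_ref <- !is.null(tables$reference) && nrow(tables$reference) > 0L
  calls <- NULL; evaluation <- NULL; space <- NULL
  if (have_ref) {
    calls <- .stage("classify",
                    classify_phenotypes(model, tables$reference,
                                        k = config$k))
    space <- severe_space_report(calls, embedding)
    evaluation <- .stage("evaluate", {
      ref <- tables$reference
      idx <- match(ref$phenotype_code, calls$phenotype_code)
      keep <- !is.na(idx)
      perf <- classification_performance(ref$label[keep],
                                         calls$label[idx[keep]])
      curves <- error_curves(model, ref)
      contrast <- measure_contrast_report(profiles, scores, ref)
      list(performance = perf,
           final_errors = as.list(curves[nrow(curves),
                                         c("oob", "mild", "severe")]),
           measure_contrast = contrast)
    })
  } else {
    .log_msg(q, "no reference standard supplied; skipping classification ",
             "and evaluation")
  }

  report <- list(
    package_version = as.character(utils::packageVersion("phenosev")),
    seed = config$seed,
    config = config[c("prevalence_threshold", "n_trees", "k", "aggregate",
                      "epsi_average")],
    n_phenotypes_input = length(prev),
    n_phenotypes_retained = length(retained),
    severe_space = space,
    evaluation = if (have_ref) list(
      performance = evaluation$performance,
      final_errors = evaluation$final_errors,
      contrast_p_values = stats::setNames(
        evaluation$measure_contrast$p_value,
        evaluation$measure_contrast$measure)) else NULL
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, name)
      write.csv(df, file.path(output_dir, name), row.names = FALSE,
                quote = FALSE)
    wcsv(profiles, "severity_profiles.csv")
    wcsv(scores, "epsi_scores.csv")
    wcsv(data.frame(phenotype_code = rownames(embedding), embedding,
                    row.names = NULL), "embedding.csv")
    wcsv(data.frame(feature = names(model$importance),
                    mean_decrease_gini = unname(model$importance)),
         "importance.csv")
    if (!is.null(calls)) wcsv(calls, "classification.csv")
    if (!is.null(evaluation))
      jsonlite::write_json(
        list(performance = evaluation$performance,
             final_errors = evaluation$final_errors,
             measure_contrast = evaluation$measure_contrast),
        file.path(output_dir, "evaluation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(report, file.path(output_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  report$artifacts <- list(profiles = profiles, scores = scores,
                           model = model, embedding = embedding,
                           calls = calls, evaluation = evaluation)
  invisible(report)
}

#' Kappa agreement report from a long ratings table
#'
#' Convenience wrapper for rating files shaped (item, rater, label):
#' pairwise Cohen's kappa for every rater pair and Fleiss' kappa across all
#' raters (items rated by every rater only).
#'
#' @param ratings `data.frame` with columns `item`, `rater`, `label`.
#' @return list with `cohen` (pairwise kappa matrix) and `fleiss`.
#' @export
rater_agreement <- function(ratings) {
  stopifnot(all(c("item", "rater", "label") %in% names(ratings)))
  wide <- stats::reshape(ratings[, c("item", "rater", "label")],
                         idvar = "item", timevar = "rater",
                         direction = "wide")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) == 0L) stop("no items rated by every rater")
  raters <- sub("^label\\.", "", names(wide)[-1])
  lab <- as.matrix(wide[, -1, drop = FALSE])
  nr <- length(raters)
  cohen <- matrix(NA_real_, nr, nr, dimnames = list(raters, raters))
  for (i in seq_len(nr)) for (j in seq_len(nr))
    cohen[i, j] <- cohens_kappa(lab[, i], lab[, j])
  lev <- sort(unique(as.vector(lab)))
  counts <- t(apply(lab, 1, function(r) table(factor(r, levels = lev))))
  colnames(counts) <- lev
  list(cohen = cohen, fleiss = fleiss_kappa(counts))
}
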