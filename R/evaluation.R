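## Evaluation statistics: confusion-based performance against the reference
## standard, inter-rater agreement (Cohen, Fleiss), Wilcoxon rank-sum
## contrasts of the measures between severity classes, and per-class error
## curves of a supervised forest on the reference-labelled phenotypes.

#' Confusion counts for mild/severe calls
#'
#' @param truth character vector of true labels (`"mild"`/`"severe"`).
#' @param predicted aligned vector of predicted labels.
#' @param positive the positive class (default `"severe"`).
#' @return list with `tp`, `fp`, `tn`, `fn` and the positive class.
#' @export
confusion_counts <- function(truth, predicted, positive = "severe") {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (length(truth) == 0L) stop("empty label vectors")
  list(tp = sum(truth == positive & predicted == positive),
       fp = sum(truth != positive & predicted == positive),
       tn = sum(truth != positive & predicted != positive),
       fn = sum(truth == positive & predicted != positive),
       positive = positive)
}

#' Sensitivity and specificity (percent)
#'
#' sensitivity = 100 tp / (tp + fn); specificity = 100 tn / (tn + fp). A
#' zero denominator yields `NA` with a warning. Swapping the positive-class
#' orientation exchanges the two values; [classification_performance()]
#' reports both orientations.
#'
#' @param counts list from [confusion_counts()].
#' @return list with `sensitivity` and `specificity` in percent.
#' @export
sensitivity_specificity <- function(counts) {
  pdenom <- counts$tp + counts$fn
  ndenom <- counts$tn + counts$fp
  if (pdenom == 0 || ndenom == 0)
    warning("zero denominator; sensitivity or specificity undefined")
  list(sensitivity = if (pdenom > 0) 100 * counts$tp / pdenom else NA_real_,
       specificity = if (ndenom > 0) 100 * counts$tn / ndenom else NA_real_)
}

#' Classifier performance in both positive-class orientations
#'
#' @inheritParams confusion_counts
#' @return nested list: per orientation (`severe_positive`,
#'   `mild_positive`), the confusion counts and sensitivity/specificity.
#' @export
classification_performance <- function(truth, predicted) {
  out <- lapply(c(severe_positive = "severe", mild_positive = "mild"),
                function(pos) {
    cc <- confusion_counts(truth, predicted, positive = pos)
    c(cc[c("tp", "fp", "tn", "fn")], sensitivity_specificity(cc))
  })
  out
}

#' Cohen's kappa for two raters
#'
#' kappa = (p_o - p_e) / (1 - p_e) with chance agreement p_e from the
#' product of the marginal label distributions. When both raters are
#' constant and identical (p_e = 1), kappa is defined as 1 so unanimous
#' data scores perfect agreement rather than NaN.
#'
#' @param rater1,rater2 aligned label vectors.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2))
    stop("rater vectors must have equal length")
  if (length(rater1) == 0L) stop("empty ratings")
  lev <- sort(unique(c(as.character(rater1), as.character(rater2))))
  t1 <- factor(rater1, levels = lev)
  t2 <- factor(rater2, levels = lev)
  tab <- table(t1, t2) / length(rater1)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (isTRUE(all.equal(p_e, 1))) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard formulation on an item-by-category matrix of rater counts; every
#' item must be rated by the same number of raters. Unanimous data (chance
#' agreement 1) scores 1.
#'
#' @param counts integer matrix, rows = items, columns = categories,
#'   entries = number of raters assigning the item to the category.
#' @return Fleiss' kappa (bounded above by 1).
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("empty ratings matrix")
  n_raters <- unique(rowSums(counts))
  if (length(n_raters) != 1L)
    stop("all items must be rated by the same number of raters")
  if (n_raters < 2) stop("need at least 2 raters")
  N <- nrow(counts); n <- n_raters
  p_j <- colSums(counts) / (N * n)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (isTRUE(all.equal(P_e, 1))) return(1)
  (P_bar - P_e) / (1 - P_e)
}

# exact two-sided rank-sum p by full enumeration of group assignments on
# midranks; handles ties, feasible for n + m <= ~22
.wilcox_exact_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  w_all <- colSums(matrix(r[combos], nrow = n))
  eps <- 1e-8
  p <- 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps))
  list(statistic = w_obs - n * (n + 1) / 2, p_value = min(p, 1))
}

#' Wilcoxon rank-sum test between severity classes
#'
#' Two-sided by construction. In `"exact"` mode the p-value is computed by
#' full enumeration of group assignments over midranks (ties allowed); in
#' `"approx"` mode the normal approximation with tie and continuity
#' correction is used (via [stats::wilcox.test()]). `"auto"` selects exact
#' when both samples have at most 10 observations and the pooled data are
#' tie-free, the approximation otherwise.
#'
#' @param x values for the severe class.
#' @param y values for the mild class.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return list with `statistic` (Mann-Whitney W for `x`), `p_value` and
#'   the `mode` used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (mode == "auto")
    mode <- if (length(x) <= 10 && length(y) <= 10 && !has_ties)
      "exact" else "approx"
  if (mode == "exact") {
    if (length(x) + length(y) > 22)
      stop("exact enumeration limited to n + m <= 22")
    res <- .wilcox_exact_enum(x, y)
    return(list(statistic = res$statistic, p_value = res$p_value,
                mode = "exact"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mode = "approx")
}

#' OOB and per-class error curves on the reference standard
#'
#' Trains a supervised random forest on the reference-labelled rows of the
#' model's feature matrix (mild/severe as outcome) and returns the
#' out-of-bag error together with the per-class errors as a function of the
#' number of trees.
#'
#' @param model a `"proximity_model"` (its feature matrix and tree count
#'   are reused).
#' @param reference reference standard `data.frame` (phenotype_code, label).
#' @param seed optional seed (defaults to the model seed).
#' @return `data.frame` with columns `trees`, `oob`, `mild`, `severe`, one
#'   row per tree count up to the model's `n_trees`.
#' @export
error_curves <- function(model, reference, seed = NULL) {
  stopifnot(inherits(model, "proximity_model"))
  feats <- model$features
  anchors <- reference[reference$phenotype_code %in% rownames(feats), ,
                       drop = FALSE]
  if (nrow(anchors) < 2L || length(unique(anchors$label)) < 2L)
    stop("need reference phenotypes of both classes in the feature matrix")
  x <- feats[anchors$phenotype_code, , drop = FALSE]
  y <- factor(anchors$label, levels = c("mild", "severe"))
  if (is.null(seed)) seed <- model$seed
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = model$n_trees)
  data.frame(trees = seq_len(model$n_trees),
             oob = rf$err.rate[, "OOB"],
             mild = rf$err.rate[, "mild"],
             severe = rf$err.rate[, "severe"])
}

#' Per-measure class contrasts (quartiles and rank-sum p-values)
#'
#' For each of the five severity measures and E-PSI: median and quartiles
#' within the severe and mild classes plus the two-sided Wilcoxon rank-sum
#' p-value of the class difference. No multiple-testing correction is
#' applied across the six comparisons.
#'
#' @param profiles severity profile table.
#' @param scores E-PSI score table.
#' @param labels `data.frame` with `phenotype_code` and `label`
#'   (mild/severe) — a reference standard or generator truth table.
#' @return `data.frame`, one row per measure: quartiles per class and
#'   `p_value`.
#' @export
measure_contrast_report <- function(profiles, scores, labels) {
  df <- merge(profiles,
              scores[, c("phenotype_code", "epsi")], by = "phenotype_code")
  df <- merge(df, labels[, c("phenotype_code", "label")],
              by = "phenotype_code")
  if (nrow(df) == 0L) stop("no labelled phenotypes in the profile table")
  measures <- c(.measure_cols, "epsi")
  rows <- lapply(measures, function(mm) {
    xs <- df[[mm]][df$label == "severe"]
    xm <- df[[mm]][df$label == "mild"]
    if (length(xs) == 0L || length(xm) == 0L)
      stop("both classes must be present among labelled phenotypes")
    qs <- stats::quantile(xs, c(0.25, 0.5, 0.75), names = FALSE)
    qm <- stats::quantile(xm, c(0.25, 0.5, 0.75), names = FALSE)
    p <- wilcoxon_rank_sum(xs, xm, mode = "auto")$p_value
    data.frame(measure = mm,
               q1_severe = qs[1], median_severe = qs[2], q3_severe = qs[3],
               q1_mild = qm[1], median_mild = qm[2], q3_mild = qm[3],
               p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
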