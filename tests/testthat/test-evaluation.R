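test_that("sensitivity/specificity follow the confusion counts", {
  ss <- sensitivity_specificity(list(tp = 11, fn = 1, tn = 7, fp = 2))
  expect_equal(round(ss$sensitivity, 2), 91.67)
  expect_equal(round(ss$specificity, 2), 77.78)
  perfect <- sensitivity_specificity(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  # an all-severe predictor
  truth <- c(rep("severe", 4), rep("mild", 6))
  pred <- rep("severe", 10)
  ss2 <- sensitivity_specificity(confusion_counts(truth, pred))
  expect_equal(ss2$sensitivity, 100)
  expect_equal(ss2$specificity, 0)
  # swapping the positive class exchanges the two outputs
  both <- classification_performance(truth, pred)
  expect_equal(both$mild_positive$sensitivity,
               both$severe_positive$specificity)
  expect_equal(both$mild_positive$specificity,
               both$severe_positive$sensitivity)
  expect_warning(sensitivity_specificity(list(tp = 0, fn = 0, tn = 3,
                                              fp = 1)), "denominator")
})

test_that("Cohen's kappa matches hand-worked tables and is symmetric", {
  r <- c(rep("mild", 10), rep("severe", 4))
  expect_equal(cohens_kappa(r, r), 1)
  # balanced 2x2 agreement table [[45,5],[5,45]]: p_o = .9, p_e = .5
  a <- c(rep("mild", 50), rep("severe", 50))
  b <- c(rep("mild", 45), rep("severe", 5), rep("mild", 5), rep("severe", 45))
  expect_equal(cohens_kappa(a, b), 0.8)
  expect_equal(cohens_kappa(b, a), cohens_kappa(a, b))
  # one constant rater against a balanced one: agreement at chance -> 0
  const <- rep("mild", 10)
  bal <- rep(c("mild", "severe"), 5)
  expect_equal(cohens_kappa(const, bal), 0)
  # unanimous constant raters: p_e = 1 handled as perfect agreement
  expect_equal(cohens_kappa(const, const), 1)
  expect_error(cohens_kappa(a, b[-1]), "equal length")
})

test_that("Fleiss' kappa matches hand-worked cases", {
  unan <- matrix(c(5, 0, 0, 5, 5, 0), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(unan), 1)
  split <- matrix(c(1, 1, 1, 1), ncol = 2)  # 2 items, 2 raters split evenly
  expect_lte(fleiss_kappa(split), 0)
  expect_error(fleiss_kappa(matrix(c(2, 0, 1, 2), 2, 2)), "same number")
})

test_that("both kappas agree with brute-force oracles on random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    a <- sample(c("mild", "severe"), n, replace = TRUE)
    b <- ifelse(runif(n) < 0.6, a, sample(c("mild", "severe"), n,
                                          replace = TRUE))
    expect_equal(cohens_kappa(a, b), oracle_cohens_kappa(a, b),
                 tolerance = 1e-10)
    n_raters <- sample(2:6, 1)
    counts <- t(stats::rmultinom(20, n_raters, prob = c(0.6, 0.4)))
    expect_equal(fleiss_kappa(counts), oracle_fleiss_kappa(counts),
                 tolerance = 1e-10)
  }
})

test_that("exact rank-sum p-values match enumeration and wilcox.test", {
  res <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), mode = "exact")
  expect_equal(res$p_value, 0.1)   # 2 / C(6,3) by enumeration
  expect_equal(res$statistic, 9)   # Mann-Whitney W, all pairs won
  # identical multisets: symmetric null, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3),
                                 mode = "exact")$p_value, 1)
  set.seed(202)
  for (i in 1:40) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- sample(seq_len(60), nx)   # tie-free by construction
    y <- sample(setdiff(seq_len(60), x), ny)
    ours <- wilcoxon_rank_sum(x, y, mode = "auto")
    expect_identical(ours$mode, "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$p_value, oracle_wilcox_exact_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("exact p-values are invariant under monotone transforms", {
  set.seed(77)
  for (i in 1:10) {
    x <- sample(seq_len(50), 6); y <- sample(setdiff(seq_len(50), x), 7)
    p0 <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    expect_equal(wilcoxon_rank_sum(exp(x / 10), exp(y / 10),
                                   mode = "exact")$p_value, p0)
    expect_equal(wilcoxon_rank_sum(x^3, y^3, mode = "exact")$p_value, p0)
  }
})

test_that("approximate mode tracks exact mode at n = m = 10", {
  set.seed(303)
  for (i in 1:10) {
    x <- sample(seq_len(200), 10); y <- sample(setdiff(seq_len(200), x), 10)
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    pa <- wilcoxon_rank_sum(x, y, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("class contrasts report quartiles and near-1 p on identical classes", {
  prof <- data.frame(
    phenotype_code = sprintf("X%02d", 1:20),
    n_patients = 1L, prevalence = 0.1,
    treatment_time = rep(1:10, 2), n_comorbidities = rep(1:10, 2),
    n_medications = rep(1:10, 2), n_procedures = rep(1:10, 2),
    cost = rep(1:10, 2))
  sc <- compute_epsi(prof)
  labels <- data.frame(phenotype_code = prof$phenotype_code,
                       label = rep(c("severe", "mild"), each = 10))
  mc <- measure_contrast_report(prof, sc, labels)
  expect_equal(nrow(mc), 6L)
  expect_true(all(mc$p_value > 0.9))
  # quartiles match a brute-force order-statistics oracle (linear
  # interpolation between order statistics at h = (n-1)p + 1)
  oracle_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(unname(unlist(mc[mc$measure == "cost",
                                c("q1_severe", "median_severe",
                                  "q3_severe")])),
               sapply(c(.25, .5, .75), function(p) oracle_q(1:10, p)))
})

test_that("error curves cover every tree count with errors in [0, 1]", {
  cf <- cluster_features(n_per = 20, default = 5, seed = 61)
  m <- fit_unsupervised_forest(cf$features, n_trees = 120, seed = 62)
  ref <- data.frame(phenotype_code = rownames(cf$features),
                    label = cf$class)
  ec <- error_curves(m, ref, seed = 63)
  expect_equal(nrow(ec), 120L)
  expect_true(all(ec$oob >= 0 & ec$oob <= 1))
  expect_true(all(ec$mild >= 0 & ec$mild <= 1, na.rm = TRUE))
  expect_true(all(ec$severe >= 0 & ec$severe <= 1, na.rm = TRUE))
  expect_error(error_curves(m, ref[ref$label == "mild", ]), "both classes")
})
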