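test_that("the contrast sample preserves marginals and determinism", {
  cf <- cluster_features(n_per = 15, seed = 3)
  feats <- cf$features
  feats[, "epsi"] <- 7  # constant column
  s1 <- make_contrast_sample(feats, seed = 99)
  s2 <- make_contrast_sample(feats, seed = 99)
  expect_identical(s1, s2)
  expect_identical(dim(s1), dim(feats))
  # a constant column resamples to itself exactly
  expect_equal(unname(s1[, "epsi"]), rep(7, nrow(feats)))
  # every synthetic value multiset is contained in the observed value set
  for (j in seq_len(ncol(feats)))
    expect_true(all(s1[, j] %in% feats[, j]))
  expect_error(make_contrast_sample(feats[1, , drop = FALSE]), "2 rows")
})

test_that("proximity is symmetric, unit-diagonal, in [0,1], and seeded", {
  cf <- cluster_features(n_per = 20, seed = 5)
  m1 <- fit_unsupervised_forest(cf$features, n_trees = 150, seed = 21)
  m2 <- fit_unsupervised_forest(cf$features, n_trees = 150, seed = 21)
  P <- m1$proximity
  expect_identical(P, t(P))
  expect_equal(unname(diag(P)), rep(1, nrow(P)))
  expect_true(all(P >= 0 & P <= 1))
  expect_identical(m1$proximity, m2$proximity)
  expect_identical(m1$importance, m2$importance)
  expect_equal(nrow(m1$oob_error_curve), 150L)
  expect_error(fit_unsupervised_forest(cf$features, n_trees = 0), "n_trees")
})

test_that("a duplicated phenotype stays proximate to its twin", {
  cf <- cluster_features(n_per = 15, seed = 8)
  feats <- rbind(cf$features, twin = cf$features[1, ])
  rownames(feats)[nrow(feats)] <- "twin"
  m <- fit_unsupervised_forest(feats, n_trees = 200, seed = 4)
  P <- m$proximity
  off <- P[upper.tri(P)]
  expect_gte(P["PH001", "twin"], median(off))
})

test_that("importance ranks the dominant separating feature first and a
           constant feature near zero", {
  # medications carries a dominant 12 SD class gap over a backdrop of weak
  # 1.5 SD gaps in the other informative features (against a
  # marginal-preserving contrast an isolated gap earns no impurity
  # decrease of its own — the dependence across features is the signal);
  # cost is constant
  cf <- cluster_features(n_per = 60, default = 1.5, seed = 12,
                         gap = c(n_medications = 12, cost = 0))
  feats <- cf$features
  feats[, "cost"] <- 5
  m <- fit_unsupervised_forest(feats, n_trees = 500, seed = 13)
  imp <- m$importance
  expect_identical(names(which.max(imp)), "n_medications")
  expect_lte(imp[["cost"]], 0.05 * max(imp))
})

test_that("classical scaling recovers Euclidean-embeddable configurations", {
  # all points identical -> zero embedding
  P1 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unname(scale_proximity(P1, 2, quiet = TRUE)),
               matrix(0, 4, 2))
  # equilateral 3-point configuration -> equal pairwise distances
  P2 <- matrix(0.5, 3, 3); diag(P2) <- 1
  dimnames(P2) <- list(letters[1:3], letters[1:3])
  emb2 <- scale_proximity(P2, 2, quiet = TRUE)
  d2 <- as.numeric(dist(emb2))
  expect_lt(max(d2) - min(d2), 1e-8)
  # a known 2D configuration is reproduced to within 1e-6
  set.seed(17)
  pts <- matrix(runif(20), 10, 2)
  D <- as.matrix(dist(pts))
  D <- D / (1.1 * max(D))          # keep 1 - D a valid proximity
  P3 <- 1 - D
  dimnames(P3) <- list(sprintf("p%02d", 1:10), sprintf("p%02d", 1:10))
  emb3 <- scale_proximity(P3, 2, quiet = TRUE)
  expect_equal(as.matrix(dist(emb3)), D, tolerance = 1e-6,
               ignore_attr = TRUE)
  # agreement with the stats::cmdscale oracle up to per-axis sign
  orc <- stats::cmdscale(D, k = 2)
  expect_equal(abs(unname(emb3)), abs(unname(orc)), tolerance = 1e-6)
  # dimensions beyond rank come back as zero columns
  emb4 <- scale_proximity(P2, 3, quiet = TRUE)
  expect_equal(unname(emb4[, 3]), rep(0, 3))
})

test_that("anchored k-NN labels well-separated clusters perfectly", {
  cf <- cluster_features(n_per = 25, default = 6, seed = 23)
  m <- fit_unsupervised_forest(cf$features, n_trees = 300, seed = 24)
  codes <- rownames(cf$features)
  anchors <- c(codes[1:10], codes[26:35])  # 10 per cluster
  ref <- data.frame(phenotype_code = anchors,
                    label = cf$class[match(anchors, codes)])
  calls <- classify_phenotypes(m, ref, k = 10)
  non_anchor <- setdiff(codes, anchors)
  got <- calls$label[match(non_anchor, calls$phenotype_code)]
  expect_identical(got, cf$class[match(non_anchor, codes)])
  expect_true(all(calls$neighbor_support >= 0.5 &
                  calls$neighbor_support <= 1))
  expect_error(classify_phenotypes(m, ref, k = 0), "k must be")
  expect_error(classify_phenotypes(
    m, data.frame(phenotype_code = "nope", label = "mild")), "no reference")
})

test_that("exactly tied proximity-weighted votes resolve to severe", {
  P <- diag(3)
  P[1, 2] <- P[2, 1] <- 0.4   # one mild anchor, one severe anchor,
  P[1, 3] <- P[3, 1] <- 0.4   # both equally proximate to row 1
  dimnames(P) <- list(c("q", "m1", "s1"), c("q", "m1", "s1"))
  ref <- data.frame(phenotype_code = c("m1", "s1"),
                    label = c("mild", "severe"))
  calls <- classify_phenotypes(P, ref, k = 2)
  expect_identical(calls$label[calls$phenotype_code == "q"], "severe")
  expect_equal(calls$neighbor_support[calls$phenotype_code == "q"], 0.5)
  # unanimity gives support 1
  calls_s <- classify_phenotypes(P, data.frame(
    phenotype_code = c("m1", "s1"), label = c("severe", "severe")), k = 2)
  expect_equal(calls_s$neighbor_support[calls_s$phenotype_code == "q"], 1)
})

test_that("severe_space_report partitions the calls", {
  calls <- data.frame(phenotype_code = c("a", "b", "c"),
                      label = c("mild", "mild", "severe"),
                      neighbor_support = c(0.9, 0.8, 0.7))
  emb <- matrix(rnorm(6), 3, 2,
                dimnames = list(c("a", "b", "c"), c("dim1", "dim2")))
  rep <- severe_space_report(calls, emb)
  expect_equal(rep$n_mild + rep$n_severe, rep$n_total)
  expect_equal(rep$n_severe, 1)
  all_mild <- calls; all_mild$label <- "mild"
  expect_equal(severe_space_report(all_mild)$n_severe, 0)
})

test_that("separability degrades monotonically to chance as effect sizes
           shrink to one", {
  ba <- sapply(c(1, 2, 3), function(ef) {
    cfg <- generator_config(
      n_patients = 600, n_phenotypes = 150,
      effect_sizes = c(cost = ef, treatment_time = ef, comorbidities = ef,
                       medications = ef, procedures = ef),
      chronic_mild_fraction = if (ef == 1) 0 else 0.1,
      reference_fraction = 0.3, seed = 400 + ef)
    co <- generate_cohort(cfg)
    keep <- filter_by_prevalence(compute_prevalence(co$conditions), 1e-4)
    prof <- build_profiles(co, keep, quiet = TRUE)
    sc <- compute_epsi(prof)
    m <- fit_unsupervised_forest(feature_matrix(prof, sc), n_trees = 300,
                                 seed = 500 + ef)
    calls <- classify_phenotypes(m, co$reference, k = 15)
    ref <- co$reference
    pred <- calls$label[match(ref$phenotype_code, calls$phenotype_code)]
    perf <- classification_performance(ref$label, pred)$severe_positive
    (perf$sensitivity + perf$specificity) / 200
  })
  expect_gt(ba[1], 0.30)   # null config: balanced accuracy near chance
  expect_lt(ba[1], 0.70)
  expect_gte(ba[3], 0.85)  # strong effects: well separated
  expect_gte(ba[3], ba[1] + 0.2)
  expect_gte(ba[2], ba[1])
})
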