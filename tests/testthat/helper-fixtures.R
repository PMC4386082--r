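# Fixture builders used across test files. All fixtures are generated in
# code; files go to tempdir().

feature_cols <- c("cost", "treatment_time", "n_comorbidities",
                  "n_medications", "n_procedures", "epsi")

# two clusters in feature space; `gap` gives each column's between-cluster
# shift in units of the within-cluster SD (1); unnamed columns get `default`
cluster_features <- function(n_per = 25, default = 8, gap = NULL, seed = 1) {
  set.seed(seed)
  cls <- rep(c(0, 1), each = n_per)
  m <- sapply(feature_cols, function(cn) {
    mu <- if (!is.null(gap) && cn %in% names(gap)) gap[[cn]] else default
    stats::rnorm(2 * n_per, mean = cls * mu, sd = 1) + 20
  })
  rownames(m) <- sprintf("PH%03d", seq_len(2 * n_per))
  list(features = m, class = ifelse(cls == 1, "severe", "mild"))
}

write_csv_fixture <- function(lines, name = "fixture.csv") {
  p <- file.path(tempdir(), name)
  writeLines(lines, p)
  p
}

small_profiles <- function() {
  data.frame(
    phenotype_code = c("A", "B"),
    n_patients = c(1L, 1L), prevalence = c(0.5, 0.5),
    treatment_time = c(10, 5), n_comorbidities = c(10, 5),
    n_medications = c(10, 5), n_procedures = c(10, 5), cost = c(10, 5))
}
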