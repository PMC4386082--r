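## Unsupervised random-forest proximity model and mild/severe calling.
##
## An ensemble of classification trees is trained to discriminate the
## observed feature rows from a synthetic contrast sample drawn from the
## product of the observed per-column marginals. Two observed phenotypes are
## proximate when they co-occupy terminal nodes: proximity(i, j) = fraction
## of all trees in which rows i and j fall in the same leaf. The proximity
## matrix is embedded in 2D by classical (Torgerson) scaling of 1-proximity,
## and phenotypes are labelled mild/severe by a proximity-weighted k-NN vote
## over reference-standard anchors.

#' Assemble the classifier feature matrix
#'
#' Six columns in fixed order: cost, treatment_time, n_comorbidities,
#' n_medications, n_procedures, epsi. Row names are phenotype codes.
#'
#' @param profiles severity profile table ([build_profiles()]).
#' @param scores E-PSI score table ([compute_epsi()]) aligned by code.
#' @return numeric matrix, one row per phenotype.
#' @export
feature_matrix <- function(profiles, scores) {
  m <- as.matrix(profiles[, .measure_cols, drop = FALSE])
  rownames(m) <- profiles$phenotype_code
  epsi <- scores$epsi[match(profiles$phenotype_code, scores$phenotype_code)]
  if (anyNA(epsi)) stop("scores missing for some profile phenotypes")
  m <- cbind(m, epsi = epsi)
  if (any(!is.finite(m))) stop("feature matrix contains non-finite values")
  m
}

#' Synthetic contrast sample for unsupervised forest training
#'
#' Each column of the output is an independent resample with replacement of
#' the corresponding observed column, so the synthetic class has the same
#' marginals as the data but none of its dependence structure.
#'
#' @param features numeric feature matrix (>= 2 rows).
#' @param seed optional integer seed; when supplied the sample is
#'   reproducible in isolation (inside [fit_unsupervised_forest()] the
#'   model seed governs the RNG stream instead).
#' @return matrix of the same dimensions and column names.
#' @export
make_contrast_sample <- function(features, seed = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 rows")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(features)
  synth <- apply(features, 2, function(col) col[sample.int(n, n, replace = TRUE)])
  rownames(synth) <- paste0("synthetic_", seq_len(n))
  synth
}

#' Fit the unsupervised random-forest proximity model
#'
#' Trains `n_trees` classification trees (via \pkg{randomForest})
#' discriminating observed rows from a [make_contrast_sample()] contrast
#' class, then computes the observed-row proximity matrix from terminal-node
#' co-occupancy over all trees (co-occurrence count / `n_trees`). Per-feature
#' mean decrease in Gini and the real-vs-synthetic OOB error curve are kept.
#'
#' @param features numeric feature matrix with phenotype row names.
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed driving both the contrast sample and tree
#'   training.
#' @return object of class `"proximity_model"`: list with `proximity`
#'   (symmetric, unit diagonal, entries in \[0,1\]), `importance` (named
#'   mean-decrease-in-Gini vector), `oob_error_curve` (per-tree-count OOB
#'   and per-class error for the real/synthetic discrimination),
#'   `n_trees`, `seed`, `features`.
#' @export
fit_unsupervised_forest <- function(features, n_trees = 1000L, seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 phenotypes")
  if (!is.numeric(n_trees) || n_trees < 1) stop("n_trees must be >= 1")
  n_trees <- as.integer(n_trees)
  if (!is.null(seed)) set.seed(seed)
  synth <- make_contrast_sample(features)
  x <- rbind(features, synth)
  y <- factor(rep(c("observed", "synthetic"), each = n))
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   keep.forest = TRUE)
  nodes <- attr(predict(rf, features, nodes = TRUE), "nodes")
  storage.mode(nodes) <- "integer"
  # global leaf id = within-tree node id offset by tree; one leaf per tree
  # per row, so tcrossprod of the indicator counts same-leaf trees
  max_node <- max(nodes)
  leaf <- nodes + matrix(rep((seq_len(n_trees) - 1L) * max_node, each = n),
                         nrow = n)
  leaf_id <- match(as.vector(leaf), sort(unique(as.vector(leaf))))
  Z <- Matrix::sparseMatrix(i = rep(seq_len(n), times = n_trees),
                            j = leaf_id, x = 1)
  prox <- as.matrix(Matrix::tcrossprod(Z)) / n_trees
  dimnames(prox) <- list(rownames(features), rownames(features))
  imp <- rf$importance[, "MeanDecreaseGini"]
  names(imp) <- colnames(features)
  curve <- data.frame(trees = seq_len(n_trees),
                      oob = rf$err.rate[, "OOB"],
                      observed = rf$err.rate[, "observed"],
                      synthetic = rf$err.rate[, "synthetic"])
  structure(list(proximity = prox, importance = imp,
                 oob_error_curve = curve, n_trees = n_trees,
                 seed = seed, features = features),
            class = "proximity_model")
}

#' @export
print.proximity_model <- function(x, ...) {
  cat("Unsupervised random-forest proximity model\n")
  cat("  phenotypes:", nrow(x$proximity), " trees:", x$n_trees, "\n")
  cat("  final real-vs-synthetic OOB error:",
      round(utils::tail(x$oob_error_curve$oob, 1), 4), "\n")
  cat("  importance (mean decrease in Gini):\n")
  print(round(sort(x$importance, decreasing = TRUE), 2))
  invisible(x)
}

.proximity_of <- function(model) {
  if (inherits(model, "proximity_model")) model$proximity
  else as.matrix(model)
}

#' Classical scaling of the proximity matrix
#'
#' Embeds phenotypes in `n_dims` dimensions by Torgerson scaling of the
#' dissimilarity D = 1 - proximity: double-center -D^2/2, take the top
#' eigenvectors scaled by the square roots of their eigenvalues. Negative
#' eigenvalues (1 - proximity need not be Euclidean) are clipped at zero —
#' a clipped requested dimension yields a zero column, logged — and each
#' dimension's largest-magnitude coordinate is made positive so the
#' embedding is sign-deterministic.
#'
#' @param model a `"proximity_model"` or a proximity matrix.
#' @param n_dims number of embedding dimensions (default 2).
#' @param quiet suppress log messages.
#' @return matrix (phenotypes x n_dims) with columns `dim1`, `dim2`, ...
#' @export
scale_proximity <- function(model, n_dims = 2L, quiet = FALSE) {
  P <- .proximity_of(model)
  n <- nrow(P)
  D2 <- (1 - P)^2
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  neg_mass <- sum(abs(pmin(eig$values, 0)))
  if (neg_mass > 1e-8)
    .log_msg(quiet, "classical scaling: clipping negative eigenvalue mass ",
             format(neg_mass, digits = 4), " at zero")
  k <- min(n_dims, n)
  lam <- pmax(eig$values[seq_len(k)], 0)
  if (any(lam == 0))
    .log_msg(quiet, "classical scaling: ", sum(lam == 0),
             " requested dimension(s) beyond rank; zero columns emitted")
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  if (k < n_dims)
    coords <- cbind(coords, matrix(0, n, n_dims - k))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(P), paste0("dim", seq_len(n_dims)))
  coords
}

#' Label phenotypes mild/severe from reference-standard anchors
#'
#' Each phenotype takes its `k` highest-proximity reference-standard
#' phenotypes (excluding itself, so anchors are scored leave-one-out) and is
#' assigned the proximity-weighted majority of their labels. Exact ties —
#' including all-zero proximity — go to severe, preferring over-detection of
#' severe phenotypes. `neighbor_support` is the winning share of the summed
#' neighbor proximity.
#'
#' @param model `"proximity_model"` or proximity matrix with code dimnames.
#' @param reference reference standard `data.frame` (phenotype_code, label).
#' @param k number of anchor neighbors (default 15; reduced per row when
#'   fewer anchors are available).
#' @return `data.frame`: phenotype_code, label, neighbor_support.
#' @export
classify_phenotypes <- function(model, reference, k = 15L) {
  P <- .proximity_of(model)
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  codes <- rownames(P)
  anchors <- reference[reference$phenotype_code %in% codes, , drop = FALSE]
  if (nrow(anchors) == 0L)
    stop("no reference-standard phenotypes present in the model")
  alab <- stats::setNames(anchors$label, anchors$phenotype_code)
  acodes <- names(alab)
  out_label <- character(length(codes))
  out_support <- numeric(length(codes))
  for (i in seq_along(codes)) {
    cand <- setdiff(acodes, codes[i])
    w <- P[i, cand]
    # deterministic top-k: proximity descending, code ascending on ties
    ord <- order(-w, cand)
    sel <- ord[seq_len(min(k, length(cand)))]
    wsel <- w[sel]; lsel <- alab[cand[sel]]
    sev <- sum(wsel[lsel == "severe"])
    mld <- sum(wsel[lsel == "mild"])
    tot <- sev + mld
    if (sev >= mld) {
      out_label[i] <- "severe"
      out_support[i] <- if (tot > 0) sev / tot else 0.5
    } else {
      out_label[i] <- "mild"
      out_support[i] <- mld / tot
    }
  }
  data.frame(phenotype_code = codes, label = out_label,
             neighbor_support = out_support, row.names = NULL)
}

#' Summarize the mild/severe call space
#'
#' Counts calls per label and, when an embedding is supplied, the bounding
#' box of each label's coordinates — the "severe space" a phenotype
#' selection can be restricted to.
#'
#' @param calls output of [classify_phenotypes()].
#' @param embedding optional [scale_proximity()] coordinates.
#' @return list with `n_total`, `n_mild`, `n_severe`, `severe_fraction` and
#'   per-label coordinate ranges (`extent`) when an embedding is given.
#' @export
severe_space_report <- function(calls, embedding = NULL) {
  n_sev <- sum(calls$label == "severe")
  n_mld <- sum(calls$label == "mild")
  rep <- list(n_total = nrow(calls), n_mild = n_mld, n_severe = n_sev,
              severe_fraction = n_sev / nrow(calls))
  if (!is.null(embedding)) {
    rep$extent <- lapply(c(mild = "mild", severe = "severe"), function(lb) {
      rows <- embedding[calls$phenotype_code[calls$label == lb], ,
                        drop = FALSE]
      if (nrow(rows) == 0L) return(NULL)
      apply(rows, 2, range)
    })
  }
  rep
}
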