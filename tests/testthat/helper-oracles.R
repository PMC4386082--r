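# Independent brute-force oracles, kept deliberately naive (explicit loops,
# textbook formulas) so they share no code path with the implementation.

oracle_cohens_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  if (abs(pe - 1) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

oracle_fleiss_kappa <- function(counts) {
  N <- nrow(counts)
  n <- sum(counts[1, ])
  k <- ncol(counts)
  pj <- numeric(k)
  for (j in seq_len(k)) pj[j] <- sum(counts[, j]) / (N * n)
  Pi <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(k)) s <- s + counts[i, j] * (counts[i, j] - 1)
    Pi[i] <- s / (n * (n - 1))
  }
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (abs(Pe - 1) < 1e-12) return(1)
  (Pbar - Pe) / (1 - Pe)
}

# exact two-sided rank-sum p by explicit subset enumeration of which pooled
# positions belong to x (independent of the package's midrank enumeration)
oracle_wilcox_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  ws <- apply(idx, 2, function(ii) sum(r[ii]))
  w_obs <- sum(r[seq_len(n)])
  min(1, 2 * min(mean(ws <= w_obs + 1e-8), mean(ws >= w_obs - 1e-8)))
}
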