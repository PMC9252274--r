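# Brute-force oracles, independent of the package's compiled kernels.

# random symmetric nonnegative weight matrix with a given edge density
random_weight_matrix <- function(n, density = 0.6) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  w <- runif(sum(ut))
  w[runif(sum(ut)) > density] <- 0
  A[ut] <- w
  A + t(A)
}

# all-pairs shortest paths by explicit Floyd-Warshall on R matrices
oracle_distances <- function(W, length_mode = c("inverse", "neglog")) {
  length_mode <- match.arg(length_mode)
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  idx <- which(W > 0, arr.ind = TRUE)
  D[idx] <- if (length_mode == "inverse") 1 / W[idx] else -log(W[idx])
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  D <- oracle_distances(W)
  Inv <- 1 / D
  diag(Inv) <- 0
  Inv[!is.finite(Inv)] <- 0
  rowSums(Inv) / (n - 1)
}

# exhaustive ordered-pair triangle enumeration
oracle_clustering <- function(W) {
  n <- nrow(W)
  wmax <- max(W)
  if (wmax <= 0) return(numeric(n))
  Wh <- W / wmax
  C <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      t_i <- t_i + (Wh[i, j] * Wh[j, h] * Wh[h, i])^(1 / 3)
    }
    t_i <- t_i / 2
    deg <- sum(W[i, ] > 0)
    C[i] <- if (deg >= 2) 2 * t_i / (deg * (deg - 1)) else 0
  }
  C
}

# small simulated study used by several test files
small_study <- function(seed = 1, n_men = 8, n_women = 10, n_regions = 10,
                        n_timepoints = 60, ...) {
  cfg <- sim_config(n_men = n_men, n_women = n_women, n_regions = n_regions,
                    n_timepoints = n_timepoints, seed = seed, ...)
  simulate_study(cfg)
}

fc_from_study <- function(study) {
  ses <- study$cohort$sessions
  fc <- lapply(ses$session_id, function(sid)
    compute_fc(study$timeseries[[sid]], session_id = sid))
  names(fc) <- ses$session_id
  fc
}
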