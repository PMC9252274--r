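#' Fisher-z functional connectivity matrix
#'
#' Computes Pearson correlations between all pairs of regional time series and
#' applies the Fisher r-to-z transform, `z = atanh(r)`. Correlations are
#' clipped to `|r| <= 1 - 1e-7` before the transform so duplicated series
#' cannot produce infinities. The diagonal is set to zero.
#'
#' @param ts A `T x N` numeric matrix of regional time series (columns =
#'   regions, ideally labelled) or an object with a `values` matrix.
#' @param session_id Optional session identifier carried in the result.
#' @return An object of class `fc_matrix`: list with `z` (`N x N` symmetric,
#'   zero diagonal), `region_labels`, `session_id`.
#' @export
compute_fc <- function(ts, session_id = NULL) {
  if (is.list(ts) && !is.null(ts$values)) {
    if (is.null(session_id)) session_id <- ts$session_id
    ts <- ts$values
  }
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L)
    stop("at least 3 timepoints are required", call. = FALSE)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  labels <- colnames(ts)
  if (is.null(labels)) labels <- region_labels(ncol(ts))
  v <- apply(ts, 2, var)
  if (any(v == 0))
    stop("constant time series (zero variance) in region(s): ",
         paste(labels[v == 0], collapse = ", "), call. = FALSE)
  r <- cor(ts)
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2   # guard against asymmetric floating-point residue
  dimnames(z) <- list(labels, labels)
  structure(list(z = z, region_labels = labels, session_id = session_id),
            class = "fc_matrix")
}

#' @export
#' @method print fc_matrix
print.fc_matrix <- function(x, ...) {
  cat(sprintf("Fisher-z FC matrix: %d regions%s\n", nrow(x$z),
              if (is.null(x$session_id)) "" else
                paste0(" (session ", x$session_id, ")")))
  ut <- x$z[upper.tri(x$z)]
  cat(sprintf("  z range: [%.3f, %.3f], %.1f%% negative\n",
              min(ut), max(ut), 100 * mean(ut < 0)))
  invisible(x)
}

#' The proportional-sparsity grid
#'
#' The 46 sparsity levels 0.05, 0.06, ..., 0.50 used for the network-metric
#' sweep, computed from integers to avoid floating-point drift.
#'
#' @return Numeric vector of length 46.
#' @export
sparsity_grid <- function() {
  (5:50) / 100
}

# round-half-away-from-zero, for bit-stable edge counts
round_half_away <- function(x) {
  floor(x + 0.5)
}

#' Number of edges retained at a sparsity level
#'
#' @param s Sparsity fraction.
#' @param n Number of nodes.
#' @return Integer edge count, `round(s * n * (n - 1) / 2)` with
#'   half-away-from-zero rounding.
#' @export
edge_count <- function(s, n) {
  as.integer(round_half_away(s * n * (n - 1) / 2))
}

#' Proportional thresholding of an FC matrix
#'
#' Retains the strongest positive Fisher-z weights at a given sparsity level.
#' Negative entries are excluded before ranking (the strength and
#' geometric-mean-triangle formulas downstream presuppose nonnegative
#' weights); retained weights keep their original magnitudes — graphs stay
#' weighted, never binarized. Ties are broken by `(i, j)` index order so the
#' edge sets are nested and platform-stable across the grid.
#'
#' @param fc An `fc_matrix` (or plain symmetric matrix).
#' @param s Sparsity fraction in `[0.05, 0.5]` (values outside are allowed
#'   but flagged); fraction of all possible edges to keep.
#' @return An object of class `thresholded_graph`: list with `weights`
#'   (`N x N` nonnegative symmetric), `sparsity`, `n_edges_kept`.
#' @export
apply_sparsity <- function(fc, s) {
  z <- if (inherits(fc, "fc_matrix")) fc$z else as.matrix(fc)
  n <- nrow(z)
  if (s <= 0 || s > 1) stop("sparsity must lie in (0, 1]", call. = FALSE)
  m_target <- edge_count(s, n)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[ut]
  pos <- which(w > 0)
  if (length(pos) < m_target) {
    warning(sprintf(
      "only %d positive edges available; keeping all (requested %d)",
      length(pos), m_target))
    keep <- pos
  } else {
    # descending weight, ties by (row, col) index
    ord <- order(-w[pos], ut[pos, 1], ut[pos, 2])
    keep <- pos[ord[seq_len(m_target)]]
  }
  W <- matrix(0, n, n, dimnames = dimnames(z))
  W[ut[keep, , drop = FALSE]] <- w[keep]
  W <- W + t(W)
  structure(list(weights = W, sparsity = s,
                 n_edges_kept = length(keep)),
            class = "thresholded_graph")
}

#' @export
#' @method print thresholded_graph
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("Thresholded weighted graph: %d nodes, %d edges (sparsity %.2f)\n",
              nrow(x$weights), x$n_edges_kept, x$sparsity))
  invisible(x)
}
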