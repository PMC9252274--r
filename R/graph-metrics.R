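#' Nodal strength
#'
#' Strength of node *i* is the sum of the weights of its incident edges,
#' `k_i = sum_j w_ij`.
#'
#' @param g A `thresholded_graph` (or nonnegative symmetric weight matrix).
#' @return Numeric vector of nodal strengths.
#' @export
nodal_strength <- function(g) {
  W <- graph_weights(g)
  rowSums(W)
}

#' Nodal efficiency
#'
#' Mean inverse weighted shortest-path length from each node to all others,
#' `E_i = sum_{j != i} d_ij^{-1} / (n - 1)`, with edge length `1/w` by default
#' (`-log(w)` available). Unreachable pairs contribute zero.
#'
#' @param g A `thresholded_graph` or weight matrix.
#' @param length One of `"inverse"` (`1/w`, default) or `"neglog"`.
#' @return Numeric vector of nodal efficiencies.
#' @export
nodal_efficiency <- function(g, length = c("inverse", "neglog")) {
  length <- match.arg(length)
  W <- graph_weights(g)
  res <- nodal_metrics_cpp(W, length_mode = if (length == "inverse") 1L else 2L,
                           norm_max = TRUE, denom_mode = 1L)
  as.numeric(res$efficiency)
}

#' Nodal clustering coefficient
#'
#' Weighted clustering via geometric-mean triangle intensities:
#' `t_i = (1/2) * sum_{j,h} (w'_ij w'_jh w'_hi)^{1/3}` with weights normalised
#' by the graph maximum (`w' = w / max(w)`), and
#' `C_i = 2 t_i / (deg_i (deg_i - 1))` with `deg_i` the count of
#' suprathreshold neighbours; `C_i = 0` for nodes of degree < 2. A strength
#' denominator variant is available but is not bounded by 1.
#'
#' @param g A `thresholded_graph` or weight matrix.
#' @param normalization `"max"` (default) to normalise weights by the graph
#'   maximum before triangle products, `"none"` to use raw weights.
#' @param denominator `"degree"` (default) or `"strength"`.
#' @return Numeric vector of nodal clustering coefficients.
#' @export
nodal_clustering <- function(g, normalization = c("max", "none"),
                             denominator = c("degree", "strength")) {
  normalization <- match.arg(normalization)
  denominator <- match.arg(denominator)
  W <- graph_weights(g)
  res <- nodal_metrics_cpp(W, length_mode = 1L,
                           norm_max = normalization == "max",
                           denom_mode = if (denominator == "degree") 1L else 2L)
  as.numeric(res$clustering)
}

graph_weights <- function(g) {
  W <- if (inherits(g, "thresholded_graph")) g$weights else as.matrix(g)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square", call. = FALSE)
  if (any(W < 0)) stop("weights must be nonnegative", call. = FALSE)
  W
}

#' Integrate a metric over the sparsity grid
#'
#' Summarises per-level metric values into a single sparsity-independent
#' value. The default is the unweighted mean over the grid; the trapezoid
#' area-under-curve divided by the grid range differs only in endpoint
#' weights and is available for comparison. Both are affine-equivalent for a
#' fixed grid, so downstream test significance is unaffected by the choice.
#'
#' @param values Numeric vector (or matrix with one row per level) of metric
#'   values at the grid levels.
#' @param levels The sparsity levels the values correspond to; must be
#'   exactly [sparsity_grid()] unless `partial = TRUE`.
#' @param method `"mean"` (default) or `"trapezoid"`.
#' @param partial Allow a grid other than the canonical 46 levels.
#' @return A single value (or vector, for matrix input: one per column).
#' @export
integrate_over_sparsity <- function(values, levels = sparsity_grid(),
                                    method = c("mean", "trapezoid"),
                                    partial = FALSE) {
  method <- match.arg(method)
  if (!partial) {
    full <- sparsity_grid()
    missing_lv <- setdiff(round(full, 10), round(levels, 10))
    if (length(missing_lv))
      stop("missing sparsity levels: ", paste(missing_lv, collapse = ", "),
           call. = FALSE)
  }
  vm <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(vm) != length(levels))
    stop("values and levels lengths differ", call. = FALSE)
  out <- if (method == "mean") {
    colMeans(vm)
  } else {
    h <- diff(levels)
    apply(vm, 2, function(v)
      sum(h * (v[-1] + v[-length(v)]) / 2) / (max(levels) - min(levels)))
  }
  if (is.matrix(values)) out else unname(out[1])
}

#' Per-session network metrics over the sparsity sweep
#'
#' For one FC matrix, thresholds at every grid level and computes nodal
#' strength, nodal efficiency and clustering coefficient, plus their global
#' (node-mean by default) summaries, then integrates over the grid.
#'
#' @param fc An `fc_matrix`.
#' @param grid Sparsity levels (default [sparsity_grid()]).
#' @param length Edge-length convention for shortest paths, see
#'   [nodal_efficiency()].
#' @param normalization,denominator Clustering conventions, see
#'   [nodal_clustering()].
#' @param global One of `"mean"` (default) or `"sum"`: how nodal values are
#'   aggregated into the global metric. Both differ by the fixed factor `n`,
#'   so z-scored group inference is identical under either.
#' @return List with `nodal` (list of three `levels x regions` matrices),
#'   `global` (`levels x 3` matrix), `integrated` (list `nodal` 3 x regions
#'   matrix, `global` length-3 vector), `grid`, `n_edges_kept`.
#' @export
session_metrics <- function(fc, grid = sparsity_grid(),
                            length = c("inverse", "neglog"),
                            normalization = c("max", "none"),
                            denominator = c("degree", "strength"),
                            global = c("mean", "sum")) {
  length <- match.arg(length)
  normalization <- match.arg(normalization)
  denominator <- match.arg(denominator)
  global <- match.arg(global)
  z <- if (inherits(fc, "fc_matrix")) fc$z else as.matrix(fc)
  n <- nrow(z)
  counts <- vapply(grid, edge_count, integer(1), n = n)
  if (is.unsorted(counts))
    stop("sparsity grid must be increasing", call. = FALSE)
  res <- metric_grid_cpp(z, counts,
                         length_mode = if (length == "inverse") 1L else 2L,
                         norm_max = normalization == "max",
                         denom_mode = if (denominator == "degree") 1L else 2L)
  agg <- if (global == "mean") rowMeans else rowSums
  nodal <- list(strength = res$strength, efficiency = res$efficiency,
                clustering = res$clustering)
  glob <- cbind(strength = agg(res$strength),
                efficiency = agg(res$efficiency),
                clustering = agg(res$clustering))
  integrated_nodal <- vapply(nodal, colMeans, numeric(n))  # mean over levels
  list(nodal = nodal, global = glob,
       integrated = list(nodal = t(integrated_nodal),
                         global = colMeans(glob)),
       grid = grid, n_edges_kept = res$n_edges_kept)
}

#' Sparsity-integrated metric table for a set of sessions
#'
#' Runs [session_metrics()] on every session's FC matrix and assembles the
#' sparsity-integrated values into a metric table: global values (one row per
#' session, columns strength/efficiency/clustering) and nodal matrices
#' (sessions x regions, one per metric).
#'
#' @param fc_list Named list of `fc_matrix` objects (names = session ids).
#' @inheritParams session_metrics
#' @return Object of class `metric_table`: list with `global` (data.frame:
#'   session_id, strength, efficiency, clustering), `nodal` (list of three
#'   sessions x regions matrices), `stage` (`"integrated"`), `grid`.
#' @export
compute_metric_table <- function(fc_list, grid = sparsity_grid(),
                                 length = "inverse", normalization = "max",
                                 denominator = "degree", global = "mean") {
  ids <- names(fc_list)
  if (is.null(ids))
    ids <- vapply(fc_list, function(f)
      if (!is.null(f$session_id)) as.character(f$session_id) else NA_character_,
      character(1))
  per <- lapply(fc_list, session_metrics, grid = grid, length = length,
                normalization = normalization, denominator = denominator,
                global = global)
  glob <- do.call(rbind, lapply(per, function(p) p$integrated$global))
  labels <- (if (inherits(fc_list[[1]], "fc_matrix"))
    fc_list[[1]]$region_labels else colnames(fc_list[[1]]))
  nodal <- lapply(c(strength = "strength", efficiency = "efficiency",
                    clustering = "clustering"), function(m) {
    M <- do.call(rbind, lapply(per, function(p) p$integrated$nodal[m, ]))
    dimnames(M) <- list(ids, labels)
    M
  })
  structure(list(global = data.frame(session_id = ids,
                                     strength = glob[, "strength"],
                                     efficiency = glob[, "efficiency"],
                                     clustering = glob[, "clustering"],
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
                 nodal = nodal, stage = "integrated", grid = grid),
            class = "metric_table")
}

#' @export
#' @method print metric_table
print.metric_table <- function(x, ...) {
  cat(sprintf("Metric table (%s): %d sessions, %d regions\n", x$stage,
              nrow(x$global), ncol(x$nodal$strength)))
  print(head(x$global, 4))
  invisible(x)
}

#' Z-score a metric table across sessions
#'
#' Standardises every metric column (global and nodal) across all sessions
#' pooled, using the n-1 SD. Rescaling to z-scores has no influence on the
#' significance of group differences; it only puts the three metrics on a
#' comparable scale.
#'
#' @param table A `metric_table`.
#' @return The table with all values standardised and `stage = "zscored"`.
#' @export
zscore_metrics <- function(table) {
  stopifnot(inherits(table, "metric_table"))
  if (nrow(table$global) < 2L)
    stop("at least 2 sessions are required to z-score", call. = FALSE)
  zs <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-SD metric column cannot be z-scored", call. = FALSE)
    (v - mean(v)) / s
  }
  for (m in c("strength", "efficiency", "clustering")) {
    table$global[[m]] <- zs(table$global[[m]])
    table$nodal[[m]] <- apply(table$nodal[[m]], 2, zs)
  }
  table$stage <- "zscored"
  table
}
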