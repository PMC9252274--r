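#' Stack per-session FC matrices into an edge matrix
#'
#' @param fc_list List of `fc_matrix` objects (or symmetric matrices).
#' @return List with `Y` (sessions x edges matrix of upper-triangle Fisher-z
#'   values), `edge_i`, `edge_j` (1-based endpoints), `labels`, `n`.
#' @export
edge_stack <- function(fc_list) {
  z1 <- if (inherits(fc_list[[1]], "fc_matrix")) fc_list[[1]]$z else fc_list[[1]]
  n <- nrow(z1)
  ut <- which(upper.tri(z1), arr.ind = TRUE)
  Y <- t(vapply(fc_list, function(f) {
    z <- if (inherits(f, "fc_matrix")) f$z else f
    z[ut]
  }, numeric(nrow(ut))))
  labels <- if (inherits(fc_list[[1]], "fc_matrix"))
    fc_list[[1]]$region_labels else colnames(z1)
  rownames(Y) <- names(fc_list)
  list(Y = Y, edge_i = ut[, 1], edge_j = ut[, 2], labels = labels, n = n)
}

# Mixed-effects adjustment of a response matrix (one column per edge).
# The model structure is fitted once on the first well-conditioned column and
# re-estimated per column via refit(), which is exactly a fresh fit of the
# same formula to the new response. Degenerate (near-constant) columns are
# passed through unadjusted and flagged.
#
# remove_subject controls whether the predicted subject intercepts are also
# subtracted. For permutation inference they must NOT be: the intercepts are
# estimated around the observed sex-group means, so subtracting them bakes
# the observed labelling into the data and destroys exchangeability. The
# subject effects instead stay in the adjusted data and are handled by
# permuting labels at the subject level.
#
# include_sex controls whether sex is in the estimation model for the
# nuisance coefficients. Permutation inference requires include_sex = FALSE
# (Freedman-Lane residualisation on the reduced model): with sex in the
# model the nuisance fit is orthogonalised against the observed labels,
# which privileges the observed sex direction over permuted ones.
adjust_edge_matrix <- function(Y, covariates, subject_id, sex,
                               remove_subject = FALSE, include_sex = TRUE) {
  sex <- factor(as.character(sex), levels = c("men", "women"))
  X <- covariate_matrix(as.data.frame(covariates))
  kept <- complete.cases(X) & !apply(Y, 1, anyNA)
  Xc <- scale(X[kept, , drop = FALSE], center = TRUE, scale = FALSE)
  Xc <- drop_constant_columns(Xc)
  df <- data.frame(sex = sex[kept], subject = factor(subject_id[kept]))
  df <- cbind(df, as.data.frame(Xc))
  nuisance <- colnames(Xc)
  rhs <- paste(c(if (include_sex) "sex", nuisance), collapse = " + ")
  fml <- as.formula(paste("y ~", rhs, "+ (1 | subject)"))
  Yk <- Y[kept, , drop = FALSE]
  vars <- apply(Yk, 2, var)
  degenerate <- !is.finite(vars) | vars < 1e-12
  adj <- Yk
  base_fit <- NULL
  mixed_ok <- TRUE
  subj_chr <- as.character(df$subject)
  for (e in which(!degenerate)) {
    df$y <- Yk[, e]
    fit <- if (!mixed_ok) {
      NULL
    } else if (is.null(base_fit)) {
      base_fit <- tryCatch(
        suppressMessages(lme4::lmer(fml, data = df, REML = TRUE)),
        error = function(err) NULL)
      if (is.null(base_fit)) {
        # e.g. every subject contributes a single session: the random
        # intercept is unidentifiable and adjustment is fixed-effects only
        mixed_ok <- FALSE
        warning("mixed-model edge adjustment unavailable; ",
                "using fixed effects only")
      }
      base_fit
    } else {
      tryCatch(suppressMessages(lme4::refit(base_fit, newresp = Yk[, e])),
               error = function(err) NULL)
    }
    if (is.null(fit)) {
      lmfit <- lm(as.formula(paste("y ~", rhs)), data = df)
      beta <- coef(lmfit)[nuisance]
      adj[, e] <- df$y - as.numeric(Xc %*% beta)
    } else {
      beta <- lme4::fixef(fit)[nuisance]
      adj[, e] <- df$y - as.numeric(Xc %*% beta)
      if (remove_subject) {
        blup <- lme4::ranef(fit)$subject
        b <- setNames(blup[["(Intercept)"]], rownames(blup))
        adj[, e] <- adj[, e] - b[subj_chr]
      }
    }
  }
  if (any(degenerate))
    message(sum(degenerate), " degenerate edge(s) passed through unadjusted")
  list(adjusted = adj, kept = kept, degenerate = degenerate,
       sex = droplevels(df$sex))
}

# Vectorized one-sided pooled t over the columns of Y.
# direction "women_lt_men": t > 0 when men exceed women.
edge_t <- function(Y, is_men, direction) {
  n1 <- sum(is_men); n2 <- sum(!is_men)
  m1 <- colMeans(Y[is_men, , drop = FALSE])
  m2 <- colMeans(Y[!is_men, , drop = FALSE])
  ss1 <- colSums(Y[is_men, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(Y[!is_men, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- if (direction == "women_lt_men") m1 - m2 else m2 - m1
  t <- ifelse(se > 0, diff / se, 0)
  list(t = t, df = n1 + n2 - 2L)
}

#' Edge-wise adjusted sex contrasts
#'
#' For every region pair, adjusts the Fisher-z connectivity with the same
#' mixed-effects formula used for network metrics (nuisance covariate effects
#' removed; subject intercepts retained by default so that subject-level
#' permutation inference stays exact), then computes a one-sided two-sample
#' t-statistic in the requested direction.
#'
#' @param fc_list List of per-session `fc_matrix` objects.
#' @param covariates Data frame of nuisance covariates, one row per session.
#' @param subject_id,sex Per-session subject ids and sex labels.
#' @param direction `"women_lt_men"` (default; positive t = lower FC in
#'   women) or `"women_gt_men"`.
#' @param remove_subject Also subtract predicted subject intercepts (as the
#'   metric-level adjustment does). Leave `FALSE` when the statistics feed
#'   permutation inference.
#' @param include_sex Keep sex in the estimation model for the nuisance
#'   coefficients. Set `FALSE` for Freedman-Lane residualisation on the
#'   reduced model, as [nbs_permutation()] does.
#' @return Object of class `edge_stats`: list with symmetric matrices `t` and
#'   `p` (raw one-sided), `direction`, `df`, `labels`, plus the internal edge
#'   stack (used by [nbs_permutation()]).
#' @export
edgewise_stats <- function(fc_list, covariates, subject_id, sex,
                           direction = c("women_lt_men", "women_gt_men"),
                           remove_subject = FALSE, include_sex = TRUE) {
  direction <- match.arg(direction)
  stack <- edge_stack(fc_list)
  adj <- adjust_edge_matrix(stack$Y, covariates, subject_id, sex,
                            remove_subject = remove_subject,
                            include_sex = include_sex)
  is_men <- adj$sex == "men"
  et <- edge_t(adj$adjusted, is_men, direction)
  p <- pt(et$t, et$df, lower.tail = FALSE)
  p[adj$degenerate] <- 1
  n <- stack$n
  Tm <- matrix(0, n, n, dimnames = list(stack$labels, stack$labels))
  Pm <- matrix(1, n, n, dimnames = list(stack$labels, stack$labels))
  idx <- cbind(stack$edge_i, stack$edge_j)
  Tm[idx] <- et$t; Tm[idx[, 2:1]] <- et$t
  Pm[idx] <- p; Pm[idx[, 2:1]] <- p
  diag(Pm) <- NA; diag(Tm) <- NA
  structure(list(t = Tm, p = Pm, direction = direction, df = et$df,
                 labels = stack$labels, stack = stack, adjust = adj),
            class = "edge_stats")
}

# union-find over an edge list; returns component id per supplied edge
components_from_edges <- function(ei, ej, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ei)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_along(ei), function(k) find(ei[k]), integer(1))
}

#' Supra-threshold connected components
#'
#' Extracts the connected components of the graph formed by edges whose raw
#' one-sided p falls below the primary threshold, sorted by extent (edge
#' count) descending.
#'
#' @param edge_stats An `edge_stats` object (or a symmetric p matrix).
#' @param threshold Primary p-value cutoff in (0, 1) (default 0.005).
#' @return List of components, each a list with `edges` (matrix of endpoint
#'   indices), `nodes`, `extent`.
#' @export
supra_components <- function(edge_stats, threshold = 0.005) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  P <- if (inherits(edge_stats, "edge_stats")) edge_stats$p else edge_stats
  n <- nrow(P)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  supra <- which(P[ut] < threshold)
  if (!length(supra)) return(list())
  ei <- ut[supra, 1]; ej <- ut[supra, 2]
  comp <- components_from_edges(ei, ej, n)
  out <- lapply(split(seq_along(comp), comp), function(ks) {
    edges <- cbind(i = ei[ks], j = ej[ks])
    list(edges = edges, nodes = sort(unique(c(edges))),
         extent = nrow(edges))
  })
  unname(out[order(-vapply(out, `[[`, numeric(1), "extent"))])
}

# max component statistic for one label assignment, from precomputed t values
max_component_stat <- function(t, tcrit, ei, ej, n, statistic) {
  supra <- which(t > tcrit)
  if (!length(supra)) return(0)
  comp <- components_from_edges(ei[supra], ej[supra], n)
  if (statistic == "extent") {
    max(tabulate(match(comp, unique(comp))))
  } else {
    max(vapply(split(t[supra], comp), sum, numeric(1)))
  }
}

#' Network-based statistic with subject-level permutation
#'
#' Computes observed supra-threshold components of the edge-wise adjusted sex
#' contrast and assigns each a family-wise-error-corrected p-value from the
#' permutation distribution of the maximal component statistic. Sex labels
#' are permuted at the subject level (all sessions of a subject move
#' together), respecting the exchangeability structure of repeated sessions.
#'
#' By default the nuisance adjustment is computed once: the covariate fixed
#' effects of the reduced (sex-free) mixed model are subtracted from every
#' edge, and only the sex contrast is recomputed under each permutation (a
#' Freedman-Lane-style shortcut). Subject intercepts are deliberately left in
#' the data — the subject-level permutation accounts for them — and sex is
#' deliberately left out of the estimation model, so the observed labelling
#' holds no privileged position in the residualised data. With `exact = TRUE`
#' the full mixed-model adjustment (sex in the model, subject intercepts
#' removed) is refitted under every permutation (slow; for verification at
#' small scale). FWE
#' p-values use the add-one estimator
#' `(1 + #{null max >= observed}) / (1 + n_perm)` and so are never zero.
#'
#' @inheritParams edgewise_stats
#' @param n_perm Number of permutations (>= 100; 10000 for confirmatory
#'   runs). If fewer distinct subject-label assignments exist they are
#'   enumerated exhaustively with a warning.
#' @param threshold Primary p-value cutoff (default 0.005).
#' @param statistic Component statistic: `"extent"` (edge count, default) or
#'   `"intensity"` (sum of supra-threshold t values).
#' @param exact Recompute the full mixed-model adjustment under every
#'   permutation instead of the Freedman-Lane-style shortcut.
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `nbs_result`: list with `components` (each with
#'   `edges`, `nodes`, `extent`, `intensity`, `fwe_p`), `edge_stats`,
#'   `n_perm`, `threshold`, `direction`, `statistic`, `seed`, `null_max`
#'   (the permutation distribution of the maximal component statistic).
#' @export
nbs_permutation <- function(fc_list, covariates, subject_id, sex,
                            n_perm = 1000L, threshold = 0.005,
                            direction = c("women_lt_men", "women_gt_men"),
                            statistic = c("extent", "intensity"),
                            exact = FALSE, seed = 1L) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  # shortcut mode: Freedman-Lane residualisation on the nuisance-only model
  # (no sex, no subject-intercept removal) so that every label assignment —
  # observed included — is processed identically
  es <- edgewise_stats(fc_list, covariates, subject_id, sex,
                       direction = direction,
                       remove_subject = exact, include_sex = exact)
  obs <- supra_components(es, threshold)
  stack <- es$stack
  Y <- es$adjust$adjusted
  kept_sub <- as.character(subject_id)[es$adjust$kept]
  df <- es$df
  tcrit <- qt(1 - threshold, df)
  Tobs <- es$t[cbind(stack$edge_i, stack$edge_j)]
  for (k in seq_along(obs)) {
    idx <- match(paste(obs[[k]]$edges[, 1], obs[[k]]$edges[, 2]),
                 paste(stack$edge_i, stack$edge_j))
    obs[[k]]$intensity <- sum(Tobs[idx])
  }
  # subject-level label assignments (who is labelled "men")
  subjects <- unique(kept_sub)
  subj_sex <- es$adjust$sex[match(subjects, kept_sub)]
  n_men_sub <- sum(subj_sex == "men")
  n_distinct <- choose(length(subjects), n_men_sub)
  set.seed(seed)
  if (n_distinct <= n_perm) {
    warning(sprintf(
      "only %.0f distinct subject-label assignments; enumerating all",
      n_distinct))
    assign_idx <- combn(length(subjects), n_men_sub, simplify = FALSE)
  } else {
    assign_idx <- replicate(n_perm, sample(length(subjects), n_men_sub),
                            simplify = FALSE)
  }
  sess_subj_pos <- match(kept_sub, subjects)
  null_max <- vapply(assign_idx, function(men_set) {
    is_men <- sess_subj_pos %in% men_set
    t <- if (exact) {
      sex_perm <- ifelse(is_men, "men", "women")
      adj_p <- suppressWarnings(suppressMessages(
        adjust_edge_matrix(stack$Y[es$adjust$kept, , drop = FALSE],
                           as.data.frame(covariates)[es$adjust$kept, ,
                                                     drop = FALSE],
                           kept_sub, sex_perm, remove_subject = TRUE)))
      edge_t(adj_p$adjusted, is_men, direction)$t
    } else {
      edge_t(Y, is_men, direction)$t
    }
    max_component_stat(t, tcrit, stack$edge_i, stack$edge_j, stack$n,
                       statistic)
  }, numeric(1))
  m <- length(null_max)
  for (k in seq_along(obs)) {
    stat_obs <- if (statistic == "extent") obs[[k]]$extent else
      obs[[k]]$intensity
    obs[[k]]$fwe_p <- (1 + sum(null_max >= stat_obs)) / (1 + m)
  }
  structure(list(components = obs, edge_stats = es, n_perm = m,
                 threshold = threshold, direction = direction,
                 statistic = statistic, exact = exact, seed = seed,
                 null_max = null_max),
            class = "nbs_result")
}

#' @export
#' @method print nbs_result
print.nbs_result <- function(x, ...) {
  cat(sprintf(
    "NBS (%s, primary p < %g, %d permutations, statistic = %s)\n",
    x$direction, x$threshold, x$n_perm, x$statistic))
  if (!length(x$components)) {
    cat("  no supra-threshold components\n")
    return(invisible(x))
  }
  for (k in seq_along(x$components)) {
    cm <- x$components[[k]]
    cat(sprintf("  component %d: %d edges, %d nodes, FWE p = %.4f\n",
                k, cm$extent, length(cm$nodes), cm$fwe_p))
  }
  invisible(x)
}

#' Macroarea-level summary of an NBS component
#'
#' Counts the component's edges within and between the six macroareas.
#'
#' @param component One element of `nbs_result$components`.
#' @param macroareas Character vector mapping node index positions to
#'   macroarea labels (e.g. from [macroarea_assign()] applied to the region
#'   labels of the FC matrices, in matrix order).
#' @return Symmetric count matrix over the macroarea labels; the sum of its
#'   diagonal plus upper triangle equals the component extent.
#' @export
macroarea_summary <- function(component, macroareas) {
  areas <- sort(unique(unname(macroareas)))
  M <- matrix(0L, length(areas), length(areas),
              dimnames = list(areas, areas))
  for (k in seq_len(nrow(component$edges))) {
    a <- unname(macroareas[component$edges[k, 1]])
    b <- unname(macroareas[component$edges[k, 2]])
    if (is.na(a) || is.na(b))
      stop("component node not present in the macroarea mapping",
           call. = FALSE)
    M[a, b] <- M[a, b] + 1L
    if (a != b) M[b, a] <- M[b, a] + 1L
  }
  M
}
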