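test_that("supra-threshold components are extracted correctly on toys", {
  n <- 6
  P <- matrix(1, n, n)
  set_edge <- function(P, i, j, v) { P[i, j] <- v; P[j, i] <- v; P }
  P <- set_edge(P, 1, 2, 1e-4)
  P <- set_edge(P, 2, 3, 1e-4)
  P <- set_edge(P, 5, 6, 1e-4)
  comps <- supra_components(P, 0.005)
  expect_length(comps, 2)
  expect_equal(comps[[1]]$extent, 2)
  expect_equal(comps[[1]]$nodes, 1:3)
  expect_equal(comps[[2]]$extent, 1)
  expect_equal(comps[[2]]$nodes, 5:6)
  # no supra edges
  expect_length(supra_components(matrix(1, 4, 4), 0.005), 0)
  # fully supra graph
  Pall <- matrix(1e-6, 5, 5)
  call <- supra_components(Pall, 0.005)
  expect_length(call, 1)
  expect_equal(call[[1]]$extent, 10)
  expect_error(supra_components(P, 0), "threshold")
})

test_that("component extraction agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(20)
  for (rep in 1:20) {
    n <- 15
    P <- matrix(1, n, n)
    ut <- which(upper.tri(P), arr.ind = TRUE)
    supra <- sample(nrow(ut), 12)
    P[ut[supra, , drop = FALSE]] <- 1e-4
    P[ut[supra, , drop = FALSE][, 2:1]] <- 1e-4
    comps <- supra_components(P, 0.005)
    A <- (P < 0.005) * 1
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    ref <- igraph::components(g)
    ref_sizes <- sort(table(ref$membership[ref$csize[ref$membership] > 1]))
    got_nodes <- sort(vapply(comps, function(cm) length(cm$nodes), integer(1)))
    expect_equal(sort(as.integer(ref_sizes)), got_nodes)
    expect_equal(sum(vapply(comps, `[[`, numeric(1), "extent")), 12)
  }
})

test_that("edgewise stats recover an implanted uniform deficit direction", {
  cfg <- sim_config(n_men = 12, n_women = 12, n_regions = 8,
                    n_timepoints = 80, sex_effect_scale = 0.6, seed = 31)
  st <- simulate_study(cfg)
  ses <- st$cohort$sessions
  fc <- fc_from_study(st)
  es <- suppressMessages(
    edgewise_stats(fc, ses[, c("age", "education", "handedness", "apoe4")],
                   ses$subject_id, ses$sex, direction = "women_lt_men"))
  tv <- es$t[upper.tri(es$t)]
  expect_gt(median(tv), 0)  # women lower -> positive t in this direction
  # direction reversal flips p to 1 - p
  es2 <- suppressMessages(
    edgewise_stats(fc, ses[, c("age", "education", "handedness", "apoe4")],
                   ses$subject_id, ses$sex, direction = "women_gt_men"))
  pv1 <- es$p[upper.tri(es$p)]
  pv2 <- es2$p[upper.tri(es2$p)]
  expect_equal(pv1 + pv2, rep(1, length(pv1)), tolerance = 1e-10)
})

test_that("NBS is deterministic given a seed and FWE p is never zero", {
  cfg <- sim_config(n_men = 10, n_women = 10, n_regions = 8,
                    n_timepoints = 60, sex_effect_scale = 0.5, seed = 32)
  st <- simulate_study(cfg)
  ses <- st$cohort$sessions
  fc <- fc_from_study(st)
  covars <- ses[, c("age", "education", "handedness", "apoe4")]
  r1 <- suppressMessages(nbs_permutation(fc, covars, ses$subject_id, ses$sex,
                                         n_perm = 120, seed = 5))
  r2 <- suppressMessages(nbs_permutation(fc, covars, ses$subject_id, ses$sex,
                                         n_perm = 120, seed = 5))
  expect_identical(vapply(r1$components, `[[`, numeric(1), "fwe_p"),
                   vapply(r2$components, `[[`, numeric(1), "fwe_p"))
  expect_true(all(vapply(r1$components, `[[`, numeric(1), "fwe_p") > 0))
  expect_error(nbs_permutation(fc, covars, ses$subject_id, ses$sex,
                               n_perm = 10), "n_perm")
})

test_that("small cohorts trigger exhaustive enumeration with a warning", {
  cfg <- sim_config(n_men = 3, n_women = 3, n_regions = 6,
                    n_timepoints = 40, seed = 33)
  st <- simulate_study(cfg)
  ses <- st$cohort$sessions
  fc <- fc_from_study(st)
  covars <- ses[, c("age", "education", "handedness", "apoe4")]
  expect_warning(
    r <- suppressMessages(nbs_permutation(fc, covars, ses$subject_id,
                                          ses$sex, n_perm = 100, seed = 1)),
    "enumerating")
  expect_equal(r$n_perm, choose(6, 3))
})

test_that("NBS localizes a strong implanted block deficit", {
  block <- 1:10
  cfg <- sim_config(n_men = 30, n_women = 30, n_regions = 24,
                    n_timepoints = 100, sex_effect_scale = 0.45,
                    seed = 34, base_rho = 0.35)
  # deficit confined to the block: build covariances by hand
  covs <- build_group_covariance(sim_config(n_regions = 24, seed = 34,
                                            base_rho = 0.35))
  R_w <- covs$men
  R_w[block, block] <- 0.45 * R_w[block, block]
  diag(R_w) <- 1
  coh <- generate_cohort(cfg)
  ses <- coh$sessions
  ts <- lapply(seq_len(nrow(ses)), function(i)
    generate_session_timeseries(
      if (ses$sex[i] == "men") covs$men else R_w, cfg, seed = 9000 + i))
  names(ts) <- ses$session_id
  fc <- lapply(ses$session_id, function(sid) compute_fc(ts[[sid]], sid))
  names(fc) <- ses$session_id
  covars <- ses[, c("age", "education", "handedness", "apoe4")]
  res <- suppressMessages(nbs_permutation(fc, covars, ses$subject_id,
                                          ses$sex, n_perm = 200, seed = 2))
  expect_gt(length(res$components), 0)
  top <- res$components[[1]]
  expect_gte(mean(block %in% top$nodes), 0.8)
  expect_lt(top$fwe_p, 0.05)
})

test_that("exact permutation mode runs, is deterministic and broadly agrees", {
  cfg <- sim_config(n_men = 3, n_women = 3, n_regions = 5, n_timepoints = 60,
                    sex_effect_scale = 0.4, seed = 36)
  st <- simulate_study(cfg)
  ses <- st$cohort$sessions
  fc <- fc_from_study(st)
  covars <- ses[, c("age", "education", "handedness", "apoe4")]
  shortcut <- suppressWarnings(suppressMessages(
    nbs_permutation(fc, covars, ses$subject_id, ses$sex, n_perm = 100,
                    threshold = 0.05, seed = 3)))
  exact <- suppressWarnings(suppressMessages(
    nbs_permutation(fc, covars, ses$subject_id, ses$sex, n_perm = 100,
                    threshold = 0.05, exact = TRUE, seed = 3)))
  exact2 <- suppressWarnings(suppressMessages(
    nbs_permutation(fc, covars, ses$subject_id, ses$sex, n_perm = 100,
                    threshold = 0.05, exact = TRUE, seed = 3)))
  expect_identical(vapply(exact$components, `[[`, numeric(1), "fwe_p"),
                   vapply(exact2$components, `[[`, numeric(1), "fwe_p"))
  # both modes see the same strong implanted deficit
  if (length(shortcut$components) && length(exact$components))
    expect_lt(abs(shortcut$components[[1]]$fwe_p -
                    exact$components[[1]]$fwe_p), 0.3)
})

test_that("macroarea summary counts conserve the component extent", {
  comp <- list(edges = cbind(i = c(1, 1, 2, 4), j = c(2, 3, 3, 5)),
               nodes = 1:5, extent = 4)
  areas <- c("A", "A", "B", "B", "C")
  M <- macroarea_summary(comp, areas)
  expect_equal(M["A", "A"], 1)          # edge 1-2
  expect_equal(M["A", "B"], 2)          # edges 1-3, 2-3
  expect_equal(M["B", "C"], 1)          # edge 4-5
  expect_true(isSymmetric(M))
  expect_equal(sum(diag(M)) + sum(M[upper.tri(M)]), comp$extent)
  # single-area component
  M2 <- macroarea_summary(list(edges = cbind(1, 2), extent = 1),
                          c("A", "A", "B"))
  expect_equal(M2["A", "A"], 1)
  expect_equal(sum(M2), 1)
})

test_that("subject-level permutation respects repeated-session clustering", {
  # With strong subject effects and 3 sessions per subject, labels are
  # exchangeable between subjects but not between sessions. The subject-level
  # permutation null of the maximal component extent must therefore be wider
  # than a session-level null (which breaks the within-subject blocks and so
  # understates the variability of block-aligned contrasts), and subject-level
  # inference must stay calibrated.
  reps <- 10
  msub <- mses <- numeric(reps)
  fwe_subject <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_men = 8, n_women = 8, n_regions = 8,
                      n_timepoints = 100, subject_effect_sd = 0.3,
                      sessions_per_subject = c(0, 0, 1),
                      seed = 900 + r)
    st <- simulate_study(cfg)
    ses <- st$cohort$sessions
    fc <- fc_from_study(st)
    covars <- ses[, c("age", "education", "handedness", "apoe4")]
    res <- suppressWarnings(suppressMessages(
      nbs_permutation(fc, covars, ses$subject_id, ses$sex,
                      n_perm = 150, threshold = 0.05, seed = r)))
    fwe_subject[r] <- length(res$components) > 0 &&
      res$components[[1]]$fwe_p < 0.05
    # session-level permutation: pretend every session is its own subject
    res2 <- suppressWarnings(suppressMessages(
      nbs_permutation(fc, covars, paste0("x", seq_len(nrow(ses))), ses$sex,
                      n_perm = 150, threshold = 0.05, seed = r)))
    msub[r] <- mean(res$null_max)
    mses[r] <- mean(res2$null_max)
  }
  expect_lte(mean(fwe_subject), 0.15)
  expect_gt(mean(msub), mean(mses))
})
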