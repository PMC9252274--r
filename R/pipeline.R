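#' End-to-end pipeline on a simulated (or supplied) study
#'
#' Orchestrates the full analysis: simulate (or accept) per-session time
#' series, build Fisher-z FC matrices, sweep the sparsity grid and integrate
#' the three network metrics, z-score, adjust with the mixed-effects model,
#' test the three global sex contrasts (Bonferroni m = 3) and the regional
#' contrasts (m = number of regions per metric family), and run NBS on the
#' inter-regional connectivity. Optionally writes all stage outputs plus a
#' provenance manifest.
#'
#' @param config A [sim_config()]; ignored when `study` is supplied.
#' @param study Optional pre-built study (list with `cohort`, `timeseries`)
#'   as returned by [simulate_study()].
#' @param out_dir Optional output directory for stage CSVs and the manifest.
#' @param nbs_n_perm Permutations for the NBS stage (default 1000).
#' @param nbs_threshold Primary NBS p threshold (default 0.005).
#' @param nbs_direction NBS contrast direction (default `"women_lt_men"`).
#' @param run_nbs Set `FALSE` to skip the NBS stage.
#' @param run_regional Set `FALSE` to skip the per-region contrast stage
#'   (useful for global-metric simulation studies).
#' @param seed Seed for the NBS permutation stream (default: config seed).
#' @return List with `cohort`, `fc`, `metrics` (z-scored `metric_table`),
#'   `adjusted` (per global metric), `global_contrasts` (data frame),
#'   `regional_contrasts` (list of data frames), `nbs` (an `nbs_result` or
#'   NULL), and `log` (session accounting per stage).
#' @export
run_pipeline <- function(config = sim_config(), study = NULL,
                         out_dir = NULL, nbs_n_perm = 1000L,
                         nbs_threshold = 0.005,
                         nbs_direction = "women_lt_men",
                         run_nbs = TRUE, run_regional = TRUE, seed = NULL) {
  if (is.null(study)) study <- simulate_study(config)
  cohort <- study$cohort
  ses <- cohort$sessions
  if (is.null(seed)) seed <- cohort$config$seed
  log <- list(n_sessions = nrow(ses), n_subjects = nrow(cohort$subjects))

  fc <- lapply(ses$session_id, function(sid)
    compute_fc(study$timeseries[[sid]], session_id = sid))
  names(fc) <- ses$session_id

  metrics <- compute_metric_table(fc)
  metrics_z <- zscore_metrics(metrics)

  covars <- ses[, c("age", "education", "handedness", "apoe4")]
  adjusted <- list()
  contrasts <- list()
  for (mname in c("strength", "efficiency", "clustering")) {
    adjusted[[mname]] <- fit_lme_adjust(metrics_z$global[[mname]], covars,
                                        ses$subject_id, ses$sex)
    contrasts[[mname]] <- sex_ttest(adjusted[[mname]], ses$sex, m = 3L)
  }
  global_contrasts <- do.call(rbind, lapply(names(contrasts), function(mn) {
    ct <- contrasts[[mn]]
    data.frame(metric = mn, t = ct$t, p = ct$p, p_bonf = ct$p_bonf,
               mean_men = ct$means["men"], mean_women = ct$means["women"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  n_regions <- ncol(metrics_z$nodal$strength)
  regional_contrasts <- if (!run_regional) list() else lapply(
    c(strength = "strength", efficiency = "efficiency",
      clustering = "clustering"),
    function(mn) {
      M <- metrics_z$nodal[[mn]]
      rows <- lapply(seq_len(n_regions), function(r) {
        adj <- fit_lme_adjust(M[, r], covars, ses$subject_id, ses$sex)
        ct <- sex_ttest(adj, ses$sex, m = n_regions)
        data.frame(region = colnames(M)[r], t = ct$t, p = ct$p,
                   p_bonf = ct$p_bonf, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })

  nbs <- NULL
  if (run_nbs)
    nbs <- nbs_permutation(fc, covars, ses$subject_id, ses$sex,
                           n_perm = nbs_n_perm, threshold = nbs_threshold,
                           direction = nbs_direction, seed = seed)

  result <- list(cohort = cohort, fc = fc, metrics = metrics_z,
                 adjusted = adjusted, global_contrasts = global_contrasts,
                 regional_contrasts = regional_contrasts, nbs = nbs,
                 log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, seed)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$cohort$sessions, file.path(out_dir, "participants.csv"),
            row.names = FALSE)
  write.csv(result$metrics$global, file.path(out_dir, "global_metrics.csv"),
            row.names = FALSE)
  write.csv(result$global_contrasts,
            file.path(out_dir, "global_contrasts.csv"), row.names = FALSE)
  for (mn in names(result$regional_contrasts))
    write.csv(result$regional_contrasts[[mn]],
              file.path(out_dir, paste0("regional_contrasts_", mn, ".csv")),
              row.names = FALSE)
  if (!is.null(result$nbs)) {
    comp <- result$nbs$components
    if (length(comp)) {
      labels <- result$nbs$edge_stats$labels
      edges <- do.call(rbind, lapply(seq_along(comp), function(k)
        data.frame(component = k,
                   region_i = labels[comp[[k]]$edges[, 1]],
                   region_j = labels[comp[[k]]$edges[, 2]],
                   stringsAsFactors = FALSE)))
      write.csv(edges, file.path(out_dir, "nbs_components.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(n_perm = result$nbs$n_perm, threshold = result$nbs$threshold,
           direction = result$nbs$direction,
           fwe_p = vapply(comp, `[[`, numeric(1), "fwe_p")),
      file.path(out_dir, "nbs_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  cfg_json <- as.character(jsonlite::toJSON(
    result$cohort$config[setdiff(names(result$cohort$config),
                                 "covariate_params")], auto_unbox = TRUE))
  manifest <- list(config_hash = fnv1a(cfg_json), seed = seed,
                   n_sessions = result$log$n_sessions,
                   n_subjects = result$log$n_subjects,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
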