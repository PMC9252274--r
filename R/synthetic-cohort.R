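#' Configuration for a synthetic resting-state cohort
#'
#' Bundles every knob of the synthetic-cohort generator: group sizes, the
#' distribution of repeated sessions per subject, the dimensions of the
#' regional time series, the implanted between-group connectivity effect, and
#' the covariate, amyloid-PET and cognition sub-models. Defaults reproduce the
#' demographic structure of a cognitively normal aging cohort with 48 men and
#' 74 women scanned roughly 1.7 times each over 94 cerebral regions.
#'
#' @param n_men,n_women Number of male / female subjects.
#' @param sessions_per_subject Probability vector over 1, 2 or 3 fMRI sessions
#'   per subject. The default mean (~1.7) matches the 1.6-1.8 sessions per
#'   subject typical of longitudinal aging cohorts.
#' @param n_regions Number of atlas regions (default 94).
#' @param n_timepoints Number of fMRI volumes per session (default 192,
#'   representative of 140-200-volume echo-planar runs; only the correlation
#'   estimates matter downstream).
#' @param sex_effect_scale Multiplier applied to the off-diagonal covariance of
#'   the female group. Values below 1 implant globally lower connectivity in
#'   women.
#' @param reversal_regions Integer indices of regions whose incident
#'   covariances receive the inverted factor `1/sex_effect_scale`, emulating
#'   subcortical structures (thalamus, dorsal striatum) where women show
#'   higher connectivity.
#' @param covariate_params Per-sex means/SDs for age, education and the
#'   session-level cognition score, plus left-handedness and APOE4-carrier
#'   probabilities.
#' @param base_rho Average off-diagonal correlation targeted by the
#'   factor-structured base covariance.
#' @param n_blocks Number of community blocks in the base covariance (default
#'   6, mirroring the six anatomical macroareas).
#' @param subject_effect_sd SD of the per-subject multiplier on off-diagonal
#'   covariance; positive values induce within-subject correlation of network
#'   metrics across repeated sessions (the subject random effect the
#'   mixed-effects stage absorbs).
#' @param suvr_params Amyloid-PET sub-model: positivity threshold, per-carrier
#'   status positivity probabilities, the two mixture components for composite
#'   SUVR, and the fractions of sessions with no PET or a PET outside the
#'   1-year matching window.
#' @param cognition_link Per-sex intercept/slope/noise linking a global network
#'   metric to a synthetic cognition score (used by [generate_cognition()]).
#' @param ar1_coef Temporal lag-1 autocorrelation of the simulated regional
#'   time series, in `[0, 1)`.
#' @param seed Integer seed; all generator stages derive their randomness from
#'   it deterministically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_men = 48L, n_women = 74L,
                       sessions_per_subject = c(0.45, 0.40, 0.15),
                       n_regions = 94L, n_timepoints = 192L,
                       sex_effect_scale = 1, reversal_regions = integer(0),
                       covariate_params = list(
                         age = list(men = c(mean = 72.2, sd = 4.3),
                                    women = c(mean = 72.6, sd = 4.5)),
                         education = list(men = c(mean = 17.7, sd = 2.2),
                                          women = c(mean = 16.3, sd = 2.3)),
                         adas_cog = list(men = c(mean = 5.7, sd = 2.3),
                                         women = c(mean = 5.5, sd = 2.2)),
                         left_handed_prob = c(men = 5 / 48, women = 11 / 74),
                         apoe4_prob = c(men = 12 / 48, women = 27 / 74)),
                       base_rho = 0.3, n_blocks = 6L,
                       subject_effect_sd = 0.05,
                       suvr_params = list(
                         threshold = 1.11,
                         p_positive = c(carrier = 0.60, noncarrier = 0.27),
                         mean_neg = 1.00, sd_neg = 0.05,
                         mean_pos = 1.30, sd_pos = 0.10,
                         p_pet_missing = 0.06, p_pet_far = 0.05),
                       cognition_link = list(
                         metric = "clustering",
                         intercept = c(men = 5.7, women = 5.5),
                         slope = c(men = 0, women = 0),
                         noise_sd = 2),
                       ar1_coef = 0.3, seed = 1L) {
  cfg <- list(n_men = as.integer(n_men), n_women = as.integer(n_women),
              sessions_per_subject = sessions_per_subject,
              n_regions = as.integer(n_regions),
              n_timepoints = as.integer(n_timepoints),
              sex_effect_scale = sex_effect_scale,
              reversal_regions = as.integer(reversal_regions),
              covariate_params = covariate_params,
              base_rho = base_rho, n_blocks = as.integer(n_blocks),
              subject_effect_sd = subject_effect_sd,
              suvr_params = suvr_params,
              cognition_link = cognition_link,
              ar1_coef = ar1_coef, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_men < 1L || cfg$n_women < 1L)
    stop("configuration error: group sizes must be positive", call. = FALSE)
  if (cfg$n_regions < 3L)
    stop("configuration error: n_regions must be >= 3", call. = FALSE)
  if (cfg$n_timepoints < 3L)
    stop("configuration error: n_timepoints must be >= 3", call. = FALSE)
  if (!(cfg$sex_effect_scale > 0))
    stop("configuration error: sex_effect_scale must be > 0", call. = FALSE)
  p <- cfg$sessions_per_subject
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("configuration error: sessions_per_subject must be a probability ",
         "vector over 1, 2, 3 sessions", call. = FALSE)
  if (cfg$ar1_coef < 0 || cfg$ar1_coef >= 1)
    stop("configuration error: ar1_coef must lie in [0, 1)", call. = FALSE)
  sds <- c(cfg$covariate_params$age$men["sd"], cfg$covariate_params$age$women["sd"],
           cfg$covariate_params$education$men["sd"],
           cfg$covariate_params$education$women["sd"],
           cfg$covariate_params$adas_cog$men["sd"],
           cfg$covariate_params$adas_cog$women["sd"])
  if (any(sds <= 0))
    stop("configuration error: covariate SDs must be positive", call. = FALSE)
  if (any(cfg$reversal_regions < 1L | cfg$reversal_regions > cfg$n_regions))
    stop("configuration error: reversal_regions out of range", call. = FALSE)
  invisible(cfg)
}

# Deterministic sub-seed stream, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %%
               2147483647)
}

#' Default region labels
#'
#' Returns the labels of the 94 cerebral regions of the revised automated
#' anatomical labelling atlas (47 bilateral pairs) when `n == 94`; for other
#' sizes generic `R001...` labels are produced (used by reduced-size
#' simulations).
#'
#' @param n Number of regions.
#' @return Character vector of length `n`.
#' @export
region_labels <- function(n = 94L) {
  if (n == 94L) {
    map <- macroarea_mapping()
    return(map$region)
  }
  sprintf("R%03d", seq_len(n))
}

#' Generate a synthetic cohort table
#'
#' Draws subjects (sex, age, education, handedness, APOE4 carrier status) and
#' their repeated fMRI sessions (dates, session-level ADAS-Cog, amyloid PET
#' SUVR with realistic missingness and MRI-PET date gaps). Subject-level
#' covariates are constant across a subject's sessions. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `fc_cohort`: a list with data frames `subjects`
#'   (subject_id, sex, age, education, handedness, apoe4) and `sessions`
#'   (session_id, subject_id, sex, mri_date, adas_cog, suvr, pet_date, plus
#'   the subject covariates replicated per session), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  cp <- config$covariate_params
  n <- config$n_men + config$n_women
  sex <- rep(c("men", "women"), c(config$n_men, config$n_women))
  subject_id <- sprintf("sub%03d", seq_len(n))
  draw <- function(par_list) {
    m <- par_list$men; w <- par_list$women
    ifelse(sex == "men", rnorm(n, m["mean"], m["sd"]),
           rnorm(n, w["mean"], w["sd"]))
  }
  age <- round(draw(cp$age), 1)
  education <- pmax(6, round(draw(cp$education)))
  lh_p <- ifelse(sex == "men", cp$left_handed_prob["men"],
                 cp$left_handed_prob["women"])
  handedness <- ifelse(rbinom(n, 1, lh_p) == 1, "L", "R")
  apoe_p <- ifelse(sex == "men", cp$apoe4_prob["men"], cp$apoe4_prob["women"])
  apoe4 <- rbinom(n, 1, apoe_p)
  subjects <- data.frame(subject_id = subject_id, sex = sex, age = age,
                         education = education, handedness = handedness,
                         apoe4 = apoe4, stringsAsFactors = FALSE)

  n_sessions <- sample(1:3, n, replace = TRUE,
                       prob = config$sessions_per_subject)
  base_date <- as.Date("2015-01-01") + sample(0:730, n, replace = TRUE)
  sp <- config$suvr_params
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_sessions[i]
    mri_date <- base_date[i] + round(cumsum(c(0, runif(k - 1, 150, 400))))
    adas <- pmax(0, round(rnorm(k,
      mean = if (sex[i] == "men") cp$adas_cog$men["mean"] else cp$adas_cog$women["mean"],
      sd = if (sex[i] == "men") cp$adas_cog$men["sd"] else cp$adas_cog$women["sd"]), 1))
    p_pos <- if (apoe4[i] == 1) sp$p_positive["carrier"] else sp$p_positive["noncarrier"]
    amy_pos <- rbinom(k, 1, p_pos)
    suvr <- ifelse(amy_pos == 1, rnorm(k, sp$mean_pos, sp$sd_pos),
                   rnorm(k, sp$mean_neg, sp$sd_neg))
    suvr <- round(pmax(suvr, 0.7), 3)
    pet_kind <- runif(k)
    pet_offset <- ifelse(pet_kind < sp$p_pet_far,
                         sample(370:900, k, replace = TRUE),
                         sample(-300:300, k, replace = TRUE))
    pet_date <- mri_date + pet_offset
    missing_pet <- pet_kind >= sp$p_pet_far &
      pet_kind < sp$p_pet_far + sp$p_pet_missing
    suvr[missing_pet] <- NA_real_
    pet_date[missing_pet] <- NA
    rows[[i]] <- data.frame(
      session_id = sprintf("%s_ses%02d", subject_id[i], seq_len(k)),
      subject_id = subject_id[i], sex = sex[i], mri_date = mri_date,
      adas_cog = adas, suvr = suvr, pet_date = pet_date,
      age = age[i], education = education[i],
      handedness = handedness[i], apoe4 = apoe4[i],
      stringsAsFactors = FALSE)
  }
  sessions <- do.call(rbind, rows)
  rownames(sessions) <- NULL
  structure(list(subjects = subjects, sessions = sessions, config = config),
            class = "fc_cohort")
}

#' @export
#' @method print fc_cohort
print.fc_cohort <- function(x, ...) {
  ns <- table(x$subjects$sex)
  nsess <- table(x$sessions$sex)
  cat("Synthetic resting-state cohort\n")
  cat(sprintf("  subjects: %d men, %d women\n", ns[["men"]], ns[["women"]]))
  cat(sprintf("  sessions: %d men, %d women (%.2f per subject)\n",
              nsess[["men"]], nsess[["women"]],
              nrow(x$sessions) / nrow(x$subjects)))
  cat(sprintf("  regions: %d, timepoints: %d, sex_effect_scale: %.3g\n",
              x$config$n_regions, x$config$n_timepoints,
              x$config$sex_effect_scale))
  invisible(x)
}

#' Group covariance matrices with an implanted sex effect
#'
#' Builds the male-group correlation matrix from a block-factor model (six
#' community blocks plus a global factor, guaranteeing positive definiteness)
#' and derives the female-group matrix by scaling all off-diagonal entries by
#' `sex_effect_scale`, except rows/columns of `reversal_regions`, whose
#' incident entries receive the inverted factor. If inversion breaks positive
#' definiteness the matrix is repaired by diagonal loading (and renormalised
#' to unit diagonal) with a message.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `men` and `women`, each an
#'   `n_regions x n_regions` correlation matrix.
#' @export
build_group_covariance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions
  set.seed(derive_seed(config$seed, 2L))
  block <- sort(rep(seq_len(config$n_blocks), length.out = n))
  # loadings chosen so mean off-diagonal correlation ~ base_rho
  lg <- sqrt(config$base_rho * 0.55) * runif(n, 0.85, 1.15)
  lb <- sqrt(config$base_rho * 0.9) * runif(n, 0.85, 1.15)
  R_men <- outer(lg, lg) + outer(lb, lb) * outer(block, block, "==")
  diag(R_men) <- 1
  s <- config$sex_effect_scale
  fac <- matrix(s, n, n)
  if (length(config$reversal_regions)) {
    fac[config$reversal_regions, ] <- 1 / s
    fac[, config$reversal_regions] <- 1 / s
  }
  R_women <- R_men * fac
  R_women[R_women > 0.97] <- 0.97   # cap inverted-factor correlations
  diag(R_women) <- 1
  R_men <- ensure_pd(R_men)
  R_women <- ensure_pd(R_women)
  list(men = R_men, women = R_women)
}

# Diagonal loading until the smallest eigenvalue clears 1e-6, then rescale
# back to a correlation matrix.
ensure_pd <- function(R, tol = 1e-6) {
  for (it in 1:50) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > tol) return(R)
    load <- abs(ev) + tol
    R <- R + diag(load, nrow(R))
    R <- stats::cov2cor(R)
    if (it == 1L)
      message("covariance repaired by diagonal loading (min eigenvalue ",
              signif(ev, 3), ")")
  }
  R
}

#' Simulate one session's regional time series
#'
#' Draws a `T x N` multivariate Gaussian time series whose columns follow the
#' correlation structure of `cov`, with optional per-region AR(1) temporal
#' autocorrelation (identical coefficient across regions, so the target
#' cross-correlation is preserved).
#'
#' @param cov Positive-definite covariance/correlation matrix (`N x N`).
#' @param config A [sim_config()] object (supplies `n_timepoints`, `ar1_coef`).
#' @param seed Integer seed for this session.
#' @param subject_scale Optional per-subject multiplier on the off-diagonal
#'   covariance (the subject random effect); 1 leaves `cov` untouched.
#' @return A `T x N` numeric matrix with region labels as column names.
#' @export
generate_session_timeseries <- function(cov, config, seed,
                                        subject_scale = 1) {
  Tn <- config$n_timepoints
  n <- nrow(cov)
  if (Tn < 3L) stop("n_timepoints must be >= 3", call. = FALSE)
  if (subject_scale != 1) {
    cov <- cov * subject_scale
    diag(cov) <- 1
    cov <- ensure_pd(cov)
  }
  set.seed(seed)
  phi <- config$ar1_coef
  E <- matrix(rnorm(Tn * n), Tn, n)
  if (phi > 0) {
    # stationary AR(1) innovations with unit marginal variance
    E[1, ] <- E[1, ]
    scale_innov <- sqrt(1 - phi^2)
    for (t in 2:Tn) E[t, ] <- phi * E[t - 1, ] + scale_innov * E[t, ]
  }
  ch <- tryCatch(chol(cov), error = function(e) chol(ensure_pd(cov)))
  X <- E %*% ch
  colnames(X) <- region_labels(n)
  X
}

#' Simulate a complete study: cohort plus per-session time series
#'
#' Orchestrates [generate_cohort()], [build_group_covariance()] and
#' [generate_session_timeseries()]; each session gets a deterministic sub-seed
#' and, when `subject_effect_sd > 0`, a subject-specific multiplier on
#' off-diagonal covariance that induces within-subject correlation of the
#' downstream network metrics.
#'
#' @param config A [sim_config()] object.
#' @return List with `cohort` (class `fc_cohort`), `timeseries` (named list of
#'   `T x N` matrices, one per session) and `truth` (the implanted
#'   parameters, for recovery checks).
#' @export
simulate_study <- function(config) {
  cohort <- generate_cohort(config)
  covs <- build_group_covariance(config)
  set.seed(derive_seed(config$seed, 3L))
  subj <- cohort$subjects
  subj_scale <- exp(rnorm(nrow(subj), 0, config$subject_effect_sd))
  subj_scale <- pmin(pmax(subj_scale, 0.6), 1.4)
  names(subj_scale) <- subj$subject_id
  ses <- cohort$sessions
  ts_list <- vector("list", nrow(ses))
  names(ts_list) <- ses$session_id
  for (i in seq_len(nrow(ses))) {
    R <- if (ses$sex[i] == "men") covs$men else covs$women
    ts_list[[i]] <- generate_session_timeseries(
      R, config, seed = derive_seed(config$seed, 100L + i),
      subject_scale = subj_scale[[ses$subject_id[i]]])
  }
  list(cohort = cohort, timeseries = ts_list,
       truth = list(sex_effect_scale = config$sex_effect_scale,
                    reversal_regions = config$reversal_regions,
                    subject_scale = subj_scale,
                    cognition_link = config$cognition_link))
}

#' Attach synthetic cognition scores linked to a network metric
#'
#' Generates per-session cognition scores as a per-sex affine function of a
#' supplied global network metric plus Gaussian noise, so that per-group
#' regression slope recovery can be verified against known truth.
#'
#' @param cohort An `fc_cohort`.
#' @param metric_values Numeric vector, one value per session, in
#'   `cohort$sessions` order (or named by session_id).
#' @param link List with per-sex `intercept` and `slope` (named `men`,
#'   `women`) and `noise_sd`; defaults to `cohort$config$cognition_link`.
#' @param score_name Column name for the new score (default `"score"`).
#' @param seed Integer seed (default derived from the cohort config).
#' @return The cohort with a score column appended to `sessions`.
#' @export
generate_cognition <- function(cohort, metric_values,
                               link = cohort$config$cognition_link,
                               score_name = "score", seed = NULL) {
  ses <- cohort$sessions
  if (!is.null(names(metric_values)))
    metric_values <- metric_values[ses$session_id]
  if (length(metric_values) != nrow(ses) || anyNA(metric_values))
    stop("one metric value per session is required", call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(cohort$config$seed, 4L)
  set.seed(seed)
  men <- ses$sex == "men"
  score <- ifelse(men,
                  link$intercept["men"] + link$slope["men"] * metric_values,
                  link$intercept["women"] + link$slope["women"] * metric_values)
  score <- score + rnorm(nrow(ses), 0, link$noise_sd)
  cohort$sessions[[score_name]] <- score
  cohort
}
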