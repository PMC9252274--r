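#' Mixed-effects adjustment of session-level values
#'
#' Fits the random-intercept linear mixed model
#' `y ~ sex + age + handedness + education + apoe4 + (1 | subject)` by REML
#' and returns adjusted values: the observed value minus the nuisance
#' fixed-effect contributions (covariates centred at their sample means) and
#' minus the predicted subject intercept. The sex effect and the residual are
#' retained, so a subsequent two-sample t-test on the adjusted values
#' estimates the sex contrast free of covariate and repeated-session
#' confounding. On fit failure the model falls back to maximum likelihood,
#' then to a fixed-effects-only fit, with a warning.
#'
#' @param values Numeric vector, one value per session.
#' @param covariates Data frame of nuisance covariates (numeric or two-level;
#'   typically age, education, handedness, apoe4), one row per session.
#'   Sessions with missing covariates are dropped with a message.
#' @param subject_id Factor/character vector of subject identifiers.
#' @param sex Factor/character with levels `men` / `women`.
#' @return Object of class `adjusted_values`: list with `adjusted` (numeric,
#'   NA for dropped sessions), `kept` (logical), `fit` (the model), `method`
#'   (`"REML"`, `"ML"` or `"fixed"`), `coefficients`, `varcomp` (subject and
#'   residual variances).
#' @export
fit_lme_adjust <- function(values, covariates, subject_id, sex) {
  covariates <- as.data.frame(covariates)
  sex <- factor(as.character(sex), levels = c("men", "women"))
  if (any(is.na(sex))) stop("sex must be 'men' or 'women'", call. = FALSE)
  n <- length(values)
  stopifnot(nrow(covariates) == n, length(subject_id) == n, length(sex) == n)
  X <- covariate_matrix(covariates)
  kept <- complete.cases(X) & !is.na(values)
  if (sum(!kept) > 0)
    message(sum(!kept), " session(s) dropped for missing covariates/values")
  if (length(unique(subject_id[kept & sex == "men"])) < 2L ||
      length(unique(subject_id[kept & sex == "women"])) < 2L)
    stop("at least 2 subjects per sex are required", call. = FALSE)
  Xc <- scale(X[kept, , drop = FALSE], center = TRUE, scale = FALSE)
  Xc <- drop_constant_columns(Xc)
  df <- data.frame(y = values[kept], sex = sex[kept],
                   subject = factor(subject_id[kept]))
  df <- cbind(df, as.data.frame(Xc))
  nuisance <- colnames(Xc)
  fml <- as.formula(paste("y ~ sex +", paste(nuisance, collapse = " + "),
                          "+ (1 | subject)"))
  fit <- NULL; method <- "REML"
  fit <- tryCatch(lme4::lmer(fml, data = df, REML = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    method <- "ML"
    fit <- tryCatch(lme4::lmer(fml, data = df, REML = FALSE),
                    error = function(e) NULL)
  }
  if (is.null(fit)) {
    method <- "fixed"
    warning("mixed-model fit failed; falling back to fixed effects only")
    lmfit <- lm(as.formula(paste("y ~ sex +",
                                 paste(nuisance, collapse = " + "))), data = df)
    beta <- coef(lmfit)[nuisance]
    adj_kept <- df$y - as.numeric(Xc %*% beta)
    vc <- c(subject = 0, residual = summary(lmfit)$sigma^2)
    coefs <- coef(lmfit)
    fit <- lmfit
  } else {
    beta <- lme4::fixef(fit)[nuisance]
    blup <- lme4::ranef(fit)$subject
    b <- setNames(blup[["(Intercept)"]], rownames(blup))
    adj_kept <- df$y - as.numeric(Xc %*% beta) - b[as.character(df$subject)]
    vcm <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(subject = vcm$vcov[vcm$grp == "subject"],
            residual = vcm$vcov[vcm$grp == "Residual"])
    coefs <- lme4::fixef(fit)
  }
  adjusted <- rep(NA_real_, n)
  adjusted[kept] <- unname(adj_kept)
  structure(list(adjusted = adjusted, kept = kept, fit = fit,
                 method = method, coefficients = coefs, varcomp = vc),
            class = "adjusted_values")
}

# constant (zero-variance) covariate columns carry no adjustment information
# and break the fixed-effect fit; drop them silently
drop_constant_columns <- function(Xc) {
  keep <- apply(Xc, 2, function(v) var(v) > 0)
  if (!any(keep))
    stop("all covariates are constant; nothing to adjust for", call. = FALSE)
  Xc[, keep, drop = FALSE]
}

# numeric design matrix from a covariate data frame (two-level factors and
# characters coded 0/1; handedness coded R=0, L=1; names kept syntactic)
covariate_matrix <- function(covariates) {
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) return(v)
    v <- as.character(v)
    lev <- sort(unique(v[!is.na(v)]))
    if (identical(lev, c("L", "R")) || identical(lev, "R") ||
        identical(lev, "L"))
      return(as.numeric(v == "L"))
    if (length(lev) > 2)
      stop("covariate '", nm, "' has more than 2 levels; recode it",
           call. = FALSE)
    as.numeric(v == lev[length(lev)])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- make.names(names(covariates))
  X
}

#' @export
#' @method print adjusted_values
print.adjusted_values <- function(x, ...) {
  cat(sprintf("LME-adjusted values (%s): %d sessions kept\n", x$method,
              sum(x$kept)))
  cat(sprintf("  variance components: subject %.4g, residual %.4g\n",
              x$varcomp["subject"], x$varcomp["residual"]))
  invisible(x)
}

#' Two-sample sex contrast on adjusted values
#'
#' Two-sided pooled-variance (Student) t-test comparing women against men on
#' session-level adjusted values, with Bonferroni correction over the stated
#' family size. Negative t means women lower than men (men are the reference
#' group).
#'
#' @param adjusted An `adjusted_values` object or numeric vector.
#' @param sex Factor/character `men` / `women`, one per session.
#' @param m Bonferroni family size: 94 for a regional metric family, 3 for
#'   the global metrics (default 1 = no correction).
#' @return Object of class `sex_contrast`: list with `t` (positive when women
#'   higher), `df`, `p`, `p_bonf`, group `means`, `sds`, `n`.
#' @export
sex_ttest <- function(adjusted, sex, m = 1L) {
  y <- if (inherits(adjusted, "adjusted_values")) adjusted$adjusted else adjusted
  sex <- factor(as.character(sex), levels = c("men", "women"))
  keep <- !is.na(y) & !is.na(sex)
  y <- y[keep]; sex <- sex[keep]
  n1 <- sum(sex == "men"); n2 <- sum(sex == "women")
  if (n1 < 2L || n2 < 2L)
    stop("at least 2 sessions per sex are required", call. = FALSE)
  y1 <- y[sex == "men"]; y2 <- y[sex == "women"]
  res <- pooled_t(mean(y2), sd(y2), n2, mean(y1), sd(y1), n1)
  structure(list(t = res$t, df = res$df, p = res$p,
                 p_bonf = min(1, res$p * m), m = m,
                 means = c(men = mean(y1), women = mean(y2)),
                 sds = c(men = sd(y1), women = sd(y2)),
                 n = c(men = n1, women = n2)),
            class = "sex_contrast")
}

#' @export
#' @method print sex_contrast
print.sex_contrast <- function(x, ...) {
  cat(sprintf(
    "Sex contrast (women - men): t = %.3f, df = %d, p = %.3g, p_bonf = %.3g\n",
    x$t, x$df, x$p, x$p_bonf))
  cat(sprintf("  men %.4g +/- %.4g (n=%d), women %.4g +/- %.4g (n=%d)\n",
              x$means["men"], x$sds["men"], x$n["men"],
              x$means["women"], x$sds["women"], x$n["women"]))
  invisible(x)
}

pooled_t <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1 (the form used
#' for categorical demographic comparisons such as APOE4 carrier status or
#' handedness by sex).
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("a 2x2 table is required", call. = FALSE)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be nonnegative with positive total", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the 2x2 table", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-sample t-test from summary statistics
#'
#' Two-sided pooled-variance t-test computed from group means, SDs and sizes
#' (as printed in a demographics table).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  pooled_t(mean1, sd1, n1, mean2, sd2, n2)
}

#' Classify amyloid status per session
#'
#' A session is amyloid-positive when the composite SUVR of its matched
#' florbetapir PET exceeds 1.11 (strictly), negative at or below, and unknown
#' when no PET exists within the 1-year window of the MRI date. When a PET
#' table is supplied, the nearest qualifying PET scan of the same subject is
#' used.
#'
#' @param sessions Data frame with `mri_date`, and either `suvr` + `pet_date`
#'   columns or a `subject_id` to match against `pet_scans`.
#' @param pet_scans Optional data frame (`subject_id`, `pet_date`, `suvr`);
#'   when given, each session is matched to its nearest PET by date.
#' @param threshold SUVR positivity cutoff (default 1.11).
#' @param window_days Maximum MRI-PET gap (default 365).
#' @return Character vector, one of `"positive"`, `"negative"`, `"unknown"`
#'   per session.
#' @export
classify_amyloid <- function(sessions, pet_scans = NULL, threshold = 1.11,
                             window_days = 365) {
  mri <- as.Date(sessions$mri_date)
  if (is.null(pet_scans)) {
    suvr <- sessions$suvr
    pet <- as.Date(sessions$pet_date)
  } else {
    suvr <- rep(NA_real_, nrow(sessions))
    pet <- rep(as.Date(NA), nrow(sessions))
    for (i in seq_len(nrow(sessions))) {
      cand <- pet_scans[pet_scans$subject_id == sessions$subject_id[i], ]
      if (!nrow(cand)) next
      gaps <- abs(as.numeric(as.Date(cand$pet_date) - mri[i]))
      j <- which.min(gaps)
      suvr[i] <- cand$suvr[j]
      pet[i] <- as.Date(cand$pet_date[j])
    }
  }
  if (any(suvr < 0, na.rm = TRUE))
    stop("negative SUVR encountered", call. = FALSE)
  gap <- abs(as.numeric(pet - mri))
  status <- rep("unknown", length(mri))
  known <- !is.na(suvr) & !is.na(gap) & gap <= window_days
  status[known & suvr > threshold] <- "positive"
  status[known & suvr <= threshold] <- "negative"
  status
}

#' Eligibility filter for the analysis cohort
#'
#' Retains sessions with age <= 80 years and ADAS-Cog <= 10 (both bounds
#' inclusive; exclusion requires strictly exceeding them), producing an
#' age- and cognition-matched sample, and logs counts per exclusion reason.
#'
#' @param cohort An `fc_cohort` or a sessions data frame with `age` and
#'   `adas_cog` columns.
#' @param age_max Maximum age retained (default 80).
#' @param adas_max Maximum ADAS-Cog retained (default 10).
#' @return List with `cohort` (filtered), `log` (named counts: n_in, n_out,
#'   excluded_age, excluded_adas).
#' @export
filter_eligibility <- function(cohort, age_max = 80, adas_max = 10) {
  ses <- if (inherits(cohort, "fc_cohort")) cohort$sessions else cohort
  if (is.null(ses$age) || is.null(ses$adas_cog))
    stop("age and adas_cog are required", call. = FALSE)
  bad_age <- ses$age > age_max
  bad_adas <- ses$adas_cog > adas_max
  keep <- !bad_age & !bad_adas
  log <- c(n_in = nrow(ses), n_out = sum(keep),
           excluded_age = sum(bad_age), excluded_adas = sum(bad_adas))
  if (inherits(cohort, "fc_cohort")) {
    cohort$sessions <- ses[keep, , drop = FALSE]
    keep_subj <- cohort$subjects$subject_id %in% cohort$sessions$subject_id
    cohort$subjects <- cohort$subjects[keep_subj, , drop = FALSE]
    out <- cohort
  } else {
    out <- ses[keep, , drop = FALSE]
  }
  list(cohort = out, log = log)
}

#' Two-way ANOVA with interaction (Type II sums of squares)
#'
#' Assesses the main effects of two factors (e.g. sex and APOE4 or amyloid
#' status) and their interaction on a global network metric, using Type II
#' sums of squares appropriate for unbalanced designs.
#'
#' @param y Numeric response (e.g. an adjusted global metric).
#' @param factor_a,factor_b Factors (coerced); at least 2 levels each and
#'   every crossed cell that exists must be non-empty.
#' @return List with `p` (named: factor_a, factor_b, interaction) and
#'   `table` (the ANOVA table).
#' @export
two_way_anova <- function(y, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  if (any(table(a) == 0) || any(table(b) == 0))
    stop("empty factor level", call. = FALSE)
  fit <- lm(y ~ a * b)
  tab <- car::Anova(fit, type = 2)
  p <- tab[["Pr(>F)"]]
  names(p) <- rownames(tab)
  list(p = c(factor_a = p[["a"]], factor_b = p[["b"]],
             interaction = p[["a:b"]]),
       table = tab)
}

#' Per-group regression and slope-difference test
#'
#' Ordinary least-squares regression of a cognition score on a network metric
#' within each group, with the Pearson correlation and its p-value, plus a
#' two-sided t-test for the difference of slopes between the two groups,
#' `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)` with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param x Numeric predictor (metric), `y` numeric response (score).
#' @param y Numeric response.
#' @param group Two-level factor/character.
#' @return List with `groups` (data frame: group, n, slope, se, intercept, r,
#'   p) and `slope_diff` (list: estimate, t, df, p).
#' @export
groupwise_regression_slope_test <- function(x, y, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly 2 groups are required", call. = FALSE)
  per <- lapply(levels(g), function(lev) {
    xi <- x[g == lev]; yi <- y[g == lev]
    ok <- !is.na(xi) & !is.na(yi)
    xi <- xi[ok]; yi <- yi[ok]
    if (length(xi) < 3L)
      stop("at least 3 points per group are required", call. = FALSE)
    if (var(xi) == 0)
      stop("zero variance in x within group ", lev, call. = FALSE)
    fit <- lm(yi ~ xi)
    sm <- summary(fit)
    ct <- cor.test(xi, yi)
    data.frame(group = lev, n = length(xi),
               slope = unname(coef(fit)["xi"]),
               se = sm$coefficients["xi", "Std. Error"],
               intercept = unname(coef(fit)["(Intercept)"]),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  se2 <- tab$se^2
  est <- tab$slope[1] - tab$slope[2]
  t <- est / sqrt(sum(se2))
  dfs <- tab$n - 2
  df <- sum(se2)^2 / sum(se2^2 / dfs)
  list(groups = tab,
       slope_diff = list(estimate = est, t = t, df = df,
                         p = 2 * pt(-abs(t), df)))
}

#' Macroarea assignment for atlas regions
#'
#' Maps each region label to one of the six anatomical macroareas
#' (prefrontal, other frontal, occipital, temporal, parietal, central
#' structures) via a mapping table.
#'
#' @param region_labels Character vector of region labels.
#' @param mapping Data frame with columns `region`, `macroarea`; default is
#'   the mapping shipped with the package (see [macroarea_mapping()]).
#' @return Named character vector: macroarea per region.
#' @export
macroarea_assign <- function(region_labels, mapping = macroarea_mapping()) {
  idx <- match(region_labels, mapping$region)
  if (anyNA(idx))
    stop("unmapped region(s): ",
         paste(region_labels[is.na(idx)], collapse = ", "), call. = FALSE)
  setNames(mapping$macroarea[idx], region_labels)
}

#' Shipped macroarea mapping
#'
#' The packaged lobar grouping of the 94 cerebral regions of the revised
#' automated anatomical labelling atlas into six macroareas. The grouping
#' approximates standard lobar anatomy and is editable configuration (pass
#' your own table to [macroarea_assign()]), not a canonical atlas product.
#'
#' @return Data frame with columns `region`, `macroarea` (94 rows, 6 distinct
#'   macroareas).
#' @export
macroarea_mapping <- function() {
  path <- system.file("extdata", "macroareas_aal94.csv", package = "fcsex")
  read.csv(path, stringsAsFactors = FALSE)
}
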