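make_sessions <- function(n_subj_per_sex = 20, sessions = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_subj_per_sex
  subj <- sprintf("s%03d", seq_len(n))
  sex <- rep(c("men", "women"), each = n_subj_per_sex)
  data.frame(
    subject_id = rep(subj, each = sessions),
    sex = rep(sex, each = sessions),
    age = rep(rnorm(n, 72, 4), each = sessions),
    education = rep(round(rnorm(n, 17, 2)), each = sessions),
    handedness = rep(sample(c("R", "L"), n, TRUE, c(0.9, 0.1)),
                     each = sessions),
    apoe4 = rep(rbinom(n, 1, 0.3), each = sessions),
    stringsAsFactors = FALSE)
}

test_that("null adjustment leaves values essentially unchanged", {
  ses <- make_sessions(seed = 2)
  set.seed(3)
  y <- rnorm(nrow(ses))
  adj <- suppressMessages(
    fit_lme_adjust(y, ses[, c("age", "education", "handedness", "apoe4")],
                   ses$subject_id, ses$sex))
  # no covariate effects, no subject variance: adjustment is small relative
  # to the spread of the data (finite-sample variance estimates still move
  # individual values a little)
  expect_lt(max(abs(adj$adjusted - y)), sd(y))
  expect_gt(cor(adj$adjusted, y), 0.95)
  expect_lt(abs(mean(adj$adjusted - y)), 0.1)
})

test_that("adjustment removes an implanted age effect", {
  ses <- make_sessions(n_subj_per_sex = 60, seed = 4)
  set.seed(5)
  age_c <- ses$age - mean(ses$age)
  subj_eff <- rnorm(length(unique(ses$subject_id)), 0, 0.5)
  names(subj_eff) <- unique(ses$subject_id)
  y <- 2 * age_c + subj_eff[ses$subject_id] +
    0.3 * (ses$sex == "women") + rnorm(nrow(ses), 0, 0.5)
  adj <- suppressMessages(
    fit_lme_adjust(y, ses[, c("age", "education", "handedness", "apoe4")],
                   ses$subject_id, ses$sex))
  fit <- lm(adj$adjusted ~ age_c)
  slope_se <- summary(fit)$coefficients["age_c", "Std. Error"]
  expect_lt(abs(coef(fit)["age_c"]), 3 * slope_se)
  # nuisance orthogonality of adjusted values
  expect_lt(abs(cor(adj$adjusted, age_c)), 0.05)
})

test_that("repeated sessions yield a positive subject variance component", {
  ses <- make_sessions(n_subj_per_sex = 30, sessions = 3, seed = 6)
  set.seed(7)
  subj_eff <- rnorm(length(unique(ses$subject_id)), 0, 1)
  names(subj_eff) <- unique(ses$subject_id)
  y <- subj_eff[ses$subject_id] + rnorm(nrow(ses), 0, 0.3)
  adj <- suppressMessages(
    fit_lme_adjust(y, ses[, c("age", "education", "handedness", "apoe4")],
                   ses$subject_id, ses$sex))
  expect_gt(adj$varcomp["subject"], 0)
  # within-subject residual spread shrinks after intercept removal
  within_raw <- mean(tapply(y, ses$subject_id, var))
  between_adj <- var(tapply(adj$adjusted, ses$subject_id, mean))
  expect_lt(between_adj, var(tapply(y, ses$subject_id, mean)))
})

test_that("sex t-test direction and Bonferroni arithmetic are correct", {
  ses <- make_sessions(n_subj_per_sex = 50, seed = 8)
  set.seed(9)
  delta <- 0.8
  y <- rnorm(nrow(ses)) - delta * (ses$sex == "women")
  ct <- sex_ttest(y, ses$sex, m = 3)
  expect_lt(ct$t, 0)              # women lower -> negative t
  expect_equal(ct$p_bonf, min(1, ct$p * 3))
  expect_gte(ct$p_bonf, ct$p)
  # trivially: raw p 0.0005 with m = 94
  expect_equal(min(1, 0.0005 * 94), 0.047)
})

test_that("chi-square matches the textbook closed form", {
  tab <- matrix(c(12, 36, 27, 47), 2, byrow = TRUE)
  res <- chi_square_2x2(tab)
  # closed form: n(ad - bc)^2 / (row/col products)
  a <- 12; b <- 36; c <- 27; d <- 47; n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$df, 1)
  # perfect independence
  res0 <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("summary t-test equals the raw-data pooled t-test", {
  set.seed(10)
  x <- rnorm(40, 1, 2); y <- rnorm(60, 1.5, 2)
  res <- ttest_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 60)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(res$t), abs(unname(ref$statistic)), tolerance = 1e-10)
  res2 <- ttest_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(res2$p, 1)
})

test_that("amyloid classification follows threshold and window rules", {
  ses <- data.frame(
    mri_date = as.Date("2016-01-01") + c(0, 0, 0, 0, 0),
    suvr = c(1.20, 1.11, 1.50, 0.95, NA),
    pet_date = as.Date("2016-01-01") + c(100, -30, 400, 364, NA))
  st <- classify_amyloid(ses)
  expect_equal(st, c("positive", "negative", "unknown", "negative",
                     "unknown"))
  expect_error(classify_amyloid(data.frame(mri_date = as.Date("2016-01-01"),
                                           suvr = -0.2,
                                           pet_date = as.Date("2016-01-01"))),
               "negative SUVR")
})

test_that("nearest qualifying PET is chosen when several exist", {
  ses <- data.frame(subject_id = "s1", mri_date = as.Date("2016-06-01"))
  pet <- data.frame(subject_id = "s1",
                    pet_date = as.Date(c("2016-01-01", "2016-05-20",
                                         "2017-09-01")),
                    suvr = c(1.00, 1.30, 1.00))
  expect_equal(classify_amyloid(ses, pet_scans = pet), "positive")
})

test_that("eligibility filtering uses strict exceedance", {
  ses <- data.frame(subject_id = c("a", "b", "c", "d"),
                    age = c(81, 72, 80, 70),
                    adas_cog = c(5, 11, 10, 5))
  res <- filter_eligibility(ses)
  expect_equal(res$cohort$subject_id, c("c", "d"))
  expect_equal(unname(res$log["excluded_age"]), 1)
  expect_equal(unname(res$log["excluded_adas"]), 1)
})

test_that("two-way ANOVA is calibrated under the null and detects effects", {
  set.seed(11)
  # null: both factors inert
  ps <- replicate(200, {
    a <- sample(rep(c("m", "w"), c(30, 40)))
    b <- sample(rep(c("pos", "neg"), c(35, 35)))
    unname(two_way_anova(rnorm(70), a, b)$p["factor_a"])
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  # strong sex effect only
  hits <- replicate(50, {
    a <- sample(rep(c("m", "w"), c(60, 60)))
    b <- sample(rep(c("pos", "neg"), c(55, 65)))
    y <- rnorm(120) + 1.5 * (a == "w")
    p <- two_way_anova(y, a, b)$p
    p[["factor_a"]] < 0.05 & p[["factor_b"]] > 0.05 & p[["interaction"]] > 0.05
  })
  expect_gte(mean(hits), 0.8)
  expect_error(two_way_anova(rnorm(5), rep("a", 5), rep(c("x", "y"), c(2, 3))),
               "2 levels")
})

test_that("balanced designs give identical Type I and Type II tables", {
  set.seed(12)
  a <- rep(c("m", "w"), each = 40)
  b <- rep(rep(c("pos", "neg"), each = 20), 2)
  y <- rnorm(80) + (a == "w") * 0.5
  t2 <- two_way_anova(y, a, b)$table
  t1 <- anova(lm(y ~ factor(a) * factor(b)))
  expect_equal(t2["a", "Sum Sq"], t1["factor(a)", "Sum Sq"], tolerance = 1e-10)
  expect_equal(t2["b", "Sum Sq"], t1["factor(b)", "Sum Sq"], tolerance = 1e-10)
})

test_that("slope-difference test matches the pooled interaction model", {
  set.seed(13)
  n <- 150
  g <- rep(c("men", "women"), each = n)
  x <- rnorm(2 * n)
  y <- ifelse(g == "men", 1 + 0.5 * x, 1 - 0.5 * x) + rnorm(2 * n, 0, 1)
  res <- groupwise_regression_slope_test(x, y, g)
  fit <- lm(y ~ x * g)
  t_int <- summary(fit)$coefficients["x:gwomen", "t value"]
  expect_equal(abs(res$slope_diff$t), abs(t_int), tolerance = 0.05)
  expect_lt(res$slope_diff$p, 0.001)
  expect_error(groupwise_regression_slope_test(rep(1, 10), rnorm(10),
                                               rep(c("a", "b"), 5)),
               "zero variance")
})

test_that("macroarea mapping partitions the 94 regions into 6 areas", {
  map <- macroarea_mapping()
  expect_equal(nrow(map), 94)
  expect_equal(length(unique(map$macroarea)), 6)
  expect_false(anyDuplicated(map$region) > 0)
  assign <- macroarea_assign(region_labels(94))
  expect_length(assign, 94)
  expect_equal(sum(table(assign)), 94)
  expect_error(macroarea_assign(c("Not_A_Region_L")), "unmapped")
})
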