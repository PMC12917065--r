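test_that("the log-slope model recovers a 2-fold arm ratio", {
  set.seed(71)
  p <- synthetic_defaults()
  p$beta_median_naive <- 0.008; p$beta_median_nat <- 0.016   # true ratio 2
  tab <- quick_clinical_cohort(30, 30, p)
  m <- fit_log_slope_model(tab)
  expect_gt(m$treatment_ratio, 1.5)
  expect_lt(m$treatment_ratio, 2.7)
  expect_equal(m$n_used + length(m$excluded_nonpositive), nrow(tab))
})

test_that("the treatment contrast is invariant to rescaling age", {
  set.seed(72)
  tab <- quick_clinical_cohort(25, 25)
  m1 <- fit_log_slope_model(tab)
  tab2 <- tab; tab2$age <- tab2$age / 10
  m2 <- fit_log_slope_model(tab2)
  expect_equal(m2$coefficients["treatmentNAT"],
               m1$coefficients["treatmentNAT"], tolerance = 1e-10)
})

test_that("non-positive slopes are excluded and reported, or shifted", {
  set.seed(73)
  tab <- quick_clinical_cohort(20, 20)
  tab$beta[c(3, 7)] <- c(-0.004, 0)
  m <- fit_log_slope_model(tab)
  expect_setequal(m$excluded_nonpositive, tab$subject_id[c(3, 7)])
  expect_equal(m$n_used, 38L)
  ms <- fit_log_slope_model(tab, policy = "shift", shift = 0.01)
  expect_equal(ms$n_used, 40L)
  expect_length(ms$excluded_nonpositive, 0L)
})

test_that("heterogeneity contrast detects an arm SD shift and calibrates", {
  # arm-specific cancer dispersion: naive SD ~ 26, NAT SD ~ 13 per quadrat
  gen_summaries <- function(theta_by_arm, n_per_arm = 20) {
    treat <- rep(c("naive", "NAT"), each = n_per_arm)
    rows <- lapply(seq_along(treat), function(i) {
      qc <- simulate_quadrat_counts(200, alpha = log(2.4), beta = 0.01,
                                    cancer_theta = theta_by_arm[treat[i]])
      data.frame(subject_id = sprintf("P%03d", i),
                 quadrat_sd_cancer = sd(qc$cancer))
    })
    do.call(rbind, rows)
  }
  set.seed(74)
  treat <- rep(c("naive", "NAT"), each = 20)
  clin <- simulate_clinical_and_survival(
    sprintf("P%03d", 1:40), treat, rlnorm(40, log(0.012), 0.6))
  s <- gen_summaries(c(naive = 1.2, NAT = 5.6))
  m <- fit_heterogeneity_model(s, clin)
  expect_lt(m$treatment_effect, 0)
  expect_gt(abs(m$treatment_effect), 8)
  expect_lt(abs(m$treatment_effect), 18)

  # null: identical arms -> effect within 2 SE of zero in >= 90% of runs
  # (replicates whose categorical design happens to be collinear are
  # refused by the model and dropped here; that is orthogonal to the
  # treatment term's calibration)
  set.seed(75)
  inside <- rep(NA, 200)
  for (r in seq_len(200)) {
    s0 <- gen_summaries(c(naive = 1.2, NAT = 1.2), n_per_arm = 15)
    clin0 <- simulate_clinical_and_survival(
      sprintf("P%03d", 1:30), rep(c("naive", "NAT"), each = 15),
      rlnorm(30, log(0.012), 0.6))
    m0 <- tryCatch(fit_heterogeneity_model(s0, clin0),
                   error = function(e) NULL)
    if (!is.null(m0)) inside[r] <- abs(m0$treatment_effect) <= 2 * m0$se
  }
  expect_gt(sum(!is.na(inside)), 150)
  expect_gte(mean(inside, na.rm = TRUE), 0.9)
})

test_that("single-level covariates are dropped with a warning", {
  set.seed(76)
  tab <- quick_clinical_cohort(15, 15)
  tab$grade <- "G2"
  tab$quadrat_sd_cancer <- rnorm(30, 20, 3)
  clin <- tab[, c("subject_id", "treatment", "sex", "age", "grade",
                  "stage", "time", "event")]
  expect_warning(m <- fit_heterogeneity_model(
    tab[, c("subject_id", "quadrat_sd_cancer")], clin), "grade")
  expect_true(is.finite(m$p_value))
})

test_that("with no between-subject variance the GLMM collapses to the pooled GLM", {
  set.seed(77)
  treat <- rep(c("naive", "NAT"), each = 6)
  rows <- lapply(seq_along(treat), function(i) {
    beta <- 0.005 + 0.002 * (treat[i] == "NAT")
    qc <- simulate_quadrat_counts(150, alpha = log(2.4), beta = beta)
    qc$subject_id <- sprintf("Z%02d", i); qc
  })
  df <- do.call(rbind, rows)
  clin <- data.frame(subject_id = unique(df$subject_id), treatment = treat)
  gl <- suppressWarnings(fit_nb_glmm(df, clin))
  pooled_df <- merge(df, clin, by = "subject_id")
  pooled_df$treatment <- factor(pooled_df$treatment,
                                levels = c("naive", "NAT"))
  pooled <- MASS::glm.nb(cd8 ~ cancer * treatment, data = pooled_df)
  expect_lt(abs(gl$beta_cancer["est"] - coef(pooled)["cancer"]) /
            abs(coef(pooled)["cancer"]), 0.02)
  expect_lt(abs(gl$beta_interaction["est"] -
                coef(pooled)["cancer:treatmentNAT"]) /
            abs(coef(pooled)["cancer:treatmentNAT"]), 0.02)
})

test_that("Laplace and adaptive quadrature agree on a small fixture", {
  set.seed(78)
  treat <- rep(c("naive", "NAT"), each = 8)
  rows <- lapply(seq_along(treat), function(i) {
    beta <- 0.005 + 0.002 * (treat[i] == "NAT")
    qc <- simulate_quadrat_counts(100, alpha = log(2.4) + rnorm(1, 0, 0.5),
                                  beta = beta)
    qc$subject_id <- sprintf("Q%02d", i); qc
  })
  df <- do.call(rbind, rows)
  clin <- data.frame(subject_id = unique(df$subject_id), treatment = treat)
  lap <- fit_nb_glmm(df, clin, method = "laplace")
  agq <- fit_nb_glmm(df, clin, method = "agq", nodes = 7)
  rel <- function(a, b) abs(a - b) / abs(b)
  expect_lt(rel(agq$beta_cancer["est"], lap$beta_cancer["est"]), 0.01)
  expect_lt(rel(agq$beta_interaction["est"],
                lap$beta_interaction["est"]), 0.01)
  expect_error(fit_nb_glmm(df, clin, method = "agq", nodes = 3), "nodes")
})
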