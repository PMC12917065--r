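# Cohort-level contrasts between treatment arms: OLS on log slopes,
# OLS on quadrat-wise heterogeneity, and the NB mixed model with the
# cancer-count x treatment interaction.

# Drop covariates with a single observed level (degenerate in simulation
# subsets); returns the pruned term vector, warning for each drop.
prune_constant_terms <- function(df, terms) {
  keep <- vapply(terms, function(tm) {
    v <- df[[tm]]
    ok <- length(unique(v[!is.na(v)])) > 1L
    if (!ok) warning("covariate '", tm, "' has a single level; dropped")
    ok
  }, logical(1))
  terms[keep]
}

check_full_rank <- function(fit) {
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased))
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  invisible(fit)
}

#' Treatment contrast of log slopes, covariate-adjusted
#'
#' Ordinary least squares of `log(beta)` on treatment, sex, age (linear,
#' years), tumor grade and tumor stage. The slope distribution is
#' right-skewed, hence the log transform; because a slope can be
#' non-positive, the default policy excludes such subjects and reports
#' them (`policy = "exclude"`). A shifted log `log(beta + shift)` is
#' available as a sensitivity analysis (`policy = "shift"`).
#'
#' The treatment coefficient is a log-ratio: `exp(coef)` is the implied
#' multiplicative ratio of NAT over naive slopes.
#'
#' @param table `cohort_table`.
#' @param policy how to handle beta <= 0: `"exclude"` (default) or
#'   `"shift"`.
#' @param shift constant added under `policy = "shift"`.
#' @return `log_slope_model`: `coefficients`, `se`, `p_values`, `n_used`,
#'   `excluded_nonpositive`, `treatment_ratio`, and the underlying `lm`
#'   fit.
#' @export
fit_log_slope_model <- function(table, policy = c("exclude", "shift"),
                                shift = 0.01) {
  policy <- match.arg(policy)
  df <- as.data.frame(table)
  excluded <- character(0)
  if (policy == "exclude") {
    bad <- df$beta <= 0
    excluded <- df$subject_id[bad]
    df <- df[!bad, , drop = FALSE]
    df$log_beta <- log(df$beta)
  } else {
    if (any(df$beta + shift <= 0))
      stop("shift too small: beta + shift must be positive")
    df$log_beta <- log(df$beta + shift)
  }
  for (arm in c("naive", "NAT"))
    if (sum(df$treatment == arm) < 2L)
      stop("need >= 2 subjects with positive slope in arm '", arm, "'")
  terms <- prune_constant_terms(df, c("treatment", "sex", "age", "grade",
                                      "stage"))
  fml <- stats::reformulate(terms, response = "log_beta")
  fit <- stats::lm(fml, data = droplevels(df))
  check_full_rank(fit)
  cf <- summary(fit)$coefficients
  structure(list(
    coefficients = cf[, 1], se = cf[, 2], p_values = cf[, 4],
    n_used = nrow(df), excluded_nonpositive = excluded,
    treatment_ratio = unname(exp(cf["treatmentNAT", 1])),
    fit = fit
  ), class = "log_slope_model")
}

#' @export
print.log_slope_model <- function(x, ...) {
  cat(sprintf(
    "log-slope model (n = %d, %d non-positive slope(s) excluded)\n",
    x$n_used, length(x$excluded_nonpositive)))
  cat(sprintf("  treatment (NAT vs naive): %.3f on the log scale => slope ratio %.2f, p = %.3g\n",
              x$coefficients["treatmentNAT"], x$treatment_ratio,
              x$p_values["treatmentNAT"]))
  invisible(x)
}

#' Treatment contrast of intratumoral heterogeneity
#'
#' OLS of the per-subject quadrat-wise SD of cancer counts on treatment,
#' sex, age, grade and stage. A negative treatment effect means the NAT
#' arm is more homogeneous (lower SD of cancer counts per quadrat).
#'
#' @param summaries `data.frame` of per-subject quadrat summaries
#'   (rbind of [quadrat_summaries()] rows).
#' @param clinical clinical table.
#' @return `heterogeneity_model`: `treatment_effect` (counts per
#'   quadrat), `se`, `p_value`, `n_used`, and the `lm` fit.
#' @export
fit_heterogeneity_model <- function(summaries, clinical) {
  df <- merge(summaries, clinical, by = "subject_id")
  df <- as_clinical_factors(df)
  for (arm in c("naive", "NAT"))
    if (sum(df$treatment == arm) < 2L)
      stop("need >= 2 subjects in arm '", arm, "'")
  terms <- prune_constant_terms(df, c("treatment", "sex", "age", "grade",
                                      "stage"))
  fit <- stats::lm(stats::reformulate(terms, "quadrat_sd_cancer"),
                   data = droplevels(df))
  check_full_rank(fit)
  cf <- summary(fit)$coefficients
  structure(list(
    treatment_effect = unname(cf["treatmentNAT", 1]),
    se = unname(cf["treatmentNAT", 2]),
    p_value = unname(cf["treatmentNAT", 4]),
    n_used = nrow(df), fit = fit
  ), class = "heterogeneity_model")
}

#' @export
print.heterogeneity_model <- function(x, ...) {
  cat(sprintf(
    "heterogeneity model (n = %d): NAT effect on quadrat-wise cancer SD = %.2f (SE %.2f), p = %.3g\n",
    x$n_used, x$treatment_effect, x$se, x$p_value))
  invisible(x)
}

#' Pool quadrat counts with treatment labels
#'
#' @keywords internal
pooled_quadrat_frame <- function(grids, clinical) {
  if (is.data.frame(grids)) {
    df <- grids[, c("subject_id", "cancer", "cd8")]
  } else {
    rows <- lapply(grids, function(g) {
      qc <- quadrat_counts(g)
      qc$subject_id <- g$subject_id
      qc
    })
    df <- do.call(rbind, rows)
  }
  df <- merge(df, clinical[, c("subject_id", "treatment")], by = "subject_id")
  df$treatment <- factor(df$treatment, levels = c("naive", "NAT"))
  df$subject_id <- factor(df$subject_id)
  df
}

#' Negative-binomial mixed model of CD8 counts with treatment interaction
#'
#' Cohort-level model of the pooled active-quadrat counts:
#' \deqn{\mathrm{cd8}_{ij} \sim \mathrm{NB}(\mu_{ij}, \theta), \quad
#'   \log \mu_{ij} = \beta_0 + b_i + \beta_c\,\mathrm{cancer}_{ij} +
#'   \beta_t\,\mathrm{NAT}_i + \beta_{ct}\,\mathrm{cancer}_{ij}\,\mathrm{NAT}_i,}
#' with a subject-level random intercept \eqn{b_i \sim N(0, \sigma_b^2)}.
#' The interaction \eqn{\beta_{ct}} is the treatment effect on the
#' spatial-coupling slope: `exp(100 * beta_interaction)` is the ratio of
#' the NAT over naive 100-cancer-cell fold changes.
#'
#' `method = "laplace"` fits by glmmTMB (Laplace approximation, theta
#' free). `method = "agq"` is a verification mode: it refits by adaptive
#' Gauss-Hermite quadrature (lme4, `nAGQ = nodes`) with theta fixed at
#' the Laplace estimate, since no installed engine offers AGQ with a free
#' NB size parameter.
#'
#' @param grids list of `quadrat_grid`, or a pre-pooled `data.frame`
#'   with columns `subject_id`, `cancer`, `cd8` (active quadrats only).
#' @param clinical clinical table with `treatment`.
#' @param method `"laplace"` (default) or `"agq"`.
#' @param nodes quadrature nodes for `method = "agq"` (>= 5).
#' @return `nb_glmm_result`: fixed effects `beta_cancer`, `beta_treat`,
#'   `beta_interaction` with SEs and Wald p-values, `ri_sd`, `theta`,
#'   `converged`, `n_quadrats`, `n_subjects`, and the engine fit.
#' @export
fit_nb_glmm <- function(grids, clinical, method = c("laplace", "agq"),
                        nodes = 7L) {
  method <- match.arg(method)
  df <- pooled_quadrat_frame(grids, clinical)
  n_fixed <- 4L
  if (nrow(df) < 10L * n_fixed)
    stop("too few pooled quadrats (", nrow(df), ") for ", n_fixed,
         " fixed effects")
  for (arm in c("naive", "NAT"))
    if (length(unique(df$subject_id[df$treatment == arm])) < 2L)
      stop("need >= 2 subjects per treatment arm")

  lap <- glmmTMB::glmmTMB(
    cd8 ~ cancer * treatment + (1 | subject_id),
    family = glmmTMB::nbinom2(), data = df)
  conv <- isTRUE(lap$fit$convergence == 0) &&
    isTRUE(lap$sdr$pdHess)
  if (!conv)
    warning("mixed-model fit did not converge cleanly (optimizer code ",
            lap$fit$convergence, ", pdHess = ", lap$sdr$pdHess, ")")
  theta_hat <- glmmTMB::sigma(lap)

  if (method == "laplace") {
    cf <- summary(lap)$coefficients$cond
    ri_sd <- sqrt(glmmTMB::VarCorr(lap)$cond$subject_id[1, 1])
    engine_fit <- lap
  } else {
    if (nodes < 5L) stop("verification mode requires >= 5 quadrature nodes")
    agq <- lme4::glmer(
      cd8 ~ cancer * treatment + (1 | subject_id), data = df,
      family = MASS::negative.binomial(theta = theta_hat),
      nAGQ = as.integer(nodes),
      control = lme4::glmerControl(calc.derivs = FALSE))
    cf <- summary(agq)$coefficients
    ri_sd <- sqrt(unname(lme4::VarCorr(agq)$subject_id[1, 1]))
    engine_fit <- agq
    conv <- conv && length(agq@optinfo$conv$lme4) == 0L
  }
  pick <- function(nm) {
    i <- match(nm, rownames(cf))
    c(est = cf[i, 1], se = cf[i, 2],
      p = 2 * stats::pnorm(-abs(cf[i, 1] / cf[i, 2])))
  }
  structure(list(
    beta_cancer = pick("cancer"),
    beta_treat = pick("treatmentNAT"),
    beta_interaction = pick("cancer:treatmentNAT"),
    intercept = pick("(Intercept)"),
    ri_sd = ri_sd, theta = theta_hat,
    method = method, converged = conv,
    n_quadrats = nrow(df), n_subjects = nlevels(df$subject_id),
    fit = engine_fit
  ), class = "nb_glmm_result")
}

#' @export
print.nb_glmm_result <- function(x, ...) {
  cat(sprintf("NB GLMM (%s; %d subjects, %d quadrats)%s\n", x$method,
              x$n_subjects, x$n_quadrats,
              if (x$converged) "" else "  [NOT converged]"))
  row <- function(nm, v) cat(sprintf(
    "  %-18s %9.5f (SE %.5f), p = %.3g\n", nm, v["est"], v["se"], v["p"]))
  row("cancer", x$beta_cancer)
  row("treatment (NAT)", x$beta_treat)
  row("cancer x NAT", x$beta_interaction)
  cat(sprintf("  random-intercept SD %.3f, theta %.3f\n", x$ri_sd, x$theta))
  invisible(x)
}

#' JSON-ready summary of a cohort model
#'
#' @param x a `log_slope_model`, `heterogeneity_model` or
#'   `nb_glmm_result`.
#' @return plain list of numeric summaries.
#' @export
model_report <- function(x) {
  if (inherits(x, "log_slope_model"))
    return(list(model = "log_slope",
                coefficients = as.list(x$coefficients),
                p_values = as.list(x$p_values),
                treatment_ratio = x$treatment_ratio, n_used = x$n_used,
                excluded_nonpositive = x$excluded_nonpositive))
  if (inherits(x, "heterogeneity_model"))
    return(list(model = "heterogeneity",
                treatment_effect = x$treatment_effect, se = x$se,
                p_value = x$p_value, n_used = x$n_used))
  if (inherits(x, "nb_glmm_result"))
    return(list(model = "nb_glmm", method = x$method,
                beta_cancer = unname(x$beta_cancer["est"]),
                beta_treat = unname(x$beta_treat["est"]),
                beta_interaction = unname(x$beta_interaction["est"]),
                ri_sd = x$ri_sd, theta = x$theta,
                converged = x$converged))
  stop("unsupported model object")
}
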