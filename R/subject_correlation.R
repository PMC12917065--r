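#' Per-subject negative-binomial slope of CD8 on cancer quadrat counts
#'
#' Fits, over the active quadrats of one subject, the log-link
#' negative-binomial GLM
#' \deqn{E[\mathrm{cd8}] = \exp(\alpha + \beta \cdot \mathrm{cancer}),}
#' with the NB size parameter \eqn{\theta} estimated by maximum likelihood
#' alongside the coefficients. The slope \eqn{\beta} is the subject's
#' spatial-coupling statistic: via the log link, an increase of n cancer
#' cells in a quadrat multiplies the expected CD8 count by
#' \eqn{\exp(n\beta)} (see [fold_change()]).
#'
#' When the ML estimate of \eqn{\theta} diverges (the data are effectively
#' Poisson, variance ~ mean) the fit falls back to a Poisson GLM and is
#' flagged via `family = "poisson"`, with `theta = Inf`.
#'
#' @param grid `quadrat_grid` (or a `data.frame` with `cancer` and `cd8`
#'   count columns already restricted to active quadrats).
#' @param theta_divergence theta above which the NB fit is treated as
#'   Poisson-limit and refit as Poisson (default 1e4).
#' @return `slope_result`: `subject_id`, `alpha`, `beta`, `beta_se`,
#'   `theta`, `n_quadrats`, `converged`, `family`.
#' @export
fit_subject_glm <- function(grid, theta_divergence = 1e4) {
  if (inherits(grid, "quadrat_grid")) {
    qc <- quadrat_counts(grid)
    subject_id <- grid$subject_id
  } else {
    qc <- grid
    subject_id <- if (!is.null(qc$subject_id)) as.character(qc$subject_id[1])
                  else NA_character_
  }
  if (nrow(qc) < 2L)
    stop("need at least 2 active quadrats to fit a slope")
  if (length(unique(qc$cancer)) < 2L)
    stop("degenerate design: cancer counts are constant across quadrats")

  res <- list(subject_id = subject_id, alpha = NA_real_, beta = NA_real_,
              beta_se = NA_real_, theta = NA_real_,
              n_quadrats = nrow(qc), converged = FALSE, family = "nb")
  theta_limit_hit <- FALSE
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(cd8 ~ cancer, data = qc), error = function(e) e),
    warning = function(w) {
      if (grepl("iteration limit|theta", conditionMessage(w)))
        theta_limit_hit <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  use_poisson <- inherits(fit, "error") ||
    (!inherits(fit, "error") && (fit$theta > theta_divergence ||
                                 (theta_limit_hit && fit$theta > 100)))
  if (use_poisson) {
    pfit <- tryCatch(
      suppressWarnings(stats::glm(cd8 ~ cancer, data = qc,
                                  family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(pfit) || !pfit$converged) {
      res$converged <- FALSE
      return(structure(res, class = "slope_result"))
    }
    cf <- summary(pfit)$coefficients
    res$alpha <- cf["(Intercept)", 1]; res$beta <- cf["cancer", 1]
    res$beta_se <- cf["cancer", 2]
    res$theta <- Inf; res$family <- "poisson"; res$converged <- TRUE
    return(structure(res, class = "slope_result"))
  }
  cf <- summary(fit)$coefficients
  res$alpha <- cf["(Intercept)", 1]; res$beta <- cf["cancer", 1]
  res$beta_se <- cf["cancer", 2]
  res$theta <- fit$theta
  res$converged <- isTRUE(fit$converged) && fit$theta > 0
  structure(res, class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf(
    "slope_result %s: beta = %.4f (SE %.4f), theta = %.3g, %d quadrats [%s%s]\n",
    x$subject_id, x$beta, x$beta_se, x$theta, x$n_quadrats, x$family,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fold change implied by a log-link slope
#'
#' Multiplicative change `exp(n * beta)` in expected CD8 count per
#' increase of `n` cancer cells in a quadrat. Rounding to the 2-decimal
#' presentation convention is the caller's job.
#'
#' @param beta slope on the log scale (per cancer cell).
#' @param n cancer-cell increment.
#' @return dimensionless ratio.
#' @export
fold_change <- function(beta, n = 10) {
  stopifnot(is.finite(beta))
  exp(n * beta)
}

#' Fit per-subject slopes across a cohort
#'
#' @param grids list of `quadrat_grid`.
#' @param ... passed to [fit_subject_glm()].
#' @return `data.frame` slope table: `subject_id`, `alpha`, `beta`, `se`,
#'   `theta`, `n_quadrats`, `converged`, `family`.
#' @export
fit_cohort_slopes <- function(grids, ...) {
  rows <- lapply(grids, function(g) {
    r <- tryCatch(fit_subject_glm(g, ...), error = function(e) {
      warning("subject ", g$subject_id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(r))
      return(data.frame(subject_id = g$subject_id, alpha = NA_real_,
                        beta = NA_real_, se = NA_real_, theta = NA_real_,
                        n_quadrats = sum(g$active), converged = FALSE,
                        family = NA_character_, stringsAsFactors = FALSE))
    data.frame(subject_id = r$subject_id, alpha = r$alpha, beta = r$beta,
               se = r$beta_se, theta = r$theta, n_quadrats = r$n_quadrats,
               converged = r$converged, family = r$family,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join slopes to clinical covariates
#'
#' One row per subject with the slope statistic, covariates and survival
#' fields; non-converged fits are dropped (with a warning) since no slope
#' exists for them. Per-treatment-arm slope medians are attached as the
#' `"arm_medians"` attribute.
#'
#' @param slopes slope table from [fit_cohort_slopes()].
#' @param clinical clinical table from [read_clinical_table()] (or the
#'   synthetic generator).
#' @return `cohort_table` data frame.
#' @export
cohort_slope_table <- function(slopes, clinical) {
  conv <- slopes[slopes$converged, , drop = FALSE]
  if (nrow(conv) < nrow(slopes))
    warning(nrow(slopes) - nrow(conv),
            " non-converged subject fit(s) dropped from the cohort table")
  unmatched <- setdiff(conv$subject_id, clinical$subject_id)
  if (length(unmatched))
    stop("subjects missing from clinical table: ",
         paste(unmatched, collapse = ", "))
  tab <- merge(conv, clinical, by = "subject_id", sort = TRUE)
  tab <- as_clinical_factors(tab)
  med <- tapply(tab$beta, tab$treatment, stats::median)
  for (arm in levels(tab$treatment))
    if (!arm %in% names(med) || is.na(med[arm]))
      warning("treatment arm '", arm, "' is empty; no arm median")
  attr(tab, "arm_medians") <- med
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Median split of the cohort on the slope statistic
#'
#' Dichotomises subjects at the whole-cohort median slope: `HigherSlope`
#' iff beta >= median (ties go to the higher group), `LowerSlope`
#' otherwise. `LowerSlope` is the factor reference level, so the Cox
#' hazard ratio of `HigherSlope` < 1 reads as protective.
#'
#' @param table `cohort_table`.
#' @return the table with a `slope_group` factor column added and the
#'   split point stored as attribute `"cohort_median_beta"`.
#' @export
median_split <- function(table) {
  if (nrow(table) < 2L) stop("need at least 2 subjects for a median split")
  med <- stats::median(table$beta)
  table$slope_group <- factor(
    ifelse(table$beta >= med, "HigherSlope", "LowerSlope"),
    levels = c("LowerSlope", "HigherSlope"))
  attr(table, "cohort_median_beta") <- med
  table
}
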