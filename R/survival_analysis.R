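# Survival layer: KM estimation with median CIs, the age dichotomy used
# in the hazard model, and the multivariate Cox fit on the slope grouping.

#' Dichotomise age at the cohort cutoff
#'
#' `upper` iff age >= cutoff; `lower` is the reference level. The default
#' cutoff of 70 years is the cohort median age.
#'
#' @param age numeric, years.
#' @param cutoff years (default 70).
#' @return factor with levels `lower`, `upper`.
#' @export
make_agecat <- function(age, cutoff = 70) {
  stopifnot(all(age > 0))
  factor(ifelse(age >= cutoff, "upper", "lower"),
         levels = c("lower", "upper"))
}

#' Kaplan-Meier fit with median survival
#'
#' Product-limit estimator, optionally by group, with the median survival
#' time and its 95% CI from the log-log-transformed curve. A group whose
#' curve never crosses 0.5 has its median reported as `NA` (not reached).
#'
#' @param table `cohort_table` (needs `time`, `event`).
#' @param group_by optional column name to stratify on (e.g.
#'   `"slope_group"`).
#' @param conf_type CI transform, default `"log-log"`.
#' @return `km_result`: the `survfit` object plus a `medians` data frame
#'   (`group`, `n`, `events`, `median`, `lower`, `upper`).
#' @export
km_fit <- function(table, group_by = NULL, conf_type = "log-log") {
  df <- as.data.frame(table)
  stopifnot(all(df$time > 0), all(df$event %in% c(0, 1)))
  if (is.null(group_by)) {
    fml <- survival::Surv(time, event) ~ 1
  } else {
    df$.group <- df[[group_by]]
    fml <- survival::Surv(time, event) ~ .group
  }
  fit <- survival::survfit(fml, data = df, conf.type = conf_type)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- t(as.matrix(tab))
  groups <- if (is.null(group_by)) "all" else
    sub("^\\.group=", "", rownames(tab))
  medians <- data.frame(
    group = groups,
    n = tab[, "records"], events = tab[, "events"],
    median = tab[, "median"],
    lower = tab[, "0.95LCL"], upper = tab[, "0.95UCL"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, medians = medians, group_by = group_by),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier fit",
      if (!is.null(x$group_by)) paste("by", x$group_by), "\n")
  print(x$medians, row.names = FALSE)
  invisible(x)
}

#' Step-function export of a KM fit
#'
#' @param km `km_result`.
#' @return `data.frame(group, time, n_risk, n_event, survival, lower,
#'   upper)`.
#' @export
km_curve_df <- function(km) {
  s <- summary(km$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) "all" else sub("^\\.group=", "", s$strata)
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, survival = s$surv,
             lower = s$lower, upper = s$upper,
             stringsAsFactors = FALSE)
}

#' Multivariate Cox model on the slope grouping
#'
#' Cox proportional-hazards fit (Efron ties) of survival on the slope
#' group together with treatment, sex, age category, tumor grade and
#' tumor stage. `LowerSlope` is the reference level, so a HigherSlope
#' hazard ratio below 1 indicates the stronger-coupling group is
#' protected. Age enters as the dichotomised `AgeCat` by default; linear
#' age in years is available via `age_form = "linear"`.
#'
#' Monotone-likelihood separation (some coefficient running to infinity)
#' is detected and flagged on the result, never silently ignored.
#'
#' @param table `cohort_table` after [median_split()].
#' @param age_form `"agecat"` (default) or `"linear"`.
#' @param age_cutoff years, for `"agecat"`.
#' @param collapse_sparse_stage collapse stage levels with < 2 events
#'   into the adjacent lower level (off by default; logged when it acts).
#' @return `cox_result`: `terms` data frame (`term`, `hr`, `lower`,
#'   `upper`, `p`), `separation` flag, and the `coxph` fit.
#' @export
cox_fit <- function(table, age_form = c("agecat", "linear"),
                    age_cutoff = 70, collapse_sparse_stage = FALSE) {
  age_form <- match.arg(age_form)
  df <- as.data.frame(table)
  stopifnot("slope_group" %in% names(df))
  if (sum(df$event) < 1L) stop("no events observed; Cox model undefined")
  df <- as_clinical_factors(df)
  df$slope_group <- factor(df$slope_group,
                           levels = c("LowerSlope", "HigherSlope"))
  if (age_form == "agecat") df$AgeCat <- make_agecat(df$age, age_cutoff)
  if (collapse_sparse_stage) {
    ev <- tapply(df$event, df$stage, sum)
    for (lv in rev(levels(df$stage))[-length(levels(df$stage))]) {
      if (!is.na(ev[lv]) && ev[lv] < 2 && sum(df$stage == lv) > 0) {
        below <- levels(df$stage)[match(lv, levels(df$stage)) - 1L]
        message("collapsing sparse stage ", lv, " into ", below)
        df$stage[df$stage == lv] <- below
      }
    }
    df$stage <- droplevels(df$stage)
  }
  terms <- prune_constant_terms(
    df, c("slope_group", "treatment", "sex",
          if (age_form == "agecat") "AgeCat" else "age", "grade", "stage"))
  fml <- stats::reformulate(terms, "survival::Surv(time, event)")
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = droplevels(df), ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation)
    warning("monotone likelihood detected (a coefficient diverges); ",
            "interpret the affected term's HR with caution")
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = out, separation = separation, n = s$n,
                 n_events = s$nevent, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH model (Efron ties): %d subjects, %d events%s\n",
              x$n, x$n_events,
              if (x$separation) "  [separation flagged]" else ""))
  df <- x$terms
  df$hr <- sprintf("%.2f", df$hr)
  df$ci <- sprintf("(%.2f-%.2f)", x$terms$lower, x$terms$upper)
  df$p <- sprintf("%.3g", x$terms$p)
  print(df[, c("term", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Forest-plot data export
#'
#' @param cox `cox_result`.
#' @return `data.frame(term, hr, lower, upper, p)` ready for any plotting
#'   layer.
#' @export
forest_data <- function(cox) cox$terms
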