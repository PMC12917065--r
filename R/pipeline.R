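# End-to-end orchestration: TIL filter -> inclusion rule -> quadrat
# grids -> per-subject slopes -> cohort contrasts -> median-split
# survival, with every output written as plain text.

#' Pipeline configuration
#'
#' All knobs of the analysis in one serialisable list. Round-trips
#' through YAML unchanged ([write_config()] / [read_config()]).
#'
#' @param quadrat_mm quadrat edge, mm.
#' @param til_um TIL distance threshold, um.
#' @param min_cancer,min_cd8 subject inclusion minima.
#' @param inclusion_after_filter apply the inclusion rule to
#'   filtered counts (default) or to raw counts.
#' @param log_slope_policy `"exclude"` or `"shift"` for non-positive
#'   slopes in the log-slope model.
#' @param glmm_method `"laplace"` or `"agq"`.
#' @param glmm_nodes quadrature nodes for `"agq"`.
#' @param cox_age `"agecat"` or `"linear"`.
#' @param age_cutoff years.
#' @param seed integer.
#' @param density_bandwidth_mm quartic-kernel bandwidth for the optional
#'   intensity maps.
#' @return named list (class `quadtil_config`).
#' @export
quadtil_config <- function(quadrat_mm = 0.5, til_um = 50,
                           min_cancer = 10, min_cd8 = 10,
                           inclusion_after_filter = TRUE,
                           log_slope_policy = "exclude",
                           glmm_method = "laplace", glmm_nodes = 7,
                           cox_age = "agecat", age_cutoff = 70,
                           seed = 1, density_bandwidth_mm = 0.25) {
  cfg <- list(quadrat_mm = quadrat_mm, til_um = til_um,
              min_cancer = min_cancer, min_cd8 = min_cd8,
              inclusion_after_filter = inclusion_after_filter,
              log_slope_policy = log_slope_policy,
              glmm_method = glmm_method, glmm_nodes = glmm_nodes,
              cox_age = cox_age, age_cutoff = age_cutoff, seed = seed,
              density_bandwidth_mm = density_bandwidth_mm)
  stopifnot(cfg$quadrat_mm > 0, cfg$til_um > 0, cfg$min_cancer > 0,
            cfg$min_cd8 > 0, cfg$density_bandwidth_mm > 0)
  structure(cfg, class = c("quadtil_config", "list"))
}

#' @rdname quadtil_config
#' @param config a `quadtil_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname quadtil_config
#' @export
read_config <- function(path) {
  do.call(quadtil_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically given the inputs and config: per-subject
#' pattern building, the TIL distance filter, the minimum-count
#' inclusion rule, quadrat counting with zero-zero exclusion, per-subject
#' NB slopes, the cohort log-slope and heterogeneity contrasts, the NB
#' mixed model, and the median-split KM/Cox survival analysis. When
#' `out_dir` is given, writes: `slopes.csv`, `exclusions.csv`,
#' `patterns.csv`, `quadrat_summaries.csv`, `models.json`,
#' `km_curves.csv`, `forest.csv`, `config.yaml` and a human-readable
#' `report.txt`.
#'
#' Cohort models that need both arms are skipped (with a log line) when
#' an arm is absent; per-subject stages always run.
#'
#' @param cells cell table (`data.frame` in the canonical columns) or a
#'   path readable by [read_cell_table()].
#' @param clinical clinical table (`data.frame`) or CSV path.
#' @param config [quadtil_config()].
#' @param out_dir optional output directory (created if needed).
#' @param quiet suppress per-stage log lines.
#' @return list with `slopes`, `table` (cohort table with
#'   `slope_group`), `exclusions`, `summaries`, `log_slope`,
#'   `heterogeneity`, `glmm`, `km_overall`, `km_groups`, `cox`.
#' @export
run_pipeline <- function(cells, clinical, config = quadtil_config(),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[quadtil] ", ...)
  if (is.character(cells)) cells <- read_cell_table(cells)
  if (is.character(clinical)) clinical <- read_clinical_table(clinical)
  clinical <- validate_clinical(as_clinical_factors(clinical))

  ids <- unique(cells$subject_id)
  say(length(ids), " subject(s) in cell table")
  patterns <- lapply(ids, function(id) build_subject_pattern(cells, id))

  filtered <- lapply(patterns, function(p) {
    if (nrow(p$cancer) == 0L) return(p)   # inclusion rule will catch it
    q <- filter_tils(p, config$til_um)
    say(q$subject_id, ": ", nrow(p$cd8) - nrow(q$cd8),
        " CD8 removed by ", config$til_um, "-um filter (",
        q$dist_source, " distances)")
    q
  })
  basis <- if (config$inclusion_after_filter) filtered else patterns
  inc <- apply_subject_inclusion(basis, config$min_cancer, config$min_cd8)
  if (config$inclusion_after_filter) {
    kept <- inc$kept
  } else {
    kept_ids <- vapply(inc$kept, `[[`, "", "subject_id")
    kept <- Filter(function(p) p$subject_id %in% kept_ids, filtered)
  }
  for (i in seq_len(nrow(inc$excluded)))
    say("excluded ", inc$excluded$subject_id[i], ": ",
        inc$excluded$reason[i])
  say(length(kept), " subject(s) retained")

  grids <- lapply(kept, make_quadrat_grid, cell_size = config$quadrat_mm)
  summaries <- do.call(rbind, lapply(grids, quadrat_summaries))
  slopes <- fit_cohort_slopes(grids)
  table <- cohort_slope_table(slopes, clinical)
  table <- median_split(table)
  say("cohort median slope: ",
      signif(attr(table, "cohort_median_beta"), 4))

  both_arms <- all(table(table$treatment) >= 2)
  try_model <- function(label, expr) {
    if (!both_arms) { say("skipping ", label, ": an arm is missing");
                      return(NULL) }
    tryCatch(expr, error = function(e) {
      say(label, " failed: ", conditionMessage(e)); NULL
    })
  }
  log_slope <- try_model("log-slope model",
    fit_log_slope_model(table, policy = config$log_slope_policy))
  het <- try_model("heterogeneity model",
    fit_heterogeneity_model(summaries, clinical))
  glmm <- try_model("NB GLMM",
    fit_nb_glmm(grids, clinical, method = config$glmm_method,
                nodes = config$glmm_nodes))

  km_all <- km_fit(table)
  km_grp <- km_fit(table, group_by = "slope_group")
  cox <- tryCatch(
    cox_fit(table, age_form = config$cox_age,
            age_cutoff = config$age_cutoff),
    error = function(e) { say("Cox model failed: ", conditionMessage(e));
                          NULL })

  res <- list(slopes = slopes, table = table, exclusions = inc$excluded,
              summaries = summaries, log_slope = log_slope,
              heterogeneity = het, glmm = glmm, km_overall = km_all,
              km_groups = km_grp, cox = cox, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, kept, out_dir)
  invisible(res)
}

# Serialise every pipeline product as plain text under out_dir.
write_pipeline_outputs <- function(res, patterns, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  slopes_out <- merge(
    res$slopes,
    res$table[, c("subject_id", "slope_group")],
    by = "subject_id", all.x = TRUE)
  utils::write.csv(slopes_out, fp("slopes.csv"), row.names = FALSE)
  utils::write.csv(res$exclusions, fp("exclusions.csv"), row.names = FALSE)
  utils::write.csv(res$summaries, fp("quadrat_summaries.csv"),
                   row.names = FALSE)
  write_pattern_csv(patterns, fp("patterns.csv"))
  utils::write.csv(km_curve_df(res$km_groups), fp("km_curves.csv"),
                   row.names = FALSE)
  if (!is.null(res$cox))
    utils::write.csv(forest_data(res$cox), fp("forest.csv"),
                     row.names = FALSE)
  models <- Filter(Negate(is.null), list(
    log_slope = if (!is.null(res$log_slope)) model_report(res$log_slope),
    heterogeneity = if (!is.null(res$heterogeneity))
      model_report(res$heterogeneity),
    glmm = if (!is.null(res$glmm)) model_report(res$glmm)))
  jsonlite::write_json(models, fp("models.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config(res$config, fp("config.yaml"))

  con <- file(fp("report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("quadtil pipeline report")
  w("=======================")
  w(sprintf("%d subject(s) analysed, %d excluded",
            nrow(res$table), nrow(res$exclusions)))
  med <- attr(res$table, "arm_medians")
  for (arm in names(med))
    w(sprintf("median slope (%s): %.4f  => fold change per 10 cancer cells %.2f",
              arm, med[arm], fold_change(med[arm], 10)))
  w(sprintf("cohort median slope: %.4f",
            attr(res$table, "cohort_median_beta")))
  if (!is.null(res$log_slope))
    w(sprintf("log-slope NAT/naive ratio: %.2f (p = %.3g)",
              res$log_slope$treatment_ratio,
              res$log_slope$p_values["treatmentNAT"]))
  if (!is.null(res$heterogeneity))
    w(sprintf("NAT effect on quadrat-wise cancer SD: %.2f (p = %.3g)",
              res$heterogeneity$treatment_effect,
              res$heterogeneity$p_value))
  if (!is.null(res$glmm))
    w(sprintf(
      "GLMM: cancer %.4f, interaction %.4f; 100-cell fold changes %.2f (naive) / %.2f (NAT)",
      res$glmm$beta_cancer["est"], res$glmm$beta_interaction["est"],
      fold_change(res$glmm$beta_cancer["est"], 100),
      fold_change(res$glmm$beta_cancer["est"] +
                  res$glmm$beta_interaction["est"], 100)))
  w(sprintf("overall median survival: %.0f days", res$km_overall$medians$median))
  if (!is.null(res$cox)) {
    hr <- res$cox$terms[res$cox$terms$term == "slope_groupHigherSlope", ]
    if (nrow(hr))
      w(sprintf("HigherSlope hazard ratio: %.2f (%.2f-%.2f), p = %.3g",
                hr$hr, hr$lower, hr$upper, hr$p))
  }
  invisible(out_dir)
}
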