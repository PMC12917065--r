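#' Column-name dialect for cell coordinate tables
#'
#' Platform exports differ in header names; a dialect maps the exporter's
#' column names onto the canonical fields. Coordinates are expected in
#' micrometres, as exported.
#'
#' @param subject_id,class,x,y,dist column names in the input file for the
#'   subject identifier, cell class, x/y coordinate (um) and the optional
#'   precomputed distance-to-gland (um).
#' @return Named list of column names.
#' @export
cell_table_dialect <- function(subject_id = "subject_id", class = "class",
                               x = "x_um", y = "y_um", dist = "dist_um") {
  list(subject_id = subject_id, class = class, x = x, y = y, dist = dist)
}

#' Read a cell coordinate table
#'
#' Reads a delimited text file (CSV/TSV, sniffed from the extension or
#' `sep`) or an xlsx workbook, one row per annotated cell, and returns the
#' canonical cell table: `subject_id`, `class` (one of `"cancer"`, `"cd8"`),
#' `x_um`, `y_um`, `dist_um` (NA when absent). Row order is preserved.
#' Rows with a non-finite coordinate or an unrecognised class are dropped
#' with a warning naming their line numbers; a missing required column is a
#' hard error.
#'
#' @param path input file.
#' @param dialect column mapping, see [cell_table_dialect()].
#' @param sep field separator for text input; default inferred from the
#'   file extension (`.tsv`/`.txt` -> tab, else comma).
#' @return `data.frame` with columns `subject_id`, `class`, `x_um`, `y_um`,
#'   `dist_um`.
#' @export
read_cell_table <- function(path, dialect = cell_table_dialect(), sep = NULL) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading workbooks requires the 'readxl' package")
    raw <- as.data.frame(readxl::read_excel(path))
  } else {
    if (is.null(sep)) sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  required <- c("subject_id", "class", "x", "y")
  for (field in required) {
    col <- dialect[[field]]
    if (!col %in% names(raw))
      stop("required column '", col, "' (field '", field,
           "') not found in ", path)
  }
  has_dist <- dialect$dist %in% names(raw)
  out <- data.frame(
    subject_id = as.character(raw[[dialect$subject_id]]),
    class      = as.character(raw[[dialect$class]]),
    x_um       = suppressWarnings(as.numeric(raw[[dialect$x]])),
    y_um       = suppressWarnings(as.numeric(raw[[dialect$y]])),
    dist_um    = if (has_dist)
      suppressWarnings(as.numeric(raw[[dialect$dist]])) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) {
    warning("cell table ", path, " contains a header but no rows")
    return(out)
  }
  bad_coord <- !is.finite(out$x_um) | !is.finite(out$y_um)
  bad_class <- !out$class %in% c("cancer", "cd8")
  bad <- bad_coord | bad_class
  if (any(bad)) {
    # +1 for the header line, so numbers match the raw file
    warning(sum(bad), " row(s) dropped (non-numeric coordinate or unknown ",
            "class) at line(s): ",
            paste(utils::head(which(bad) + 1L, 20L), collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  neg_dist <- !is.na(out$dist_um) & out$dist_um < 0
  if (any(neg_dist)) stop("negative dist_um value(s) in ", path)
  rownames(out) <- NULL
  out
}

#' Write a cell coordinate table
#'
#' Inverse of [read_cell_table()] for the default dialect; full double
#' precision is written so read/write round-trips are exact to well beyond
#' six decimals.
#'
#' @param records cell table as returned by [read_cell_table()].
#' @param path output CSV path.
#' @export
write_cell_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' One row per subject: `subject_id`, `treatment` (`naive`/`NAT`), `sex`,
#' `age` (years), `grade` (`G1`-`G3`), `stage` (`I`-`IV`), `time`
#' (follow-up days), `event` (1 = death observed). Factors are coded with
#' the reference levels used throughout the cohort models: naive, G1,
#' stage I.
#'
#' @param path CSV path.
#' @return `data.frame` with validated, factor-coded columns.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "treatment", "sex", "age", "grade", "stage",
                "time", "event")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  validate_clinical(as_clinical_factors(df))
}

#' @keywords internal
as_clinical_factors <- function(df) {
  df$treatment <- factor(df$treatment, levels = c("naive", "NAT"))
  df$sex   <- factor(df$sex)
  df$grade <- factor(df$grade, levels = c("G1", "G2", "G3"))
  df$stage <- factor(df$stage, levels = c("I", "II", "III", "IV"))
  df
}

#' @keywords internal
validate_clinical <- function(df) {
  if (anyNA(df$treatment)) stop("treatment must be 'naive' or 'NAT'")
  if (anyNA(df$grade)) stop("grade must be one of G1, G2, G3")
  if (anyNA(df$stage)) stop("stage must be one of I, II, III, IV")
  if (any(df$time <= 0)) stop("follow-up time must be positive")
  if (any(df$age <= 0)) stop("age must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}

#' Build a subject's two-class point pattern
#'
#' Splits a subject's cell records into cancer and CD8 point sets, rescales
#' coordinates 1:1000 from micrometres to millimetres, and attaches the
#' observation window as the bounding box of all the subject's points
#' (both classes). The precomputed distance-to-gland, when present on CD8
#' rows, is carried along in micrometres.
#'
#' @param records cell table (canonical columns, um).
#' @param subject_id subject to extract; default: the single id present.
#' @return `subject_pattern` object: `cancer` and `cd8` data frames with
#'   `x`, `y` in mm (`cd8` also has `dist_um`), and `window =
#'   c(xmin, xmax, ymin, ymax)` in mm.
#' @export
build_subject_pattern <- function(records, subject_id = NULL) {
  if (is.null(subject_id)) {
    ids <- unique(records$subject_id)
    if (length(ids) != 1L)
      stop("records contain ", length(ids),
           " subjects; supply subject_id explicitly")
    subject_id <- ids
  }
  rec <- records[records$subject_id == subject_id, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for subject '", subject_id, "'")
  mm <- function(v) v / 1000  # exact 1:1000 um -> mm rescale
  ca <- rec[rec$class == "cancer", , drop = FALSE]
  cd <- rec[rec$class == "cd8", , drop = FALSE]
  window <- c(min(rec$x_um), max(rec$x_um), min(rec$y_um), max(rec$y_um)) / 1000
  structure(list(
    subject_id = subject_id,
    cancer = data.frame(x = mm(ca$x_um), y = mm(ca$y_um)),
    cd8    = data.frame(x = mm(cd$x_um), y = mm(cd$y_um),
                        dist_um = cd$dist_um),
    window = window,
    dist_source = NA_character_
  ), class = "subject_pattern")
}

#' @export
print.subject_pattern <- function(x, ...) {
  cat("subject_pattern:", x$subject_id, "\n")
  cat(sprintf("  %d cancer, %d cd8 points; window [%.3f, %.3f] x [%.3f, %.3f] mm\n",
              nrow(x$cancer), nrow(x$cd8),
              x$window[1], x$window[2], x$window[3], x$window[4]))
  if (!is.na(x$dist_source)) cat("  TIL distance source:", x$dist_source, "\n")
  invisible(x)
}

#' Apply the minimum-cell-count inclusion rule
#'
#' Subjects with fewer than `min_cancer` cancer cells or fewer than
#' `min_cd8` CD8 cells are excluded (strict `< min` rule, so a subject at
#' exactly the minimum is kept). When the TIL distance filter is part of
#' the pipeline the rule is applied to the filtered patterns, i.e. to the
#' cells the downstream models actually use.
#'
#' @param patterns list of `subject_pattern`.
#' @param min_cancer,min_cd8 minimum counts (default 10 each).
#' @return list with `kept` (list of patterns) and `excluded`
#'   (`data.frame(subject_id, reason)`).
#' @export
apply_subject_inclusion <- function(patterns, min_cancer = 10, min_cd8 = 10) {
  keep <- logical(length(patterns))
  reasons <- character(0)
  ids <- character(0)
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    why <- c(
      if (nrow(p$cancer) < min_cancer) sprintf("cancer<%d", min_cancer),
      if (nrow(p$cd8) < min_cd8) sprintf("cd8<%d", min_cd8)
    )
    keep[i] <- length(why) == 0L
    if (!keep[i]) {
      ids <- c(ids, p$subject_id)
      reasons <- c(reasons, paste(why, collapse = ";"))
    }
  }
  list(
    kept = patterns[keep],
    excluded = data.frame(subject_id = ids, reason = reasons,
                          stringsAsFactors = FALSE)
  )
}

#' Write normalized per-subject coordinates
#'
#' Emits the normalized long-format table (`subject_id`, `class`, `x_mm`,
#' `y_mm`) for a list of patterns.
#'
#' @param patterns list of `subject_pattern`.
#' @param path output CSV.
#' @export
write_pattern_csv <- function(patterns, path) {
  rows <- lapply(patterns, function(p) {
    rbind(
      if (nrow(p$cancer)) data.frame(subject_id = p$subject_id,
                                     class = "cancer",
                                     x_mm = p$cancer$x, y_mm = p$cancer$y),
      if (nrow(p$cd8)) data.frame(subject_id = p$subject_id, class = "cd8",
                                  x_mm = p$cd8$x, y_mm = p$cd8$y)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export a cohort to the cell-table input format
#'
#' Serialises a list of subject patterns back to one canonical cell table
#' in micrometres, i.e. the format [read_cell_table()] ingests. Used to
#' materialise synthetic cohorts as pipeline input.
#'
#' @param patterns list of `subject_pattern`.
#' @return canonical cell table `data.frame` (um).
#' @export
patterns_to_cell_table <- function(patterns) {
  rows <- lapply(patterns, function(p) {
    rbind(
      if (nrow(p$cancer))
        data.frame(subject_id = p$subject_id, class = "cancer",
                   x_um = p$cancer$x * 1000, y_um = p$cancer$y * 1000,
                   dist_um = NA_real_),
      if (nrow(p$cd8))
        data.frame(subject_id = p$subject_id, class = "cd8",
                   x_um = p$cd8$x * 1000, y_um = p$cd8$y * 1000,
                   dist_um = p$cd8$dist_um)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
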