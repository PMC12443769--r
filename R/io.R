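#' Required cohort columns
#'
#' @return character vector of the column names every cohort table must
#'   carry (rater decision columns \code{decision_*} are optional).
#' @export
cohort_required_cols <- function() {
  c("eye_id", "axial_length", "preop_bcva", "predicted_postop_bcva",
    "nuclear_gold", "cortical_gold", "nuclear_ai", "cortical_ai",
    "oct_findings")
}

#' Read a per-eye cohort table
#'
#' Reads a cohort from CSV or JSON, validates the schema, and normalises
#' every visual-acuity column to logMAR: cells may hold Snellen fractions
#' (\code{"6/12"}), numeric logMAR, or the categorical low-vision codes
#' CF/HM/LP/NLP (case-insensitive). Eyes with axial length at or below
#' 26.0 mm violate the high-myopia inclusion criterion and raise a warning;
#' a duplicate \code{eye_id} or a missing required column is an error.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"json"}.
#' @return validated cohort tibble with attribute \code{provenance}.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character())),
    json = tibble::as_tibble(jsonlite::fromJSON(path))
  )
  missing_cols <- setdiff(cohort_required_cols(), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$eye_id)) {
    stop("duplicate eye_id(s): ",
         paste(unique(raw$eye_id[duplicated(raw$eye_id)]), collapse = ", "),
         call. = FALSE)
  }
  va_cols <- intersect(
    c("preop_bcva", "predicted_postop_bcva", "actual_postop_bcva"),
    names(raw))
  num_cols <- intersect(
    c("axial_length", "nuclear_gold", "cortical_gold", "psc_gold",
      "nuclear_ai", "cortical_ai", "psc_ai"), names(raw))
  dec_cols <- grep("^decision_", names(raw), value = TRUE)
  out <- raw
  problems <- character()
  for (col in va_cols) {
    parsed <- tryCatch(va_to_logmar(out[[col]]), error = function(e) e)
    if (inherits(parsed, "error")) {
      bad <- which(is.na(suppressWarnings(
        vapply(out[[col]], function(v)
          tryCatch(va_to_logmar(v), error = function(e) NA_real_),
          numeric(1)))) & !is.na(out[[col]]))
      problems <- c(problems, sprintf("column %s, row(s) %s: %s", col,
                                      paste(bad, collapse = ","),
                                      conditionMessage(parsed)))
    } else {
      out[[col]] <- parsed
    }
  }
  for (col in c(num_cols, dec_cols)) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) & out[[col]] != "")
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("column %s, row(s) %s: not numeric",
                                      col, paste(bad, collapse = ",")))
    }
    out[[col]] <- v
  }
  if (length(problems) > 0) {
    stop("malformed cohort cells:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  for (col in dec_cols) decision_factor(out[[col]])  # validate range
  low_al <- !is.na(out$axial_length) & out$axial_length <= 26.0
  if (any(low_al)) {
    warning(sum(low_al), " eye(s) have axial length <= 26.0 mm and fall ",
            "outside the highly myopic inclusion criterion: ",
            paste(utils::head(out$eye_id[low_al], 5), collapse = ", "),
            call. = FALSE)
  }
  attr(out, "provenance") <- list(path = path, format = format,
                                  parser = "eyetriage read_cohort v1")
  out
}

#' Write a cohort table
#'
#' @param data cohort data frame.
#' @param path destination; extension selects CSV or JSON unless
#'   \code{format} is given.
#' @param format \code{"auto"}, \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(data, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(data, path)
  } else {
    jsonlite::write_json(data, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

.fmt <- list(
  pct = function(x) round_half_up(x, 2),
  coef = function(x) round_half_up(x, 3),
  logmar = function(x) round_half_up(x, 4)
)

.frac <- function(k, n) {
  list(percent = .fmt$pct(100 * k / n), numerator = k, denominator = n)
}

#' Consolidated cohort evaluation report
#'
#' Runs the whole evaluation battery on a cohort and returns one structured
#' report: LOCS III grading evaluation per subtype (AI vs gold), the
#' visual-acuity prediction evaluation, the per-rater decision distribution,
#' and per-rater agreement with the gold standard overall and on the
#' special-case subset. Sections whose inputs are missing are skipped with
#' an explicit reason, never silently. Percentages are reported to 2
#' decimals, kappa/ICC/AUC to 3, logMAR metrics to 4; every percentage
#' carries its numerator and denominator.
#'
#' @param data cohort tibble (e.g. from \code{\link{read_cohort}} or
#'   \code{\link{simulate_cohort}}).
#' @param config a \code{\link{decision_config}} (used for the grading
#'   threshold).
#' @param raters character vector of rater names (suffixes of
#'   \code{decision_<rater>} columns); defaults to all present.
#' @return object of class \code{eyetriage_report} (a nested list).
#' @export
run_report <- function(data, config = decision_config(), raters = NULL) {
  report <- list(meta = list(n = nrow(data),
                             thresholds = list(
                               grade = config$grade_threshold,
                               preop_va = config$preop_va_threshold,
                               improvement = config$improvement_threshold,
                               al_caution = config$al_caution_threshold)),
                 skipped = list())

  # grading section
  grading_cols <- c("nuclear_ai", "nuclear_gold", "cortical_ai",
                    "cortical_gold")
  if (all(grading_cols %in% names(data))) {
    report$grading <- lapply(c(nuclear = "nuclear", cortical = "cortical"),
      function(st) {
        ev <- grading_eval(NULL, data[[paste0(st, "_ai")]],
                           data[[paste0(st, "_gold")]], subtype = st,
                           threshold = config$grade_threshold)
        list(
          re10 = .frac(ev$re$within, ev$re$n),
          icc = .fmt$coef(ev$icc$icc),
          accuracy = .fmt$pct(100 * ev$binary$accuracy),
          sensitivity = .fmt$pct(100 * ev$binary$sensitivity),
          specificity = .fmt$pct(100 * ev$binary$specificity),
          auc = if (is.null(ev$auc)) NA_real_ else .fmt$coef(ev$auc$auc),
          auc_ci = if (is.null(ev$auc)) NULL else .fmt$coef(ev$auc$ci),
          n = ev$n
        )
      })
  } else {
    report$skipped$grading <- paste(
      "missing column(s):",
      paste(setdiff(grading_cols, names(data)), collapse = ", "))
  }

  # VA prediction section
  if (all(c("predicted_postop_bcva", "actual_postop_bcva") %in% names(data)) &&
      !anyNA(data$actual_postop_bcva)) {
    ev <- va_eval(data, predicted_postop_bcva, actual_postop_bcva)
    groups <- lapply(seq_len(nrow(ev$groups)), function(i) {
      g <- ev$groups[i, ]
      list(group = g$group,
           sensitivity = .frac(g$correct, g$actual_n),
           precision = .frac(g$correct, g$predicted_n))
    })
    names(groups) <- ev$groups$group
    report$va_prediction <- list(
      mae = .fmt$logmar(ev$mae), rmse = .fmt$logmar(ev$rmse),
      re_within = .frac(round(ev$re_within * ev$n), ev$n),
      groups = groups, n = ev$n)
  } else {
    report$skipped$va_prediction <-
      "actual postoperative BCVA absent or incomplete"
  }

  # decision distribution + agreement sections
  if ("decision_gold" %in% names(data)) {
    if (is.null(raters)) {
      raters <- sub("^decision_", "",
                    setdiff(grep("^decision_", names(data), value = TRUE),
                            "decision_gold"))
    }
    gold <- decision_factor(data$decision_gold)
    dist <- list(gold = as.integer(table(gold)))
    agreement <- list()
    special <- special_cases(data)
    for (r in raters) {
      col <- paste0("decision_", r)
      if (!col %in% names(data)) {
        report$skipped[[paste0("rater_", r)]] <-
          paste("no column", col, "in cohort")
        next
      }
      dec <- decision_factor(data[[col]])
      dist[[r]] <- as.integer(table(dec))
      cm <- confusion_matrix(NULL, gold, dec)
      kap <- cohen_kappa(cm)
      entry <- list(
        consistency = .frac(kap$agree, kap$n),
        kappa = .fmt$coef(kap$kappa),
        confusion = unclass(cm)
      )
      if (nrow(special) > 0) {
        skap <- cohen_kappa(decision_factor(special$decision_gold),
                            decision_factor(special[[col]]))
        entry$special <- list(consistency = .frac(skap$agree, skap$n),
                              kappa = .fmt$coef(skap$kappa))
      }
      agreement[[r]] <- entry
    }
    report$decisions <- dist
    report$agreement <- agreement
    report$special_case_n <- nrow(special)
  } else {
    report$skipped$agreement <- "no decision_gold column in cohort"
  }

  structure(report, class = "eyetriage_report")
}

#' @export
print.eyetriage_report <- function(x, ...) {
  cat(sprintf("Cohort evaluation report (n = %d eyes)\n", x$meta$n))
  if (!is.null(x$grading)) {
    for (st in names(x$grading)) {
      g <- x$grading[[st]]
      cat(sprintf("  %s grading: Re1.0 %.2f%% (%d/%d), ICC %s, AUC %s\n",
                  st, g$re10$percent, g$re10$numerator, g$re10$denominator,
                  .fmt_or_na(g$icc, "%.3f"), .fmt_or_na(g$auc, "%.3f")))
    }
  }
  if (!is.null(x$va_prediction)) {
    cat(sprintf("  VA prediction: MAE %.4f, RMSE %.4f logMAR; within band %.2f%% (%d/%d)\n",
                x$va_prediction$mae, x$va_prediction$rmse,
                x$va_prediction$re_within$percent,
                x$va_prediction$re_within$numerator,
                x$va_prediction$re_within$denominator))
  }
  for (r in names(x$agreement)) {
    a <- x$agreement[[r]]
    cat(sprintf("  rater %s: consistency %.2f%% (%d/%d), kappa %s\n",
                r, a$consistency$percent, a$consistency$numerator,
                a$consistency$denominator, .fmt_or_na(a$kappa, "%.3f")))
    if (!is.null(a$special)) {
      cat(sprintf("    special cases: %.2f%% (%d/%d), kappa %s\n",
                  a$special$consistency$percent,
                  a$special$consistency$numerator,
                  a$special$consistency$denominator,
                  .fmt_or_na(a$special$kappa, "%.3f")))
    }
  }
  for (nm in names(x$skipped)) {
    cat(sprintf("  [skipped] %s: %s\n", nm, x$skipped[[nm]]))
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Writes the report as JSON and, for each rater, the confusion-matrix CSV
#' and heatmap image. Output is a deterministic function of the report.
#'
#' @param report an \code{\link{run_report}} result.
#' @param dir output directory (created if needed).
#' @param heatmaps write PNG heatmaps alongside the CSVs.
#' @return invisibly, character vector of files written.
#' @export
write_report <- function(report, dir, heatmaps = TRUE) {
  stopifnot(inherits(report, "eyetriage_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), files, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  for (r in names(report$agreement)) {
    cm <- report$agreement[[r]]$confusion
    cmx <- structure(cm, class = c("confusion_matrix", "matrix"),
                     n = sum(cm), agree = sum(diag(cm)))
    csv <- file.path(dir, sprintf("confusion_%s.csv", r))
    img <- if (heatmaps) file.path(dir, sprintf("heatmap_%s.png", r)) else NULL
    export_heatmap(cmx, image_path = img, csv_path = csv)
    files <- c(files, csv, img)
  }
  invisible(files)
}
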