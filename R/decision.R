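#' Surgical decision categories
#'
#' The four-level recommendation scale for highly myopic cataract eyes:
#' 0 = surgery not advised, 1 = cataract surgery recommended,
#' 2 = retinal surgery recommended, 3 = combined cataract-retinal surgery
#' recommended.
#'
#' @return named character vector of labels, names \code{"0"}..\code{"3"}.
#' @export
decision_labels <- function() {
  c(`0` = "surgery not advised",
    `1` = "cataract surgery recommended",
    `2` = "retinal surgery recommended",
    `3` = "combined cataract-retinal surgery recommended")
}

#' Decision categories as a factor
#'
#' @param x integer-like vector of categories in 0..3.
#' @return factor with levels \code{0,1,2,3}.
#' @export
decision_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% 0:3)
  if (any(bad)) {
    stop("decision categories must be 0, 1, 2 or 3; got: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  factor(x, levels = 0:3)
}

#' Default OCT finding vocabulary and surgical mapping
#'
#' Macular OCT findings commonly seen in high myopia and whether each one
#' indicates retinal surgery under the default rule table. Choroidal
#' neovascularization (CNV) maps to \code{"none"} by default (it is
#' typically managed medically); every mapping is configurable through
#' \code{\link{decision_config}}.
#'
#' @return named character vector: finding label -> \code{"none"} or
#'   \code{"retinal_surgery"}.
#' @export
oct_default_map <- function() {
  c(none = "none",
    epiretinal_traction = "retinal_surgery",
    macular_retinoschisis = "retinal_surgery",
    retinal_thickening = "retinal_surgery",
    lamellar_hole = "retinal_surgery",
    foveal_retinoschisis = "retinal_surgery",
    foveal_retinal_detachment = "retinal_surgery",
    macular_hole = "retinal_surgery",
    cnv = "none")
}

#' Configuration of the five-step decision rule
#'
#' Every threshold and mapping used by \code{\link{decide}} lives here so
#' the rule table can be re-specified without code changes.
#'
#' @param preop_va_threshold logMAR below which preoperative vision counts
#'   as good (step 1 gate), default 0.30.
#' @param improvement_threshold minimum predicted gain
#'   (preop minus predicted postop logMAR) that counts as a clinically
#'   meaningful improvement, default 0.20 (about two Snellen lines).
#' @param grade_threshold LOCS III grade above which cataract is
#'   surgically significant, default 3.5 (strict inequality).
#' @param al_caution_threshold axial length (mm) at or beyond which a
#'   significant cataract without meaningful predicted gain is not operated,
#'   default 30.0.
#' @param oct_surgical_map named character vector mapping every OCT finding
#'   label to \code{"none"} or \code{"retinal_surgery"}; default
#'   \code{\link{oct_default_map}()}.
#' @return object of class \code{decision_config}.
#' @export
decision_config <- function(preop_va_threshold = 0.30,
                            improvement_threshold = 0.20,
                            grade_threshold = 3.5,
                            al_caution_threshold = 30.0,
                            oct_surgical_map = oct_default_map()) {
  thresholds <- c(preop_va_threshold = preop_va_threshold,
                  improvement_threshold = improvement_threshold,
                  grade_threshold = grade_threshold,
                  al_caution_threshold = al_caution_threshold)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("all decision thresholds must be finite and positive", call. = FALSE)
  }
  if (is.null(names(oct_surgical_map)) || any(names(oct_surgical_map) == "")) {
    stop("oct_surgical_map must be a fully named vector", call. = FALSE)
  }
  if (!all(oct_surgical_map %in% c("none", "retinal_surgery"))) {
    stop("oct_surgical_map values must be 'none' or 'retinal_surgery'",
         call. = FALSE)
  }
  structure(
    list(preop_va_threshold = preop_va_threshold,
         improvement_threshold = improvement_threshold,
         grade_threshold = grade_threshold,
         al_caution_threshold = al_caution_threshold,
         oct_surgical_map = oct_surgical_map),
    class = "decision_config"
  )
}

#' @export
print.decision_config <- function(x, ...) {
  cat("Five-step decision rule configuration\n")
  cat(sprintf("  preop VA threshold:     %.2f logMAR\n", x$preop_va_threshold))
  cat(sprintf("  improvement threshold:  %.2f logMAR\n",
              x$improvement_threshold))
  cat(sprintf("  grade threshold:        >%.1f LOCS III\n", x$grade_threshold))
  cat(sprintf("  AL caution threshold:   %.1f mm\n", x$al_caution_threshold))
  surg <- names(x$oct_surgical_map)[x$oct_surgical_map == "retinal_surgery"]
  cat("  OCT findings -> retinal surgery: ",
      paste(surg, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# split a ";"-separated oct_findings cell into labels, dropping blanks
split_findings <- function(x) {
  x[is.na(x)] <- ""
  strsplit(gsub("\\s", "", x), ";", fixed = FALSE) |>
    lapply(function(v) v[nzchar(v)])
}

#' Apply the five-step surgical decision rule to a cohort
#'
#' Maps each eye to one of the four surgical categories by the fixed rule
#' order S1-S5 (later steps are only reached when earlier ones do not
#' decide):
#' \enumerate{
#'   \item \strong{Preoperative VA}: good preoperative vision
#'     (below \code{preop_va_threshold}) with no surgically-mapped OCT
#'     finding ends the evaluation at category 0.
#'   \item \strong{Predicted improvement}: the predicted gain
#'     (preop minus predicted postop logMAR) is flagged meaningful when it
#'     reaches \code{improvement_threshold}.
#'   \item \strong{Cataract grading}: the cataract is surgically significant
#'     when the nuclear or cortical grade exceeds \code{grade_threshold}
#'     (see \code{\link{surgical_indication}}).
#'   \item \strong{OCT}: any finding mapped to retinal surgery yields
#'     category 3 when the cataract is also significant, otherwise 2.
#'   \item \strong{Axial length}: a significant cataract yields category 1
#'     when the gain is meaningful, or — without meaningful gain — only for
#'     axial length below \code{al_caution_threshold}; otherwise category 0.
#' }
#'
#' The returned trace records, per eye, each step evaluated and the value it
#' contributed, making the applied rule auditable.
#'
#' @param data cohort data frame; requires columns \code{eye_id},
#'   \code{preop_bcva}, \code{predicted_postop_bcva}, \code{axial_length},
#'   \code{oct_findings} (";"-separated labels or empty/\code{"none"}), and
#'   grade columns \code{nuclear_<source>} / \code{cortical_<source>}.
#' @param config a \code{\link{decision_config}}.
#' @param grade_source which grades drive step 3: \code{"ai"} (default) or
#'   \code{"gold"}.
#' @return tibble with \code{eye_id}, \code{category} (factor 0-3),
#'   \code{label}, and \code{trace} (character), one row per input row, in
#'   input order.
#' @examples
#' eye <- tibble::tibble(
#'   eye_id = "e1", axial_length = 27, preop_bcva = 0.8,
#'   predicted_postop_bcva = 0.2, nuclear_ai = 4.5, cortical_ai = 2.0,
#'   oct_findings = "none"
#' )
#' decide(eye)
#' @export
decide <- function(data, config = decision_config(),
                   grade_source = c("ai", "gold")) {
  grade_source <- match.arg(grade_source)
  stopifnot(inherits(config, "decision_config"))
  ncol_name <- paste0("nuclear_", grade_source)
  ccol_name <- paste0("cortical_", grade_source)
  need <- c("eye_id", "preop_bcva", "predicted_postop_bcva", "axial_length",
            "oct_findings", ncol_name, ccol_name)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  if (n == 0L) {
    return(tibble::tibble(eye_id = character(), category = decision_factor(integer()),
                          label = character(), trace = character()))
  }
  eye_id <- as.character(data$eye_id)
  preop <- as.numeric(data$preop_bcva)
  predicted <- as.numeric(data$predicted_postop_bcva)
  al <- as.numeric(data$axial_length)
  if (any(!is.na(al) & al <= 26.0)) {
    warning("eye(s) with axial length <= 26.0 mm are outside the highly ",
            "myopic inclusion criterion: ",
            paste(utils::head(eye_id[!is.na(al) & al <= 26.0], 5),
                  collapse = ", "), call. = FALSE)
  }
  findings <- split_findings(as.character(data$oct_findings))
  vocab <- names(config$oct_surgical_map)
  unknown <- setdiff(unique(unlist(findings)), vocab)
  if (length(unknown) > 0) {
    stop("OCT finding label(s) not in the configured surgical map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  retinal_indicated <- vapply(findings, function(v) {
    any(config$oct_surgical_map[v] == "retinal_surgery")
  }, logical(1))

  # S1: good preop vision, retina clear -> stop at 0
  s1_stop <- preop < config$preop_va_threshold & !retinal_indicated

  needs_pred <- !s1_stop
  if (any(needs_pred & is.na(predicted))) {
    stop("predicted_postop_bcva is missing for eye(s) ",
         paste(utils::head(eye_id[needs_pred & is.na(predicted)], 5),
               collapse = ", "),
         ": the decision rule requires a postoperative visual-acuity ",
         "prediction beyond step 1", call. = FALSE)
  }

  improvement <- preop - predicted
  meaningful_gain <- improvement >= config$improvement_threshold
  significant <- surgical_indication(data[[ncol_name]], data[[ccol_name]],
                                     threshold = config$grade_threshold)

  category <- integer(n)
  trace <- character(n)
  s1_txt <- sprintf("S1 preop=%.2f(%s)", preop,
                    ifelse(preop < config$preop_va_threshold, "good", "poor"))
  s2_txt <- sprintf("S2 gain=%.2f(%s)", improvement,
                    ifelse(meaningful_gain, "meaningful", "limited"))
  s3_txt <- sprintf("S3 cataract=%s",
                    ifelse(significant, "significant", "not-significant"))
  s4_txt <- sprintf("S4 oct=%s",
                    ifelse(retinal_indicated, "retinal-surgical", "clear"))
  s5_txt <- sprintf("S5 AL=%.1fmm(%s)", al,
                    ifelse(al < config$al_caution_threshold, "below-caution",
                           "extreme"))

  for (i in seq_len(n)) {
    if (s1_stop[i]) {
      category[i] <- 0L
      trace[i] <- paste(s1_txt[i], "-> 0")
      next
    }
    steps <- c(s1_txt[i], s2_txt[i], s3_txt[i], s4_txt[i])
    if (retinal_indicated[i]) {
      category[i] <- if (significant[i]) 3L else 2L
      trace[i] <- paste(paste(steps, collapse = "; "), "->", category[i])
      next
    }
    steps <- c(steps, s5_txt[i])
    if (!significant[i]) {
      category[i] <- 0L
    } else if (meaningful_gain[i]) {
      category[i] <- 1L
    } else {
      category[i] <- if (al[i] < config$al_caution_threshold) 1L else 0L
    }
    trace[i] <- paste(paste(steps, collapse = "; "), "->", category[i])
  }

  tibble::tibble(
    eye_id = eye_id,
    category = decision_factor(category),
    label = unname(decision_labels()[as.character(category)]),
    trace = trace
  )
}
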