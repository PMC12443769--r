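#' Convert visual acuity to logMAR
#'
#' Accepts acuities in any of the three notations used in clinical records
#' and normalises them to logMAR:
#' \itemize{
#'   \item Snellen fractions, e.g. \code{"6/12"} or \code{"20/40"}:
#'     \eqn{\log_{10}(\mathrm{den}/\mathrm{num})};
#'   \item numeric logMAR, e.g. \code{"0.30"} or \code{0.30}: identity;
#'   \item categorical low-vision codes (case-insensitive): counting fingers
#'     \code{CF} = 1.9, hand motion \code{HM} = 2.3, light perception
#'     \code{LP} = 2.7, no light perception \code{NLP} = 3.0.
#' }
#'
#' Snellen conversions are rounded to \code{rounding} decimal places by
#' default (2), so that 6/12 maps to 0.30 rather than 0.30103; pass
#' \code{rounding = NULL} for the raw value.
#'
#' @param x character or numeric vector of acuities. \code{NA} passes through.
#' @param rounding integer number of decimal places applied to Snellen
#'   conversions, or \code{NULL} for no rounding.
#' @return numeric vector of logMAR values.
#' @examples
#' va_to_logmar(c("6/12", "6/6", "HM", "0.5"))
#' va_to_logmar("6/12", rounding = NULL)
#' @export
va_to_logmar <- function(x, rounding = 2) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x_chr <- trimws(as.character(x))
  out <- rep(NA_real_, length(x_chr))
  blank <- is.na(x_chr) | x_chr == ""
  up <- toupper(x_chr)
  is_cat <- !blank & up %in% names(.va_code_table)
  out[is_cat] <- .va_code_table[up[is_cat]]
  is_snellen <- !blank & !is_cat & grepl("/", x_chr, fixed = TRUE)
  if (any(is_snellen)) {
    parts <- strsplit(x_chr[is_snellen], "/", fixed = TRUE)
    bad_shape <- lengths(parts) != 2L
    if (any(bad_shape)) {
      stop("malformed Snellen fraction: ",
           paste(x_chr[is_snellen][bad_shape], collapse = ", "), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    den <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    out[is_snellen] <- snellen_to_logmar(num, den, rounding = rounding)
  }
  rest <- !blank & !is_cat & !is_snellen
  if (any(rest)) {
    val <- suppressWarnings(as.numeric(x_chr[rest]))
    if (anyNA(val)) {
      stop("unrecognised visual-acuity value(s): ",
           paste(unique(x_chr[rest][is.na(val)]), collapse = ", "),
           " (expected Snellen \"n/d\", numeric logMAR, or CF/HM/LP/NLP)",
           call. = FALSE)
    }
    out[rest] <- val
  }
  out
}

.va_code_table <- c(CF = 1.9, HM = 2.3, LP = 2.7, NLP = 3.0)

#' Snellen fraction to logMAR
#'
#' @param num,den numerator and denominator of the Snellen fraction, in the
#'   same distance units (both must be positive).
#' @inheritParams va_to_logmar
#' @return numeric logMAR, \eqn{\log_{10}(den/num)}.
#' @examples
#' snellen_to_logmar(6, 12)
#' @export
snellen_to_logmar <- function(num, den, rounding = 2) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  ok <- is.finite(num) & is.finite(den) & num > 0 & den > 0
  if (!all(ok | (is.na(num) & is.na(den)))) {
    stop("Snellen numerator and denominator must be positive and finite",
         call. = FALSE)
  }
  val <- log10(den / num)
  if (!is.null(rounding)) val <- round(val, rounding)
  val
}

#' Classify eyes into good / poor visual-acuity groups
#'
#' Good vision is BCVA strictly below the cutoff (default 0.30 logMAR,
#' Snellen 6/12); an acuity exactly at the cutoff is classified poor.
#'
#' @param bcva numeric vector of logMAR acuities (finite; \code{NA} allowed).
#' @param cutoff logMAR boundary, default 0.30.
#' @return factor with levels \code{good}, \code{poor}.
#' @examples
#' va_group(c(0.1, 0.3, 1.9))
#' @export
va_group <- function(bcva, cutoff = 0.30) {
  bcva <- as.numeric(bcva)
  if (any(!is.na(bcva) & !is.finite(bcva))) {
    stop("BCVA values must be finite", call. = FALSE)
  }
  factor(ifelse(bcva < cutoff, "good", "poor"), levels = c("good", "poor"))
}

#' Evaluate postoperative visual-acuity predictions
#'
#' Compares predicted against measured postoperative BCVA (both in logMAR)
#' and computes the standard error battery: mean absolute error (MAE), root
#' mean square error (RMSE), the fraction of predictions within
#' \code{re_threshold} logMAR of the truth (closed interval, so an error of
#' exactly 0.30 counts as within), and per-group sensitivity and precision
#' after dichotomising both vectors at \code{cutoff} into good
#' (< cutoff) and poor (>= cutoff) vision. A "correct" eye for the group
#' metrics is one whose predicted and actual acuity fall in the same group;
#' sensitivity divides by the actual group size, precision by the predicted
#' group size. Groups with an empty denominator report \code{NA}.
#'
#' @param data data frame with one row per eye, or \code{NULL} to pass bare
#'   vectors to \code{predicted} / \code{actual}.
#' @param predicted,actual columns of \code{data} (tidy-eval) or numeric
#'   vectors of logMAR acuities, paired by eye.
#' @param re_threshold half-width of the "within" band in logMAR.
#' @param cutoff good/poor boundary in logMAR.
#' @return an object of class \code{va_eval}; see \code{\link[generics]{tidy}}
#'   and \code{\link[generics]{glance}} methods.
#' @examples
#' cohort <- tibble::tibble(pred = c(0.1, 0.4, 0.9), obs = c(0.1, 0.6, 0.8))
#' va_eval(cohort, pred, obs)
#' @export
va_eval <- function(data = NULL, predicted, actual,
                    re_threshold = 0.30, cutoff = 0.30) {
  if (!is.null(data)) {
    predicted <- rlang::eval_tidy(rlang::enquo(predicted), data)
    actual <- rlang::eval_tidy(rlang::enquo(actual), data)
  }
  predicted <- as.numeric(predicted)
  actual <- as.numeric(actual)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) {
    stop("cannot evaluate an empty prediction set", call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(actual)) {
    stop("predicted and actual must not contain missing values", call. = FALSE)
  }
  err <- predicted - actual
  n <- length(err)
  pg <- va_group(predicted, cutoff)
  ag <- va_group(actual, cutoff)
  correct <- pg == ag
  groups <- purrr::map_dfr(c("good", "poor"), function(g) {
    actual_n <- sum(ag == g)
    predicted_n <- sum(pg == g)
    tp <- sum(correct & ag == g)
    tibble::tibble(
      group = g,
      sensitivity = if (actual_n > 0L) tp / actual_n else NA_real_,
      precision = if (predicted_n > 0L) tp / predicted_n else NA_real_,
      correct = tp, actual_n = actual_n, predicted_n = predicted_n
    )
  })
  structure(
    list(
      mae = mean(abs(err)),
      rmse = sqrt(mean(err^2)),
      # closed interval; tolerance guards against binary-representation
      # artefacts at the boundary (0.4 - 0.1 > 0.3 in doubles)
      re_within = mean(abs(err) <= re_threshold + 1e-9),
      re_threshold = re_threshold,
      cutoff = cutoff,
      groups = groups,
      n = n
    ),
    class = "va_eval"
  )
}

#' @export
print.va_eval <- function(x, ...) {
  cat(sprintf("Visual-acuity prediction evaluation (n = %d eyes)\n", x$n))
  cat(sprintf("  MAE  %.4f logMAR\n  RMSE %.4f logMAR\n", x$mae, x$rmse))
  cat(sprintf("  within +/-%.2f logMAR: %.2f%%\n",
              x$re_threshold, 100 * x$re_within))
  cat(sprintf("  groups at %.2f logMAR cutoff:\n", x$cutoff))
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("    %-4s sensitivity %s (%d/%d)  precision %s (%d/%d)\n",
                g$group,
                .fmt_or_na(100 * g$sensitivity, "%.2f%%"),
                g$correct, g$actual_n,
                .fmt_or_na(100 * g$precision, "%.2f%%"),
                g$correct, g$predicted_n))
  }
  invisible(x)
}

.fmt_or_na <- function(x, fmt) if (is.na(x)) "undefined" else sprintf(fmt, x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.va_eval <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      metric = c("mae", "rmse", "re_within"),
      group = NA_character_,
      value = c(x$mae, x$rmse, x$re_within)
    ),
    tidyr::pivot_longer(
      dplyr::select(x$groups, "group", "sensitivity", "precision"),
      cols = c("sensitivity", "precision"),
      names_to = "metric", values_to = "value"
    )[, c("metric", "group", "value")]
  )
}

#' @export
glance.va_eval <- function(x, ...) {
  tibble::tibble(
    mae = x$mae, rmse = x$rmse, re_within = x$re_within, n = x$n
  )
}
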