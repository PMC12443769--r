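#' LOCS III grade ranges
#'
#' Nuclear opalescence is graded 1.0-6.0; cortical and posterior
#' subcapsular (PSC) opacities 1.0-5.0, all at 0.1 resolution.
#'
#' @param subtype one of \code{"nuclear"}, \code{"cortical"}, \code{"psc"}.
#' @return length-2 numeric \code{c(min, max)}.
#' @export
locs_range <- function(subtype = c("nuclear", "cortical", "psc")) {
  subtype <- match.arg(subtype)
  if (subtype == "nuclear") c(1.0, 6.0) else c(1.0, 5.0)
}

#' Validate LOCS III grades
#'
#' @param value numeric vector of grades.
#' @inheritParams locs_range
#' @return \code{value}, invisibly, after range checking.
#' @export
validate_locs <- function(value, subtype = c("nuclear", "cortical", "psc")) {
  subtype <- match.arg(subtype)
  rng <- locs_range(subtype)
  bad <- !is.na(value) & (value < rng[1] | value > rng[2])
  if (any(bad)) {
    stop(sprintf("%s grade(s) outside LOCS III range [%.1f, %.1f]: %s",
                 subtype, rng[1], rng[2],
                 paste(unique(value[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(value)
}

#' Grading prediction error
#'
#' The absolute difference between a predicted grade and the gold-standard
#' grade of the same cataract subtype, in LOCS III units.
#'
#' @param predicted,gold numeric vectors of grades (same subtype, paired).
#' @inheritParams locs_range
#' @return numeric vector of absolute errors.
#' @examples
#' grading_error(4.0, 3.0, "nuclear")
#' @export
grading_error <- function(predicted, gold,
                          subtype = c("nuclear", "cortical", "psc")) {
  subtype <- match.arg(subtype)
  if (length(predicted) != length(gold)) {
    stop("predicted and gold must have equal length", call. = FALSE)
  }
  validate_locs(predicted, subtype)
  validate_locs(gold, subtype)
  abs(predicted - gold)
}

#' Share of grading errors within a tolerance (Re1.0)
#'
#' Percentage of absolute grading errors less than or equal to \code{tol}
#' LOCS III units (default 1.0, the Re1.0 statistic). The boundary counts as
#' within.
#'
#' @param errors numeric vector of non-negative absolute errors.
#' @param tol tolerance in LOCS III units.
#' @return one-row tibble with \code{percent}, \code{within} (numerator) and
#'   \code{n} (denominator).
#' @examples
#' re_within(c(0.5, 1.0, 1.1, 2.0))
#' @export
re_within <- function(errors, tol = 1.0) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("no errors supplied", call. = FALSE)
  if (any(!is.na(errors) & errors < 0)) {
    stop("absolute errors must be non-negative", call. = FALSE)
  }
  k <- sum(errors <= tol + 1e-9)  # closed boundary, robust to 0.1-grid doubles
  tibble::tibble(percent = 100 * k / length(errors),
                 within = k, n = length(errors))
}

#' Cataract surgical indication from LOCS III grades
#'
#' Cataract surgery is indicated when the nuclear grade or the cortical
#' grade strictly exceeds the threshold (default 3.5); a grade of exactly
#' 3.5 does not indicate surgery.
#'
#' @param nuclear,cortical numeric grade vectors.
#' @param threshold LOCS III grade threshold.
#' @return logical vector.
#' @examples
#' surgical_indication(c(4.0, 3.5, 1.0), c(2.0, 3.5, 5.0))
#' @export
surgical_indication <- function(nuclear, cortical, threshold = 3.5) {
  validate_locs(nuclear, "nuclear")
  validate_locs(cortical, "cortical")
  nuclear > threshold | cortical > threshold
}

#' Binary diagnostic metrics
#'
#' Accuracy, sensitivity and specificity from paired logical flags, with the
#' positive class defined by the gold standard:
#' accuracy = (TP + TN) / (TP + TN + FP + FN),
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP).
#' A metric with an empty denominator is reported as \code{NA}.
#'
#' @param predicted,gold logical vectors, paired.
#' @return one-row tibble with the three metrics and the 2x2 cell counts.
#' @export
binary_metrics <- function(predicted, gold) {
  predicted <- as.logical(predicted)
  gold <- as.logical(gold)
  if (length(predicted) != length(gold)) {
    stop("predicted and gold must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) stop("no observations", call. = FALSE)
  tp <- sum(predicted & gold)
  tn <- sum(!predicted & !gold)
  fp <- sum(predicted & !gold)
  fn <- sum(!predicted & gold)
  tibble::tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(2,1) between two raters from the standard mean-squares decomposition
#' of the subjects-by-raters table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{k = 2} raters, \eqn{MS_R} the between-subject, \eqn{MS_C} the
#' between-rater and \eqn{MS_E} the residual mean square. Absolute agreement
#' penalises a systematic offset between raters. Fewer than 3 pairs or a
#' zero-variance table yields \code{NA}.
#'
#' @param x,y numeric vectors: the two raters' values, paired by subject.
#' @return one-row tibble with \code{icc}, the mean squares, \code{n}
#'   subjects and \code{k} raters.
#' @export
icc_agreement <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  k <- 2L
  if (n < 3L) {
    return(tibble::tibble(icc = NA_real_, msr = NA_real_, msc = NA_real_,
                          mse = NA_real_, n = n, k = k))
  }
  mat <- cbind(x, y)
  grand <- mean(mat)
  row_means <- rowMeans(mat)
  col_means <- colMeans(mat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (sst <= 0 || denom == 0) NA_real_ else (msr - mse) / denom
  tibble::tibble(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' ROC curve and AUC
#'
#' Area under the receiver operating characteristic curve for continuous
#' scores against a binary gold label, computed with the Mann-Whitney
#' convention (ties count one half). Higher scores are treated as more
#' indicative of the positive class.
#'
#' @param scores numeric vector.
#' @param labels logical vector (TRUE = positive), paired with scores.
#' @return object of class \code{roc_auc}: list with \code{auc}, a
#'   \code{curve} tibble of (threshold, fpr, tpr) points, \code{n_pos},
#'   \code{n_neg}, and the underlying \code{pROC::roc} fit.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must be paired", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in labels", call. = FALSE)
  }
  fit <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  curve <- tibble::tibble(
    threshold = fit$thresholds,
    fpr = 1 - fit$specificities,
    tpr = fit$sensitivities
  )
  structure(
    list(auc = as.numeric(pROC::auc(fit)), curve = curve,
         n_pos = sum(labels), n_neg = sum(!labels), roc = fit),
    class = "roc_auc"
  )
}

#' @export
print.roc_auc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two correlated AUCs with DeLong's test
#'
#' Both score vectors are measured on the same eyes against the same gold
#' label, so their AUCs are correlated; DeLong's structural-components
#' estimator supplies the variances and covariance, from which a two-sided
#' normal-approximation p-value for the AUC difference is formed. DeLong
#' 95\% confidence intervals for each single AUC are also reported.
#'
#' @param scores_a,scores_b numeric score vectors, paired by eye.
#' @param labels logical gold labels.
#' @param conf_level confidence level for the single-AUC intervals.
#' @return object of class \code{delong_test}: \code{auc_a}, \code{auc_b},
#'   \code{var_a}, \code{var_b}, \code{cov_ab}, \code{var_diff}, \code{z},
#'   \code{p_value}, \code{ci_a}, \code{ci_b}.
#' @export
delong_test <- function(scores_a, scores_b, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("scores and labels must be paired on the same eyes", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in labels", call. = FALSE)
  }
  ra <- pROC::roc(response = labels, predictor = as.numeric(scores_a),
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = labels, predictor = as.numeric(scores_b),
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  # a perfectly separating score has zero DeLong variance; pROC flags this
  # with a warning, but the degenerate case is handled explicitly below
  quiet_degenerate <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("always 0 and can be misleading", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  var_a <- quiet_degenerate(pROC::var(ra, method = "delong"))
  var_b <- quiet_degenerate(pROC::var(rb, method = "delong"))
  cov_ab <- quiet_degenerate(pROC::cov(ra, rb, method = "delong"))
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  var_diff <- var_a + var_b - 2 * cov_ab
  d <- auc_a - auc_b
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) < sqrt(.Machine$double.eps)) {
      z <- 0; p <- 1
    } else {
      warning("degenerate variance of the AUC difference; p-value undefined",
              call. = FALSE)
      z <- NA_real_; p <- NA_real_
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  ci <- function(auc, v) {
    half <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(v)
    c(max(0, auc - half), min(1, auc + half))
  }
  structure(
    list(auc_a = auc_a, auc_b = auc_b, var_a = var_a, var_b = var_b,
         cov_ab = cov_ab, var_diff = var_diff, z = z, p_value = p,
         ci_a = ci(auc_a, var_a), ci_b = ci(auc_b, var_b),
         conf_level = conf_level),
    class = "delong_test"
  )
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong comparison of correlated AUCs\n"))
  cat(sprintf("  AUC A = %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$auc_a, 100 * x$conf_level, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  AUC B = %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$auc_b, 100 * x$conf_level, x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  difference %.4f, z = %s, p = %s\n", x$auc_a - x$auc_b,
              .fmt_or_na(x$z, "%.3f"), .fmt_or_na(x$p_value, "%.4g")))
  invisible(x)
}

#' Full grading evaluation for one cataract subtype
#'
#' Runs the evaluation battery used for automated LOCS III grading against a
#' gold standard: Re1.0 (share of absolute errors <= 1.0 grade), ICC(2,1),
#' and — after converting both graders' output to a binary surgical
#' indication at \code{threshold} — accuracy, sensitivity, specificity and
#' the AUC of the continuous predicted grade against the gold indication,
#' with a DeLong confidence interval. PSC grades are carried in cohort data
#' but not evaluated by this battery.
#'
#' @param data data frame with one row per eye, or \code{NULL} for vectors.
#' @param predicted,gold grade columns (tidy-eval) or numeric vectors.
#' @inheritParams locs_range
#' @param threshold surgical-indication grade threshold.
#' @param re_tol Re tolerance in LOCS III units.
#' @return object of class \code{grading_eval}.
#' @examples
#' set.seed(1)
#' g <- round(runif(40, 1, 5.8), 1)
#' p <- pmin(6, pmax(1, g + round(stats::rnorm(40, 0, 0.4), 1)))
#' grading_eval(NULL, p, g, subtype = "nuclear")
#' @export
grading_eval <- function(data = NULL, predicted, gold,
                         subtype = c("nuclear", "cortical"),
                         threshold = 3.5, re_tol = 1.0) {
  subtype <- match.arg(subtype)
  if (!is.null(data)) {
    predicted <- rlang::eval_tidy(rlang::enquo(predicted), data)
    gold <- rlang::eval_tidy(rlang::enquo(gold), data)
  }
  err <- grading_error(predicted, gold, subtype)
  re <- re_within(err, tol = re_tol)
  icc <- icc_agreement(predicted, gold)
  gold_flag <- gold > threshold
  pred_flag <- predicted > threshold
  bm <- binary_metrics(pred_flag, gold_flag)
  auc <- NULL
  if (length(unique(gold_flag)) == 2L) {
    dl <- delong_test(predicted, predicted, gold_flag)
    auc <- list(auc = dl$auc_a, ci = dl$ci_a)
  }
  structure(
    list(subtype = subtype, threshold = threshold, re = re, re_tol = re_tol,
         icc = icc, binary = bm, auc = auc, n = length(err)),
    class = "grading_eval"
  )
}

#' @export
print.grading_eval <- function(x, ...) {
  cat(sprintf("LOCS III %s grading evaluation (n = %d eyes)\n",
              x$subtype, x$n))
  cat(sprintf("  Re%.1f: %.2f%% (%d/%d)\n", x$re_tol,
              x$re$percent, x$re$within, x$re$n))
  cat(sprintf("  ICC(2,1): %s\n", .fmt_or_na(x$icc$icc, "%.3f")))
  cat(sprintf("  indication at >%.1f: accuracy %s, sensitivity %s, specificity %s\n",
              x$threshold,
              .fmt_or_na(x$binary$accuracy, "%.2f"),
              .fmt_or_na(x$binary$sensitivity, "%.2f"),
              .fmt_or_na(x$binary$specificity, "%.2f")))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC: %.3f (95%% CI %.3f-%.3f)\n",
                x$auc$auc, x$auc$ci[1], x$auc$ci[2]))
  }
  invisible(x)
}

#' @export
tidy.grading_eval <- function(x, ...) {
  tibble::tibble(
    subtype = x$subtype,
    metric = c("re_percent", "icc", "accuracy", "sensitivity", "specificity",
               "auc"),
    value = c(x$re$percent, x$icc$icc, x$binary$accuracy,
              x$binary$sensitivity, x$binary$specificity,
              if (is.null(x$auc)) NA_real_ else x$auc$auc)
  )
}

#' @export
glance.grading_eval <- function(x, ...) {
  tibble::tibble(
    subtype = x$subtype,
    re_percent = x$re$percent,
    icc = x$icc$icc,
    accuracy = x$binary$accuracy,
    sensitivity = x$binary$sensitivity,
    specificity = x$binary$specificity,
    auc = if (is.null(x$auc)) NA_real_ else x$auc$auc,
    n = x$n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
autoplot.roc_auc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}
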