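#' Round half away from zero
#'
#' Reported kappas are conventionally rounded half-up (0.8115 -> 0.812),
#' unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Cross-tabulate two raters' surgical decisions
#'
#' Builds the 4x4 confusion matrix of decision categories with a fixed
#' convention: rows are the gold standard, columns the comparator, category
#' order 0, 1, 2, 3.
#'
#' @param data data frame, or \code{NULL} to pass bare vectors.
#' @param gold,comparator decision columns (tidy-eval) or vectors coercible
#'   to categories 0-3, paired by eye.
#' @return object of class \code{confusion_matrix}: the 4x4 integer matrix
#'   with attributes \code{n} (total) and \code{agree} (diagonal sum).
#' @examples
#' confusion_matrix(NULL, c(1, 1, 2), c(1, 1, 2))
#' @export
confusion_matrix <- function(data = NULL, gold, comparator) {
  if (!is.null(data)) {
    gold <- rlang::eval_tidy(rlang::enquo(gold), data)
    comparator <- rlang::eval_tidy(rlang::enquo(comparator), data)
  }
  gold <- decision_factor(gold)
  comparator <- decision_factor(comparator)
  if (length(gold) != length(comparator)) {
    stop("gold and comparator must be paired by eye", call. = FALSE)
  }
  if (length(gold) == 0L) stop("no decisions to tabulate", call. = FALSE)
  if (anyNA(gold) || anyNA(comparator)) {
    stop("decisions must not be missing", call. = FALSE)
  }
  m <- table(gold = gold, comparator = comparator)
  m <- matrix(as.integer(m), nrow = 4, ncol = 4,
              dimnames = list(gold = 0:3, comparator = 0:3))
  structure(m, class = c("confusion_matrix", "matrix"),
            n = sum(m), agree = sum(diag(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Decision confusion matrix (rows = gold, cols = comparator), n = %d, agreement = %d\n",
              attr(x, "n"), attr(x, "agree")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

.agreement_result <- function(po, pe, agree, n) {
  kappa <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  structure(
    list(po = po, pe = pe, kappa = kappa,
         kappa_reported = if (is.na(kappa)) NA_real_ else round_half_up(kappa, 3),
         consistency_pct = 100 * po, agree = agree, n = n,
         note = if (pe >= 1) "both raters constant: chance agreement is 1, kappa undefined" else NULL),
    class = "agreement"
  )
}

#' Cohen's kappa and percent consistency
#'
#' Unweighted Cohen's kappa from a 4x4 decision confusion matrix (or from
#' two paired decision vectors): observed agreement \eqn{p_o} is the
#' diagonal fraction, chance agreement \eqn{p_e = \sum_k r_k c_k / n^2} from
#' the marginal products, and \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. When
#' both raters are constant (\eqn{p_e = 1}) kappa is undefined and reported
#' as \code{NA} with a diagnostic note.
#'
#' @param x a \code{\link{confusion_matrix}}, or a gold decision vector.
#' @param comparator comparator decision vector when \code{x} is a vector.
#' @return object of class \code{agreement}: \code{po}, \code{pe},
#'   \code{kappa} (raw), \code{kappa_reported} (3 decimals, half-up),
#'   \code{consistency_pct}, \code{agree}, \code{n}.
#' @examples
#' cohen_kappa(c(0, 1, 1, 2), c(0, 1, 1, 3))
#' @export
cohen_kappa <- function(x, comparator = NULL) {
  if (!inherits(x, "confusion_matrix")) {
    x <- confusion_matrix(NULL, x, comparator)
  }
  n <- attr(x, "n")
  agree <- attr(x, "agree")
  po <- agree / n
  pe <- sum(rowSums(x) * colSums(x)) / n^2
  .agreement_result(po, pe, agree, n)
}

#' Reconstruct kappa from marginal counts and an agreement count
#'
#' Cohen's kappa depends on the full cross-tabulation only through its
#' marginals and its diagonal sum, so published per-category decision counts
#' plus a reported agreement count determine kappa exactly.
#'
#' @param gold_counts,comparator_counts integer vectors of per-category
#'   counts (same length K, both summing to \code{n}).
#' @param agree number of agreeing eyes.
#' @param n total number of eyes.
#' @return object of class \code{agreement} (see \code{\link{cohen_kappa}}).
#' @examples
#' kappa_from_marginals(c(1, 95, 5, 6), c(1, 96, 2, 8), 103, 107)
#' @export
kappa_from_marginals <- function(gold_counts, comparator_counts, agree, n) {
  gold_counts <- as.numeric(gold_counts)
  comparator_counts <- as.numeric(comparator_counts)
  if (length(gold_counts) != length(comparator_counts)) {
    stop("marginal vectors must have the same length", call. = FALSE)
  }
  if (sum(gold_counts) != n || sum(comparator_counts) != n) {
    stop(sprintf("marginals must sum to n = %d (got %g and %g)",
                 n, sum(gold_counts), sum(comparator_counts)), call. = FALSE)
  }
  if (agree < 0 || agree > n) {
    stop("agree must lie in [0, n]", call. = FALSE)
  }
  po <- agree / n
  pe <- sum(gold_counts * comparator_counts) / n^2
  .agreement_result(po, pe, agree, n)
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Agreement vs gold standard: %.2f%% (%d/%d)\n",
              x$consistency_pct, x$agree, x$n))
  cat(sprintf("  po = %.4f, pe = %.4f, Cohen's kappa = %s\n",
              x$po, x$pe, .fmt_or_na(x$kappa_reported, "%.3f")))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.agreement <- function(x, ...) {
  tibble::tibble(
    metric = c("po", "pe", "kappa", "consistency_pct"),
    value = c(x$po, x$pe, x$kappa, x$consistency_pct)
  )
}

#' @export
glance.agreement <- function(x, ...) {
  tibble::tibble(po = x$po, pe = x$pe, kappa = x$kappa,
                 consistency_pct = x$consistency_pct,
                 agree = x$agree, n = x$n)
}

#' Percent consistency between two decision vectors
#'
#' @param gold,comparator decision vectors, paired by eye.
#' @return one-row tibble: \code{percent} (2-decimal scale retained as raw
#'   value), \code{matches}, \code{n}.
#' @examples
#' consistency(c(1, 1, 0), c(1, 2, 0))
#' @export
consistency <- function(gold, comparator) {
  gold <- decision_factor(gold)
  comparator <- decision_factor(comparator)
  if (length(gold) != length(comparator)) {
    stop("gold and comparator must be paired by eye", call. = FALSE)
  }
  if (length(gold) == 0L) stop("no decisions to compare", call. = FALSE)
  matches <- sum(gold == comparator)
  tibble::tibble(percent = 100 * matches / length(gold),
                 matches = matches, n = length(gold))
}

#' Restrict a cohort to special cases
#'
#' Special cases are eyes whose gold-standard decision is not plain cataract
#' surgery: category 0 (no surgery), 2 (retinal surgery) or 3 (combined
#' surgery). Downstream consistency and kappa are computed on this subset,
#' still on the full 4-category table (a comparator may answer 1).
#'
#' @param data cohort data frame.
#' @param gold_col name of the gold decision column, default
#'   \code{"decision_gold"}.
#' @return filtered data frame.
#' @export
special_cases <- function(data, gold_col = "decision_gold") {
  if (!gold_col %in% names(data)) {
    stop("cohort has no gold decision column '", gold_col, "'", call. = FALSE)
  }
  g <- data[[gold_col]]
  if (anyNA(g)) {
    stop("every record needs a gold decision to build the special-case subset",
         call. = FALSE)
  }
  decision_factor(g)  # validates categories
  data[as.integer(as.character(decision_factor(g))) %in% c(0L, 2L, 3L), ,
       drop = FALSE]
}

#' Heatmap of a decision confusion matrix
#'
#' @param object a \code{\link{confusion_matrix}}.
#' @param ... unused.
#' @return a ggplot: annotated 4x4 count grid, gold standard on the y axis.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("gold", "comparator", "count")
  df$count <- as.integer(df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparator, y = .data$gold,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$gold))) +
    ggplot2::labs(x = "Comparator decision", y = "Gold-standard decision",
                  fill = "Eyes",
                  title = sprintf("Decision agreement (n = %d, %d agree)",
                                  attr(object, "n"), attr(object, "agree"))) +
    ggplot2::theme_minimal()
}

#' Export a confusion matrix as heatmap image and CSV
#'
#' Writes the annotated 4x4 count grid as an image (format inferred from the
#' file extension) and the underlying counts as CSV with gold categories in
#' rows. Both outputs are deterministic functions of the matrix.
#'
#' @param x a \code{\link{confusion_matrix}}.
#' @param image_path path for the image (\code{.png} or \code{.pdf}), or
#'   \code{NULL} to skip the image.
#' @param csv_path path for the counts CSV, or \code{NULL} to skip.
#' @return invisibly, a character vector of the files written.
#' @export
export_heatmap <- function(x, image_path = NULL, csv_path = NULL) {
  stopifnot(inherits(x, "confusion_matrix"))
  written <- character()
  if (!is.null(csv_path)) {
    df <- tibble::as_tibble(unclass(x), rownames = "gold")
    names(df) <- c("gold", paste0("comparator_", 0:3))
    readr::write_csv(df, csv_path)
    written <- c(written, csv_path)
  }
  if (!is.null(image_path)) {
    p <- autoplot.confusion_matrix(x)
    ggplot2::ggsave(image_path, plot = p, width = 5, height = 4, dpi = 150)
    written <- c(written, image_path)
  }
  invisible(written)
}

#' Read a confusion-matrix CSV written by \code{\link{export_heatmap}}
#'
#' @param path CSV path.
#' @return a \code{\link{confusion_matrix}}.
#' @export
read_confusion_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, paste0("comparator_", 0:3)])
  dimnames(m) <- list(gold = 0:3, comparator = 0:3)
  storage.mode(m) <- "integer"
  structure(m, class = c("confusion_matrix", "matrix"),
            n = sum(m), agree = sum(diag(m)))
}
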