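#' Calibrate a grading-error scale from a target Re1.0
#'
#' The generator models automated grading error as a Gaussian rounded to the
#' 0.1 LOCS III step, so a rounded error is within 1.0 exactly when the raw
#' error is within 1.05. This solves for the sigma at which
#' \eqn{P(|\mathrm{round}_{0.1}(N(0,\sigma))| \le 1.0)} equals
#' \code{target_re10}/100, by bisection to 1e-6 on the probability.
#'
#' @param target_re10 target Re1.0 percentage, strictly between 0 and 100.
#' @return sigma in LOCS III units.
#' @examples
#' calibrate_sigma_re10(99.07)
#' @export
calibrate_sigma_re10 <- function(target_re10) {
  if (!is.finite(target_re10) || target_re10 <= 0 || target_re10 >= 100) {
    stop("target_re10 must lie strictly between 0 and 100", call. = FALSE)
  }
  target <- target_re10 / 100
  prob <- function(sigma) 2 * stats::pnorm(1.05 / sigma) - 1
  lo <- 1e-6; hi <- 1e3   # prob(lo) ~ 1, prob(hi) ~ 0; decreasing in sigma
  repeat {
    mid <- (lo + hi) / 2
    p <- prob(mid)
    if (abs(p - target) < 1e-6 || (hi - lo) < 1e-12) return(mid)
    if (p > target) lo <- mid else hi <- mid
  }
}

#' Calibrate a prediction-error scale from a target MAE
#'
#' For zero-mean Gaussian prediction error, \eqn{E|X| = \sigma\sqrt{2/\pi}},
#' so the sigma reproducing a target mean absolute error is
#' \eqn{\mathrm{MAE}\cdot\sqrt{\pi/2}}.
#'
#' @param target_mae target mean absolute error (logMAR).
#' @return sigma in logMAR.
#' @examples
#' calibrate_sigma_mae(0.156)
#' @export
calibrate_sigma_mae <- function(target_mae) {
  if (!is.finite(target_mae) || target_mae < 0) {
    stop("target_mae must be non-negative", call. = FALSE)
  }
  target_mae * sqrt(pi / 2)
}

#' Default per-rater decision confusion matrices
#'
#' Row-stochastic 4x4 matrices giving, for each gold category (row), the
#' probability of each answered category (column). The default single
#' \code{ai} rater is a synthetic stand-in shaped like a strong rater:
#' near-perfect on plain cataract-surgery eyes and noisier on the rarer
#' special categories, with confusions flowing mostly toward category 1.
#' The true rater-by-gold cross-tabulations of any given clinic are not
#' identifiable from marginal summaries, so treat these as illustrative.
#'
#' @return named list of 4x4 matrices.
#' @export
default_rater_confusion <- function() {
  ai <- rbind(
    c(0.75, 0.15, 0.05, 0.05),
    c(0.010, 0.970, 0.005, 0.015),
    c(0.05, 0.15, 0.60, 0.20),
    c(0.02, 0.08, 0.10, 0.80)
  )
  dimnames(ai) <- list(gold = 0:3, answer = 0:3)
  list(ai = ai)
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults encode the study conditions the evaluation framework assumes:
#' category prevalence proportional to the internal gold-standard decision
#' marginals (1, 95, 5, 6 of 107 eyes); automated-grading error scales
#' calibrated so that Re1.0 is 99.07\% (nuclear) and 88.79\% (cortical);
#' visual-acuity prediction error scale 0.1955 logMAR so the expected MAE is
#' 0.156 logMAR; axial length from a truncated normal (mean 28.5, sd 1.5,
#' minimum 26.0 mm).
#'
#' @param n cohort size (>= 1).
#' @param prevalence probability 4-vector over decision categories 0-3.
#' @param sigma_nuclear,sigma_cortical,sigma_psc grading-error scales in
#'   LOCS III units.
#' @param sigma_pred VA-prediction error scale in logMAR.
#' @param rater_confusion named list of row-stochastic 4x4 matrices, one per
#'   simulated rater; \code{list()} for no rated decisions.
#' @param al_mean,al_sd,al_min axial-length distribution (mm), truncated
#'   below at \code{al_min}.
#' @param seed integer seed; one global seed drives named substreams
#'   (per-field) so adding fields never perturbs existing draws.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n = 107,
                       prevalence = c(1, 95, 5, 6) / 107,
                       sigma_nuclear = calibrate_sigma_re10(99.07),
                       sigma_cortical = calibrate_sigma_re10(88.79),
                       sigma_psc = sigma_cortical,
                       sigma_pred = calibrate_sigma_mae(0.156),
                       rater_confusion = default_rater_confusion(),
                       al_mean = 28.5, al_sd = 1.5, al_min = 26.0,
                       seed = 1L) {
  problems <- character()
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    problems <- c(problems, "n must be a positive integer")
  }
  if (length(prevalence) != 4 || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-8) {
    problems <- c(problems,
                  "prevalence must be 4 non-negative probabilities summing to 1")
  }
  for (s in c(sigma_nuclear = sigma_nuclear, sigma_cortical = sigma_cortical,
              sigma_psc = sigma_psc, sigma_pred = sigma_pred)) {
    if (!is.finite(s) || s < 0) {
      problems <- c(problems, "error scales (sigma) must be finite and >= 0")
      break
    }
  }
  if (!is.list(rater_confusion) ||
      (length(rater_confusion) > 0 && is.null(names(rater_confusion)))) {
    problems <- c(problems, "rater_confusion must be a named list of matrices")
  } else {
    for (nm in names(rater_confusion)) {
      m <- rater_confusion[[nm]]
      if (!is.matrix(m) || !all(dim(m) == c(4, 4)) || any(m < 0) ||
          any(abs(rowSums(m) - 1) > 1e-8)) {
        problems <- c(problems, sprintf(
          "rater_confusion[['%s']] must be a row-stochastic 4x4 matrix", nm))
      }
    }
  }
  if (!is.finite(al_mean) || !is.finite(al_sd) || al_sd < 0 ||
      al_min < 26.0 - 1e-9) {
    problems <- c(problems,
                  "axial length needs finite mean, sd >= 0 and min >= 26.0 mm")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    problems <- c(problems, "seed must be a single integer")
  }
  if (length(problems) > 0) {
    stop("invalid simulation configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence,
         sigma_nuclear = sigma_nuclear, sigma_cortical = sigma_cortical,
         sigma_psc = sigma_psc, sigma_pred = sigma_pred,
         rater_confusion = rater_confusion,
         al_mean = al_mean, al_sd = al_sd, al_min = al_min,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort configuration: n = %d, seed = %d\n",
              x$n, x$seed))
  cat(sprintf("  prevalence (0,1,2,3): %s\n",
              paste(sprintf("%.3f", x$prevalence), collapse = ", ")))
  cat(sprintf("  sigma: nuclear %.3f, cortical %.3f, psc %.3f (LOCS III); VA pred %.4f logMAR\n",
              x$sigma_nuclear, x$sigma_cortical, x$sigma_psc, x$sigma_pred))
  cat(sprintf("  axial length: truncN(%.1f, %.1f) >= %.1f mm\n",
              x$al_mean, x$al_sd, x$al_min))
  cat(sprintf("  raters: %s\n",
              if (length(x$rater_confusion) == 0) "(none)"
              else paste(names(x$rater_confusion), collapse = ", ")))
  invisible(x)
}

# deterministic per-field substream seed from the global seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 1000003L)
}

with_substream <- function(seed, name, expr) {
  withr::with_seed(substream_seed(seed, name), expr)
}

round_grid <- function(x, step = 0.1) round(x / step) * step

rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

#' Generate a synthetic highly-myopic cataract cohort
#'
#' Draws one eye record per row with the dependency structure the decision
#' pipeline assumes. Per eye: a gold decision category from the configured
#' prevalence; gold LOCS III grades consistent with that category
#' (cataract-surgical categories 1 and 3 have nuclear grade > 3.5, the
#' others have both nuclear and cortical <= 3.5); automated (AI) grades as
#' gold plus a 0.1-rounded Gaussian error clipped to the LOCS III range;
#' preoperative and actual postoperative BCVA consistent with the category
#' (retinal-pathology categories recover less); a predicted postoperative
#' BCVA as actual plus Gaussian error; OCT findings (categories 2 and 3 get
#' a surgically-mapped finding); axial length from a truncated normal; and
#' one decision column per configured rater drawn from that rater's
#' confusion row for the gold category. Every draw comes from a named
#' substream of the single seed, so the cohort is fully reproducible and
#' adding fields does not perturb existing ones.
#'
#' @param config a \code{\link{sim_config}}.
#' @return cohort tibble; columns \code{eye_id}, \code{axial_length},
#'   \code{preop_bcva}, \code{predicted_postop_bcva},
#'   \code{actual_postop_bcva}, gold/ai grade columns, \code{oct_findings},
#'   \code{decision_gold}, and one \code{decision_<rater>} per rater.
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 20, seed = 42))
#' dplyr::count(cohort, decision_gold)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  seed <- config$seed

  gold_class <- with_substream(seed, "gold_class",
    sample(0:3, n, replace = TRUE, prob = config$prevalence))
  cataract <- gold_class %in% c(1L, 3L)
  retinal <- gold_class %in% c(2L, 3L)

  # gold grades on the 0.1 grid, consistent with the decision category
  nuclear_gold <- with_substream(seed, "nuclear_gold", {
    v <- numeric(n)
    v[cataract] <- round_grid(stats::runif(sum(cataract), 3.6, 5.5))
    v[!cataract] <- round_grid(stats::runif(sum(!cataract), 1.0, 3.4))
    v
  })
  cortical_gold <- with_substream(seed, "cortical_gold", {
    v <- numeric(n)
    v[cataract] <- round_grid(stats::runif(sum(cataract), 1.0, 5.0))
    v[!cataract] <- round_grid(stats::runif(sum(!cataract), 1.0, 3.4))
    v
  })
  psc_gold <- with_substream(seed, "psc_gold",
    round_grid(stats::runif(n, 1.0, 4.0)))

  ai_grade <- function(gold, sigma, subtype, stream) {
    rng <- locs_range(subtype)
    err <- with_substream(seed, stream,
      round_grid(stats::rnorm(length(gold), 0, sigma)))
    pmin(pmax(gold + err, rng[1]), rng[2])
  }
  nuclear_ai <- ai_grade(nuclear_gold, config$sigma_nuclear, "nuclear",
                         "nuclear_ai_err")
  cortical_ai <- ai_grade(cortical_gold, config$sigma_cortical, "cortical",
                          "cortical_ai_err")
  psc_ai <- ai_grade(psc_gold, config$sigma_psc, "psc", "psc_ai_err")

  # preoperative vision: good for category 0 (no indication), poor otherwise
  preop_bcva <- with_substream(seed, "preop_bcva", {
    v <- numeric(n)
    v[gold_class == 0L] <- round(stats::runif(sum(gold_class == 0L),
                                              0.00, 0.28), 2)
    v[gold_class != 0L] <- round(stats::runif(sum(gold_class != 0L),
                                              0.40, 1.50), 2)
    v
  })
  # actual postoperative vision: cataract-only eyes recover well; eyes with
  # retinal pathology recover less
  actual_postop_bcva <- with_substream(seed, "actual_postop_bcva", {
    v <- numeric(n)
    v[gold_class == 0L] <- preop_bcva[gold_class == 0L]
    v[gold_class == 1L] <- round(stats::runif(sum(gold_class == 1L),
                                              0.00, 0.30), 2)
    v[retinal] <- round(stats::runif(sum(retinal), 0.30, 1.00), 2)
    v
  })
  predicted_postop_bcva <- with_substream(seed, "predicted_postop_bcva",
    actual_postop_bcva + stats::rnorm(n, 0, config$sigma_pred))

  retinal_labels <- setdiff(
    names(oct_default_map())[oct_default_map() == "retinal_surgery"], NULL)
  oct_findings <- with_substream(seed, "oct_findings", {
    v <- character(n)
    v[retinal] <- sample(retinal_labels, sum(retinal), replace = TRUE)
    benign <- sample(c("none", "cnv"), sum(!retinal), replace = TRUE,
                     prob = c(0.9, 0.1))
    v[!retinal] <- benign
    v
  })

  # inclusion criterion is strict (AL > min), so keep rounded values above it
  axial_length <- with_substream(seed, "axial_length",
    pmax(round(rtrunc_norm(n, config$al_mean, config$al_sd, config$al_min), 2),
         config$al_min + 0.01))

  cohort <- tibble::tibble(
    eye_id = sprintf("eye%05d", seq_len(n)),
    axial_length = axial_length,
    preop_bcva = preop_bcva,
    predicted_postop_bcva = predicted_postop_bcva,
    actual_postop_bcva = actual_postop_bcva,
    nuclear_gold = nuclear_gold, cortical_gold = cortical_gold,
    psc_gold = psc_gold,
    nuclear_ai = nuclear_ai, cortical_ai = cortical_ai, psc_ai = psc_ai,
    oct_findings = oct_findings,
    decision_gold = gold_class
  )

  for (rater in names(config$rater_confusion)) {
    m <- config$rater_confusion[[rater]]
    cohort[[paste0("decision_", rater)]] <- with_substream(
      seed, paste0("decision_", rater), {
        vapply(gold_class, function(g) {
          sample(0:3, 1L, prob = m[g + 1L, ])
        }, integer(1))
      })
  }
  cohort
}
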