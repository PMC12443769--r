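# builders for per-eye records used across the suite

make_eye <- function(eye_id = "e1", axial_length = 27,
                     preop_bcva = 0.8, predicted_postop_bcva = 0.2,
                     actual_postop_bcva = 0.25,
                     nuclear_ai = 4.5, cortical_ai = 2.0, psc_ai = 1.5,
                     nuclear_gold = nuclear_ai, cortical_gold = cortical_ai,
                     psc_gold = psc_ai,
                     oct_findings = "none", decision_gold = NA_integer_) {
  tibble::tibble(
    eye_id = eye_id, axial_length = axial_length,
    preop_bcva = preop_bcva,
    predicted_postop_bcva = predicted_postop_bcva,
    actual_postop_bcva = actual_postop_bcva,
    nuclear_ai = nuclear_ai, cortical_ai = cortical_ai, psc_ai = psc_ai,
    nuclear_gold = nuclear_gold, cortical_gold = cortical_gold,
    psc_gold = psc_gold,
    oct_findings = oct_findings, decision_gold = decision_gold
  )
}

# a random but valid eye record, for property-style loops
random_eye <- function(id) {
  retinal <- sample(c(TRUE, FALSE), 1)
  make_eye(
    eye_id = id,
    axial_length = round(runif(1, 26.1, 33), 2),
    preop_bcva = round(runif(1, 0, 2), 2),
    predicted_postop_bcva = round(runif(1, 0, 2), 2),
    nuclear_ai = round(runif(1, 1, 6), 1),
    cortical_ai = round(runif(1, 1, 5), 1),
    oct_findings = if (retinal) {
      sample(names(oct_default_map())[oct_default_map() == "retinal_surgery"], 1)
    } else {
      sample(c("none", "cnv", ""), 1)
    }
  )
}

random_cohort <- function(n) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) random_eye(sprintf("r%03d", i))))
}

# exhaustive pairwise-concordance AUC (Mann-Whitney, ties = 1/2)
auc_concordance <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}
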