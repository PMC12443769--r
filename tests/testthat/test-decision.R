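test_that("the rule table maps the canonical single-eye cases", {
  # good preop vision, clear retina: stops at step 1 with category 0
  quiet <- make_eye(preop_bcva = 0.10, predicted_postop_bcva = NA_real_,
                    nuclear_ai = 2.0, cortical_ai = 2.0)
  expect_equal(as.character(decide(quiet)$category), "0")

  # significant cataract, meaningful predicted gain: cataract surgery
  cat_eye <- make_eye(preop_bcva = 0.8, predicted_postop_bcva = 0.2,
                      nuclear_ai = 4.5, cortical_ai = 2.0, axial_length = 27)
  expect_equal(as.character(decide(cat_eye)$category), "1")

  # retinal pathology without significant cataract: retinal surgery
  ret_eye <- make_eye(preop_bcva = 1.0, predicted_postop_bcva = 0.9,
                      nuclear_ai = 2.0, cortical_ai = 2.0,
                      oct_findings = "foveal_retinal_detachment")
  expect_equal(as.character(decide(ret_eye)$category), "2")

  # retinal pathology plus significant cataract: combined surgery
  comb_eye <- make_eye(preop_bcva = 1.2, predicted_postop_bcva = 0.3,
                       nuclear_ai = 4.0, cortical_ai = 2.0,
                       oct_findings = "macular_hole")
  expect_equal(as.character(decide(comb_eye)$category), "3")
})

test_that("axial-length caution withholds cataract surgery without predicted gain", {
  base <- make_eye(preop_bcva = 0.8, predicted_postop_bcva = 0.75,
                   nuclear_ai = 4.5, cortical_ai = 2.0)
  below <- dplyr::mutate(base, axial_length = 29.5)
  above <- dplyr::mutate(base, axial_length = 31.0)
  expect_equal(as.character(decide(below)$category), "1")
  expect_equal(as.character(decide(above)$category), "0")
  # with meaningful gain the caution does not apply
  gain <- dplyr::mutate(above, predicted_postop_bcva = 0.2)
  expect_equal(as.character(decide(gain)$category), "1")
})

test_that("decision errors name their cause", {
  needs_pred <- make_eye(preop_bcva = 0.8, predicted_postop_bcva = NA_real_)
  expect_error(decide(needs_pred), "postoperative visual-acuity prediction")
  unknown <- make_eye(oct_findings = "weird_label")
  expect_error(decide(unknown), "weird_label")
  expect_error(decide(make_eye()[, -2]), "axial_length")
  expect_error(decision_config(grade_threshold = -1), "positive")
  expect_error(decision_config(oct_surgical_map = c(none = "maybe")),
               "retinal_surgery")
})

test_that("batch decisions are empty-safe, order-invariant and deterministic", {
  expect_equal(nrow(decide(make_eye()[0, ])), 0L)
  set.seed(88)
  cohort <- random_cohort(40)
  d1 <- decide(cohort)
  d2 <- decide(cohort)
  expect_identical(d1, d2)
  perm <- sample(nrow(cohort))
  dp <- decide(cohort[perm, ])
  expect_equal(dp$category[order(perm)], d1$category)
})

test_that("every valid record yields one category with a trace of at most five steps", {
  set.seed(99)
  cohort <- random_cohort(120)
  d <- decide(cohort)
  expect_equal(nrow(d), 120L)
  expect_false(anyNA(d$category))
  expect_true(all(d$category %in% as.character(0:3)))
  n_steps <- lengths(regmatches(d$trace, gregexpr("S[1-5]", d$trace)))
  expect_true(all(n_steps >= 1 & n_steps <= 5))
})

test_that("the rule is monotone in cataract severity and retinal findings", {
  set.seed(123)
  cohort <- random_cohort(60)
  base <- decide(cohort)
  # raising the nuclear grade to the top never moves an eye from 1 to 0
  worse <- dplyr::mutate(cohort, nuclear_ai = 6.0)
  after <- decide(worse)
  expect_false(any(base$category == "1" & after$category == "0"))
  # adding a surgically-mapped OCT finding never yields category 0 or 1
  with_ret <- dplyr::mutate(cohort, oct_findings = "macular_retinoschisis")
  dret <- decide(with_ret)
  expect_true(all(dret$category %in% c("2", "3")))
})

test_that("gold and AI grade sources agree when the grades agree", {
  set.seed(55)
  cohort <- random_cohort(30)
  cohort$nuclear_gold <- cohort$nuclear_ai
  cohort$cortical_gold <- cohort$cortical_ai
  expect_equal(decide(cohort, grade_source = "ai")$category,
               decide(cohort, grade_source = "gold")$category)
})

test_that("thresholds are configurable and flow through the rule", {
  eye <- make_eye(preop_bcva = 0.8, predicted_postop_bcva = 0.5,
                  nuclear_ai = 3.2, cortical_ai = 2.0)
  expect_equal(as.character(decide(eye)$category), "0")  # 3.2 <= 3.5
  lax <- decision_config(grade_threshold = 3.0)
  expect_equal(as.character(decide(eye, lax)$category), "1")
  # a grade of exactly the threshold never indicates surgery
  at <- make_eye(preop_bcva = 0.8, predicted_postop_bcva = 0.5,
                 nuclear_ai = 3.5, cortical_ai = 3.5)
  expect_equal(as.character(decide(at)$category), "0")
})
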