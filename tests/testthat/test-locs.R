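test_that("grading errors are absolute LOCS III differences with range checks", {
  expect_equal(grading_error(4.0, 3.0, "nuclear"), 1.0)
  expect_equal(grading_error(2.5, 2.5, "cortical"), 0)
  expect_equal(grading_error(1.0, 6.0, "nuclear"), 5.0)
  expect_error(grading_error(6.5, 3.0, "nuclear"), "range")
  expect_error(grading_error(5.5, 3.0, "cortical"), "range")  # cortical tops at 5
  expect_error(grading_error(c(1, 2), 1, "nuclear"), "equal length")
})

test_that("Re1.0 counts boundary errors as within and is order-invariant", {
  expect_equal(re_within(c(0.5, 1.0, 1.1, 2.0))$percent, 50)
  expect_equal(re_within(rep(0, 5))$percent, 100)
  r <- re_within(c(rep(0.2, 106), 1.6))
  expect_equal(r$percent, 100 * 106 / 107, tolerance = 1e-12)
  expect_equal(r$within, 106L)
  set.seed(7)
  e <- runif(30, 0, 2)
  expect_equal(re_within(e)$percent, re_within(sample(e))$percent)
  expect_error(re_within(numeric()), "no errors")
  expect_error(re_within(c(0.2, -0.1)), "non-negative")
})

test_that("surgical indication uses a strict grade threshold on either subtype", {
  expect_equal(surgical_indication(c(4.0, 3.5, 1.0), c(2.0, 3.5, 5.0)),
               c(TRUE, FALSE, TRUE))
  # monotone non-decreasing in each grade
  set.seed(21)
  for (i in 1:25) {
    nuc <- round(runif(1, 1, 5.8), 1)
    cor <- round(runif(1, 1, 4.8), 1)
    base <- surgical_indication(nuc, cor)
    expect_true(surgical_indication(min(nuc + 0.5, 6), cor) >= base)
    expect_true(surgical_indication(nuc, min(cor + 0.5, 5)) >= base)
  }
})

test_that("binary diagnostic metrics match hand-built 2x2 tables", {
  mixed <- c(TRUE, FALSE, TRUE, FALSE)
  perfect <- binary_metrics(mixed, mixed)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  allpos <- binary_metrics(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 0.5)

  half <- binary_metrics(c(TRUE, FALSE, TRUE, FALSE),
                         c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(half$accuracy, 0.5)
  expect_equal(half$sensitivity, 0.5)
  expect_equal(half$specificity, 0.5)

  # no gold positives: sensitivity undefined, not zero
  nopos <- binary_metrics(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(nopos$sensitivity))
  expect_false(is.na(nopos$specificity))
  # permutation invariance
  set.seed(5)
  p <- runif(40) > 0.5; g <- runif(40) > 0.5
  o <- sample(40)
  expect_equal(binary_metrics(p, g), binary_metrics(p[o], g[o]))
})

test_that("ICC(2,1) matches an aov mean-squares oracle and its fixed points", {
  # frozen 6-pair worked set; expected value from the two-way aov
  # decomposition computed independently
  a <- c(2.1, 3.4, 1.8, 4.6, 3.0, 5.2)
  b <- c(2.5, 3.1, 2.2, 4.9, 2.7, 5.6)
  expect_equal(icc_agreement(a, b)$icc, 0.967009765110, tolerance = 1e-9)

  # recompute the oracle in place to guard the frozen constant
  long <- data.frame(y = c(a, b), subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / 6) * (ms[2] - ms[3]))
  expect_equal(icc_agreement(a, b)$icc, oracle, tolerance = 1e-12)

  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_agreement(x, x)$icc, 1)
  expect_equal(icc_agreement(x, x)$icc, icc_agreement(rev(x), rev(x))$icc)
  # absolute agreement penalises a constant offset
  expect_lt(icc_agreement(x, x + 10)$icc, 0.2)
  # column exchange invariance
  expect_equal(icc_agreement(a, b)$icc, icc_agreement(b, a)$icc)
  # degenerate inputs yield an explicit missing marker
  expect_true(is.na(icc_agreement(c(1, 2), c(1, 2))$icc))
  expect_true(is.na(icc_agreement(rep(2, 5), rep(2, 5))$icc))
})

test_that("AUC equals the exhaustive pairwise-concordance oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(FALSE, TRUE), 3))$auc, 0.5)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 0.75)
  set.seed(303)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)  # both classes guaranteed
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_concordance(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC curve endpoints span (0,0) to (1,1)", {
  set.seed(9)
  r <- roc_auc(runif(30), runif(30) > 0.4)
  expect_equal(min(r$curve$fpr), 0)
  expect_equal(max(r$curve$fpr), 1)
  expect_equal(min(r$curve$tpr), 0)
  expect_equal(max(r$curve$tpr), 1)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("DeLong comparison is internally consistent and matches a bootstrap oracle", {
  labels <- rep(c(FALSE, TRUE), each = 4)
  sa <- c(1, 4, 2, 6, 3, 7, 5, 8)
  sb <- c(2, 3, 1, 5, 6, 4, 8, 7)

  # identical scores: zero difference, p = 1
  same <- delong_test(sa, sa, labels)
  expect_equal(same$auc_a, same$auc_b)
  expect_equal(same$p_value, 1)

  dl <- delong_test(sa, sb, labels)
  # AUCs agree exactly with the ROC computation on the same inputs
  expect_equal(dl$auc_a, roc_auc(sa, labels)$auc)
  expect_equal(dl$auc_b, roc_auc(sb, labels)$auc)
  expect_true(dl$ci_a[1] <= dl$auc_a && dl$auc_a <= dl$ci_a[2])
  expect_gte(dl$p_value, 0)
  expect_lte(dl$p_value, 1)

  # stratified bootstrap oracle for the variance of the AUC difference
  pos_i <- which(labels); neg_i <- which(!labels)
  set.seed(2024)
  d <- replicate(100000, {
    i <- c(sample(pos_i, length(pos_i), TRUE),
           sample(neg_i, length(neg_i), TRUE))
    l <- labels[i]
    auc_concordance(sa[i], l) - auc_concordance(sb[i], l)
  })
  expect_equal(var(d), dl$var_diff, tolerance = 0.10)
})

test_that("grading evaluation assembles the full battery per subtype", {
  set.seed(17)
  gold <- round(runif(60, 1, 5.8), 1)
  pred <- pmin(6, pmax(1, gold + round(rnorm(60, 0, 0.5), 1)))
  ev <- grading_eval(NULL, pred, gold, subtype = "nuclear")
  expect_equal(ev$re$n, 60L)
  expect_equal(ev$re$percent,
               re_within(abs(pred - gold))$percent)
  expect_equal(ev$icc$icc, icc_agreement(pred, gold)$icc)
  expect_equal(ev$auc$auc, roc_auc(pred, gold > 3.5)$auc)
  expect_true(ev$auc$ci[1] <= ev$auc$auc && ev$auc$auc <= ev$auc$ci[2])
  gl <- glance(ev)
  expect_equal(gl$n, 60L)
  expect_equal(gl$auc, ev$auc$auc)
  # data-frame-first interface is equivalent
  df <- tibble::tibble(p = pred, g = gold)
  expect_equal(glance(grading_eval(df, p, g, subtype = "nuclear")), gl)
})
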