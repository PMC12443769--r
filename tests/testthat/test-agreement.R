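test_that("confusion matrices tally paired decisions with fixed orientation", {
  m <- confusion_matrix(NULL, c(1, 1, 2), c(1, 1, 2))
  expect_equal(diag(unclass(m)), c(`0` = 0L, `1` = 2L, `2` = 1L, `3` = 0L),
               ignore_attr = TRUE)
  expect_equal(attr(m, "agree"), 3L)

  m0 <- confusion_matrix(NULL, c(0, 1), c(1, 0))
  expect_equal(attr(m0, "agree"), 0L)

  # 10-eye hand tally: rows gold, columns comparator
  gold <- c(0, 0, 1, 1, 1, 2, 2, 3, 3, 3)
  comp <- c(0, 1, 1, 1, 2, 2, 3, 3, 3, 0)
  m10 <- confusion_matrix(NULL, gold, comp)
  expect_equal(unclass(m10)["0", "1"], 1L, ignore_attr = TRUE)
  expect_equal(unclass(m10)["1", "2"], 1L, ignore_attr = TRUE)
  expect_equal(unclass(m10)["3", "0"], 1L, ignore_attr = TRUE)
  expect_equal(attr(m10, "n"), 10L)
  expect_equal(attr(m10, "agree"), 6L)
  expect_equal(rowSums(m10), c(`0` = 2, `1` = 3, `2` = 2, `3` = 3))

  expect_error(confusion_matrix(NULL, c(0, 1), c(1)), "paired")
  expect_error(confusion_matrix(NULL, integer(), integer()), "no decisions")
})

test_that("Cohen's kappa has its textbook fixed points", {
  perfect <- cohen_kappa(c(0, 1, 1, 2, 3), c(0, 1, 1, 2, 3))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$po, 1)

  # statistically independent table: counts = outer product of marginals / n
  ind <- matrix(outer(c(10, 20, 30, 40), c(25, 25, 25, 25)) / 100, 4, 4,
                dimnames = list(gold = 0:3, comparator = 0:3))
  ind <- structure(ind, class = c("confusion_matrix", "matrix"),
                   n = sum(ind), agree = sum(diag(ind)))
  expect_equal(cohen_kappa(ind)$kappa, 0)

  # both raters constant: chance agreement is 1, kappa undefined
  const <- cohen_kappa(rep(1, 10), rep(1, 10))
  expect_true(is.na(const$kappa))
  expect_match(const$note, "constant")
})

test_that("kappa depends on the table only through marginals and the diagonal", {
  set.seed(614)
  for (i in 1:200) {
    m <- matrix(rpois(16, sample(1:40, 1)), 4, 4)
    if (sum(m) == 0) next
    cm <- structure(m, class = c("confusion_matrix", "matrix"),
                    dimnames = list(gold = 0:3, comparator = 0:3),
                    n = sum(m), agree = sum(diag(m)))
    full <- cohen_kappa(cm)
    marg <- kappa_from_marginals(rowSums(m), colSums(m), sum(diag(m)), sum(m))
    expect_identical(full$kappa, marg$kappa)
    expect_identical(full$po, marg$po)
    expect_identical(full$pe, marg$pe)
    if (!is.na(full$kappa)) {
      expect_gte(full$kappa, -1)
      expect_lte(full$kappa, 1)
    }
  }
})

test_that("kappa is invariant under a shared relabelling of the categories", {
  set.seed(71)
  gold <- sample(0:3, 80, replace = TRUE)
  comp <- ifelse(runif(80) < 0.7, gold, sample(0:3, 80, replace = TRUE))
  k0 <- cohen_kappa(gold, comp)$kappa
  perm <- sample(0:3)
  k1 <- cohen_kappa(perm[gold + 1], perm[comp + 1])$kappa
  expect_equal(k0, k1)
})

test_that("published marginal counts reconstruct the reported kappas", {
  internal_gold <- c(1, 95, 5, 6)
  expect_equal(
    kappa_from_marginals(internal_gold, c(1, 96, 2, 8), 103, 107)$kappa_reported,
    0.811)
  external_gold <- c(15, 38, 0, 2)
  expect_equal(
    kappa_from_marginals(external_gold, c(7, 44, 0, 4), 45, 55)$kappa_reported,
    0.556)
  expect_equal(kappa_from_marginals(c(2, 3), c(2, 3), 5, 5)$kappa, 1)
  expect_error(kappa_from_marginals(c(1, 2), c(2, 2), 3, 3), "sum to n")
  expect_error(kappa_from_marginals(c(1, 2), c(1, 2), 5, 3), "\\[0, n\\]")
})

test_that("consistency reports the matching fraction", {
  expect_equal(consistency(c(1, 1, 0), c(1, 2, 0))$percent, 100 * 2 / 3)
  expect_equal(consistency(c(1, 1), c(1, 1))$percent, 100)
  set.seed(31)
  gold <- sample(0:3, 50, replace = TRUE)
  comp <- sample(0:3, 50, replace = TRUE)
  cm <- confusion_matrix(NULL, gold, comp)
  expect_equal(consistency(gold, comp)$percent,
               100 * attr(cm, "agree") / attr(cm, "n"))
  expect_error(consistency(integer(), integer()), "no decisions")
})

test_that("special cases are the eyes whose gold decision is 0, 2 or 3", {
  # cohort shaped like the internal gold marginals (1, 95, 5, 6)
  gold <- rep(0:3, times = c(1, 95, 5, 6))
  cohort <- tibble::tibble(eye_id = seq_along(gold), decision_gold = gold)
  expect_equal(nrow(special_cases(cohort)), 12L)
  ext <- tibble::tibble(eye_id = 1:55,
                        decision_gold = rep(0:3, times = c(15, 38, 0, 2)))
  expect_equal(nrow(special_cases(ext)), 17L)
  all1 <- tibble::tibble(eye_id = 1:5, decision_gold = rep(1, 5))
  expect_equal(nrow(special_cases(all1)), 0L)
  miss <- tibble::tibble(eye_id = 1, decision_gold = NA)
  expect_error(special_cases(miss), "gold decision")
})

test_that("heatmap export writes an image plus a CSV that round-trips", {
  gold <- rep(0:3, times = c(3, 10, 4, 3))
  comp <- c(rep(0, 3), rep(1, 10), rep(2, 4), rep(3, 3))
  cm <- confusion_matrix(NULL, gold, comp)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "cm.csv")
  img <- file.path(dir, "cm.png")
  export_heatmap(cm, image_path = img, csv_path = csv)
  expect_true(file.exists(img) && file.size(img) > 0)
  back <- read_confusion_csv(csv)
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)
  expect_equal(attr(back, "n"), attr(cm, "n"))
  expect_equal(attr(back, "agree"), attr(cm, "agree"))
  # diagonal matrix: all off-diagonal cells zero in the plotted data
  p <- autoplot(cm)
  expect_s3_class(p, "ggplot")
  expect_equal(sum(p$data$count), attr(cm, "n"))
})
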