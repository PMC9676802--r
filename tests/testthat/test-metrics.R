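test_that("the metric suite reproduces known report values", {
  r <- metrics_from_confusion(confusion_matrix(56, 12, 5, 56))
  expect_equal(round_half_up(r$sensitivity), 0.82)
  expect_equal(round_half_up(r$specificity), 0.92)
  expect_equal(round_half_up(r$lr_pos), 10.05)
  expect_equal(round_half_up(r$lr_neg), 0.19)
  expect_equal(round_half_up(r$ppv), 0.92)
  expect_equal(round_half_up(r$npv), 0.82)
  expect_equal(round_half_up(r$accuracy, 3), 0.868)
  expect_equal(round_half_up(r$se_sensitivity), 0.05)
  expect_equal(round_half_up(r$se_specificity), 0.04)

  r2 <- metrics_from_confusion(confusion_matrix(44, 24, 12, 49))
  expect_equal(round_half_up(r2$accuracy, 3), 0.721)
  expect_equal(round_half_up(r2$npv), 0.67)
})

test_that("degenerate confusion matrices are flagged, not fudged", {
  perfect <- metrics_from_confusion(confusion_matrix(10, 0, 0, 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$lr_neg, 0)
  expect_true(perfect$lr_pos_infinite)
  expect_true(is.finite(perfect$lr_pos))  # continuity-corrected companion

  none_called_pd <- metrics_from_confusion(confusion_matrix(0, 5, 0, 5))
  expect_true(is.na(none_called_pd$ppv))
})

test_that("proportion SE follows the binomial closed form", {
  expect_equal(proportion_se(56 / 68, 68), sqrt((56 / 68) * (12 / 68) / 68))
  expect_equal(round_half_up(proportion_se(56 / 68, 68)), 0.05)
  expect_equal(proportion_se(0, 50), 0)
  expect_equal(proportion_se(1, 50), 0)
  expect_equal(proportion_se(0.5, 100), 0.05)
  expect_error(proportion_se(0.5, 0))
})

test_that("confusion matrices reconstruct uniquely from rounded metrics", {
  cm <- reconstruct_confusion(0.82, 0.92, 68, 61)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(56L, 12L, 5L, 56L))
  cm2 <- reconstruct_confusion(0.79, 0.85, 68, 61)
  expect_identical(c(cm2$tp, cm2$tn), c(54L, 52L))
  cm3 <- reconstruct_confusion(1, 1, 10, 10)
  expect_identical(c(cm3$tp, cm3$tn), c(10L, 10L))
  # 99/200 and 100/200 both round to 0.50: multiplicity must be reported
  expect_error(reconstruct_confusion(0.50, 1, 200, 10), "ambiguous")
  # no count of 3 gives a proportion rounding to 0.50
  expect_error(reconstruct_confusion(0.50, 1, 3, 10), "no integer matrix")
})

test_that("reconstruction inverts rounding for random matrices at 68/61", {
  set.seed(61)
  for (i in 1:50) {
    tp <- sample(0:68, 1)
    tn <- sample(0:61, 1)
    cm <- reconstruct_confusion(round_half_up(tp / 68), round_half_up(tn / 61),
                                68, 61)
    expect_identical(c(cm$tp, cm$tn), c(tp, tn))
  }
})

test_that("likelihood ratios and accuracy respect their identities", {
  set.seed(62)
  for (i in 1:50) {
    tp <- sample(0:68, 1); tn <- sample(0:61, 1)
    if (tn == 61 || tn == 0) next  # keep LRs finite and spec > 0
    r <- metrics_from_confusion(confusion_matrix(tp, 68 - tp, 61 - tn, tn))
    j <- r$sensitivity + r$specificity - 1
    expect_identical(r$lr_pos > 1, j > 0)
    expect_identical(r$lr_neg < 1, j > 0)
    expect_equal(r$accuracy,
                 (r$sensitivity * 68 + r$specificity * 61) / 129,
                 tolerance = 1e-12)
  }
})
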