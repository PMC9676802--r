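test_that("sum scores count correct panel responses", {
  co <- toy_cohort(matrix(c(1, 1, 1, 0, 1, 0), 2, byrow = TRUE),
                   matrix(c(0, 0, 0), 1, byrow = TRUE))
  expect_identical(sum_score(co), c(3L, 1L, 0L))
  expect_identical(sum_score(co, panel = c(1, 3)), c(2L, 0L, 0L))
  full <- simulate_cohort(cohort_spec(3, 3, rep(1, 8), rep(1, 8)), seed = 1)
  expect_identical(sum_score(full), rep(8L, 6))
})

test_that("the enumerated toy ROC matches brute force with ties resolved low", {
  scores <- c(2, 3, 6, 5, 7, 8)
  labels <- rep(c("PD", "HS"), each = 3)
  roc <- roc_over_cutoffs(scores, labels)
  # brute-force oracle over every integer threshold
  oracle <- vapply(-1:8, function(t) {
    mean(scores[1:3] <= t) + mean(scores[4:6] > t) - 1
  }, numeric(1))
  expect_equal(roc$points$youden, oracle, tolerance = 1e-12)
  expect_equal(max(roc$points$youden), 2 / 3)
  best <- youden_cutoff(roc)
  # J = 2/3 is attained at t in {3, 4, 6}; the documented rule takes the lowest
  expect_identical(best$threshold, 3L)
  expect_equal(best$youden, 2 / 3)
})

test_that("ROC endpoints and AUC behave for separated and identical scores", {
  sep <- roc_over_cutoffs(c(0, 1, 2, 5, 6, 7), rep(c("PD", "HS"), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(max(sep$points$youden), 1)
  same <- roc_over_cutoffs(c(1, 2, 3, 1, 2, 3), rep(c("PD", "HS"), each = 3))
  expect_equal(same$auc, 0.5)
  expect_error(roc_over_cutoffs(c(1, 2), c("PD", "PD")), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic on the scores", {
  set.seed(101)
  for (i in 1:20) {
    co <- simulate_cohort(default_spec(), seed = 1010 + i)
    s <- sum_score(co, panel = 1:8)
    roc <- roc_over_cutoffs(s, co$labels)
    expect_equal(roc$auc, midrank_auc(-s, co$labels == "PD"),
                 tolerance = 1e-12)
  }
})

test_that("the chosen cut-off maximises J and respects monotonicity", {
  co <- simulate_cohort(default_spec(), seed = 102)
  roc <- roc_over_cutoffs(sum_score(co, 1:10), co$labels)
  best <- youden_cutoff(roc)
  expect_true(all(best$youden >= roc$points$youden - 1e-12))
  expect_true(all(diff(roc$points$sensitivity) >= 0))
  expect_true(all(diff(roc$points$specificity) <= 0))
  # sens(t) + P(score > t | PD) = 1 exactly
  s_pd <- sum_score(co, 1:10)[co$labels == "PD"]
  over <- vapply(roc$points$threshold, function(t) mean(s_pd > t), numeric(1))
  expect_equal(roc$points$sensitivity + over, rep(1, nrow(roc$points)))
})

test_that("the planted-panel cut-off concentrates near the analytic optimum", {
  sp <- default_spec()
  # analytic J over Binomial(8, .3) vs Binomial(8, .8) total scores peaks at 4
  j <- pbinom(0:8, 8, 0.30) - pbinom(0:8, 8, 0.80)
  t_star <- which.max(j) - 1L
  expect_identical(t_star, 4L)
  near <- 0
  for (i in 1:50) {
    co <- simulate_cohort(sp, seed = 1100 + i)
    best <- youden_cutoff(roc_over_cutoffs(sum_score(co, sp$planted_items),
                                           co$labels))
    near <- near + (abs(best$threshold - t_star) <= 1)
  }
  expect_gte(near / 50, 0.9)
})
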