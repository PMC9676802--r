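test_that("Fisher exact p matches hand-enumerated and degenerate cases", {
  expect_equal(as.numeric(fisher_exact_p(contingency_table(5, 5, 5, 5))), 1)
  # margins (10,10|10,10): tables with point prob <= obs are a in {0,1,9,10}
  p <- fisher_exact_p(contingency_table(9, 1, 1, 9))
  expect_equal(as.numeric(p), 202 / 184756, tolerance = 1e-10)
  expect_false(attr(p, "degenerate"))
  # every subject correct: no information, flagged
  pdg <- fisher_exact_p(contingency_table(0, 7, 0, 5))
  expect_equal(as.numeric(pdg), 1)
  expect_true(attr(pdg, "degenerate"))
})

test_that("Fisher exact p equals the enumeration oracle on random tables", {
  set.seed(42)
  for (i in 1:300) {
    tb <- random_table(30)
    expect_equal(as.numeric(fisher_exact_p(tb)),
                 enum_fisher_p(tb$incorrect_pd, tb$correct_pd,
                               tb$incorrect_hs, tb$correct_hs),
                 tolerance = 1e-9)
  }
})

test_that("diagnostic odds ratio follows ad/bc with Haldane correction", {
  d1 <- diagnostic_odds_ratio(contingency_table(4, 6, 2, 3))
  expect_equal(as.numeric(d1), 1)  # identical incorrect odds
  d2 <- diagnostic_odds_ratio(contingency_table(40, 28, 15, 46))
  expect_equal(as.numeric(d2), 1840 / 420, tolerance = 1e-12)
  expect_false(attr(d2, "corrected"))
  d3 <- diagnostic_odds_ratio(contingency_table(40, 28, 0, 61))
  expect_equal(as.numeric(d3), (40.5 * 61.5) / (28.5 * 0.5), tolerance = 1e-12)
  expect_true(attr(d3, "corrected"))
})

test_that("DOR inverts under class swap and is monotone in incorrect_pd", {
  set.seed(7)
  for (i in 1:50) {
    tb <- random_table(25)
    if (any(unlist(tb[1:4]) == 0L)) next
    swapped <- contingency_table(tb$incorrect_hs, tb$correct_hs,
                                 tb$incorrect_pd, tb$correct_pd)
    expect_equal(as.numeric(diagnostic_odds_ratio(swapped)),
                 1 / as.numeric(diagnostic_odds_ratio(tb)), tolerance = 1e-12)
  }
  # shift one PD subject from correct to incorrect: never less discriminative
  for (i in 1:50) {
    tb <- random_table(25)
    if (tb$correct_pd < 2L || tb$incorrect_pd < 1L ||
        tb$incorrect_hs < 1L || tb$correct_hs < 1L) next
    up <- contingency_table(tb$incorrect_pd + 1L, tb$correct_pd - 1L,
                            tb$incorrect_hs, tb$correct_hs)
    expect_gte(as.numeric(diagnostic_odds_ratio(up)),
               as.numeric(diagnostic_odds_ratio(tb)))
    expect_gte(item_auc(up), item_auc(tb))
  }
})

test_that("single-item AUC is (TPR + TNR)/2 and matches the rank oracle", {
  expect_equal(item_auc(contingency_table(3, 3, 4, 4)), 0.5)
  expect_equal(item_auc(contingency_table(6, 0, 0, 9)), 1)
  tb <- contingency_table(56, 12, 5, 56)
  expect_equal(item_auc(tb), (56 / 68 + 56 / 61) / 2, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:50) {
    tb <- random_table(20)
    pred <- c(rep(1, tb$incorrect_pd), rep(0, tb$correct_pd),
              rep(1, tb$incorrect_hs), rep(0, tb$correct_hs))
    is_pd <- rep(c(TRUE, FALSE),
                 c(tb$incorrect_pd + tb$correct_pd,
                   tb$incorrect_hs + tb$correct_hs))
    expect_equal(item_auc(tb), midrank_auc(pred, is_pd), tolerance = 1e-12)
  }
})

test_that("rank_items orders deterministically with index tie-breaks", {
  # item 2 perfect, items 1 and 3 identical and uninformative
  pd <- cbind(c(1, 0, 1, 0), c(0, 0, 0, 0), c(1, 0, 1, 0))
  hs <- cbind(c(1, 0, 1, 0), c(1, 1, 1, 1), c(1, 0, 1, 0))
  co <- toy_cohort(pd, hs)
  for (m in c("dor", "auc")) {
    r <- rank_items(co, m)
    expect_identical(r$order[1], 2L)
    expect_identical(r$order[2:3], c(1L, 3L))  # tie broken to lower index
  }
  expect_error(rank_items(co, "chi2"))
})

test_that("planted items occupy the top ranks under all univariate methods", {
  sp <- default_spec(n_pd = 500, n_hs = 500)
  co <- simulate_cohort(sp, seed = 21)
  for (m in c("fisher", "dor", "auc")) {
    expect_setequal(intersect(top_k(rank_items(co, m), 8), sp$planted_items),
                    sp$planted_items)
  }
})
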