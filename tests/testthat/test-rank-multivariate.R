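test_that("a perfectly discriminating item dominates both multivariate rankings", {
  set.seed(31)
  n <- 200
  noise <- matrix(rbinom(2 * n * 9, 1, 0.5), 2 * n, 9)
  perfect <- rep(c(0, 1), c(n, n))  # PD incorrect, HS correct
  co <- cohort(cbind(perfect, noise, deparse.level = 0),
               rep(c("PD", "HS"), c(n, n)))
  expect_identical(rank_items(co, "logistic")$order[1], 1L)
  expect_identical(rank_items(co, "lda")$order[1], 1L)
})

test_that("ridge symmetry: duplicated item columns share one coefficient", {
  set.seed(32)
  X <- matrix(rbinom(400, 1, 0.5), 100, 4)
  X[, 2] <- X[, 1]
  y <- rbinom(100, 1, plogis(-0.5 + X[, 1] + 0.5 * X[, 3]))
  co <- cohort(X, ifelse(y == 1, "PD", "HS"))
  b <- attr(logistic_ranking(co), "coefficients")
  expect_equal(unname(b[2]), unname(b[3]), tolerance = 1e-6)
})

test_that("ridge logistic with vanishing penalty recovers the glm MLE", {
  set.seed(33)
  X <- matrix(rbinom(900, 1, 0.5), 300, 3)
  y <- rbinom(300, 1, plogis(-0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  co <- cohort(X, ifelse(y == 1, "PD", "HS"))
  ours <- attr(logistic_ranking(co, lambda = 1e-10), "coefficients")
  ref <- coef(glm(y ~ X, family = binomial))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-5)
})

test_that("logistic ranking reports non-convergence instead of looping", {
  set.seed(34)
  X <- matrix(rbinom(200, 1, 0.5), 100, 2)
  co <- cohort(X, rep(c("PD", "HS"), 50))
  expect_error(logistic_ranking(co, max_iter = 1L), "converge")
})

test_that("under the null no item is preferentially selected by logistic", {
  set.seed(35)
  hits <- numeric(40)
  for (i in 1:100) {
    X <- matrix(rbinom(200 * 40, 1, 0.5), 200, 40)
    co <- cohort(X, rep(c("PD", "HS"), each = 100))
    hits[top_k(logistic_ranking(co), 12)] <- hits[top_k(logistic_ranking(co), 12)] + 1
  }
  chance <- 12 / 40
  bound <- chance + 3 * sqrt(chance * (1 - chance) / 100)
  expect_true(all(hits / 100 <= bound))
})

test_that("LDA weight favours the only mean-shifted item", {
  set.seed(36)
  n <- 300
  x1 <- c(rbinom(n, 1, 0.25), rbinom(n, 1, 0.75))
  x2 <- rbinom(2 * n, 1, 0.5)
  co <- cohort(cbind(x1, x2, deparse.level = 0), rep(c("PD", "HS"), each = n))
  w <- abs(attr(lda_ranking(co), "weights"))
  expect_gt(w[1], 5 * w[2])
})

test_that("LDA direction solves its regularised linear system and is", {
  # proportional to the class-mean difference when shrinkage dominates
  set.seed(37)
  co <- simulate_cohort(default_spec(), seed = 37)
  r <- lda_ranking(co)
  w <- attr(r, "weights")
  S <- attr(r, "cov")
  pd <- co$labels == "PD"
  delta <- colMeans(co$responses[pd, ]) - colMeans(co$responses[!pd, ])
  expect_equal(drop(S %*% w), delta, tolerance = 1e-8, ignore_attr = TRUE)

  r2 <- lda_ranking(co, ridge_frac = 1e6)  # ridge swamps S: w ∝ delta
  w2 <- attr(r2, "weights")
  expect_gt(cor(w2, delta), 0.999999)
})

test_that("multivariate rankings are invariant to subject order", {
  co <- simulate_cohort(default_spec(), seed = 38)
  set.seed(38)
  perm <- sample(nrow(co$responses))
  co_p <- cohort(co$responses[perm, ], co$labels[perm],
                 subject_ids = co$subject_ids[perm])
  for (m in c("logistic", "lda")) {
    expect_equal(rank_items(co, m)$scores, rank_items(co_p, m)$scores,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("single-item logistic weight is monotone in the DOR", {
  set.seed(39)
  res <- t(replicate(40, {
    tb <- random_table(25)
    while (any(unlist(tb[1:4]) == 0L) ||
           as.numeric(diagnostic_odds_ratio(tb)) < 1) tb <- random_table(25)
    X <- matrix(rep(c(0, 1, 0, 1),
                    c(tb$incorrect_pd, tb$correct_pd,
                      tb$incorrect_hs, tb$correct_hs)), ncol = 1)
    labs <- rep(c("PD", "HS"),
                c(tb$incorrect_pd + tb$correct_pd,
                  tb$incorrect_hs + tb$correct_hs))
    co <- cohort(X, labs)
    c(dor = as.numeric(diagnostic_odds_ratio(tb)),
      beta = unname(logistic_ranking(co, lambda = 1e-8)$scores))
  }))
  # the small ridge can swap tables with near-identical DORs, so demand
  # near-perfect rather than exact rank agreement
  expect_gt(cor(res[, "dor"], res[, "beta"], method = "spearman"), 0.999)
})

test_that("LDA requires two subjects per class", {
  co <- cohort(matrix(c(0, 1, 1, 0, 1, 1), 3), c("PD", "HS", "HS"))
  expect_error(lda_ranking(co), "2 subjects per class")
})
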