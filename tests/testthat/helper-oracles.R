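# Independent oracles and fixture builders shared across the suite.

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (point-probability rule).
enum_fisher_p <- function(incorrect_pd, correct_pd, incorrect_hs, correct_hs) {
  n1 <- incorrect_pd + correct_pd
  n2 <- incorrect_hs + correct_hs
  m <- incorrect_pd + incorrect_hs
  if (m == 0L || m == n1 + n2) return(1)
  k <- max(0L, m - n2):min(n1, m)
  pr <- dhyper(k, n1, n2, m)
  p_obs <- dhyper(incorrect_pd, n1, n2, m)
  min(sum(pr[pr <= p_obs * (1 + 1e-7)]), 1)
}

# Mann-Whitney AUC with mid-rank ties; higher score => positive class.
midrank_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  (sum(rank(scores)[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small cohort from explicit per-class response matrices.
toy_cohort <- function(pd_rows, hs_rows, item_names = NULL) {
  cohort(rbind(pd_rows, hs_rows),
         c(rep("PD", nrow(pd_rows)), rep("HS", nrow(hs_rows))),
         item_names = item_names)
}

# Random valid contingency table with both class sizes in 2..n_max and
# no structural constraint on the cells.
random_table <- function(n_max = 30) {
  n1 <- sample(2:n_max, 1)
  n2 <- sample(2:n_max, 1)
  a <- sample(0:n1, 1)
  c <- sample(0:n2, 1)
  contingency_table(a, n1 - a, c, n2 - c)
}

# Vote tally reproducing the published count distribution
# {5 votes: 4 items, 4: 4, 3: 4, 1: 9} (57 votes across unequal lists).
published_tally <- function() {
  sets <- list(m1 = c(1:4, 5:8, 9:12, 13, 14),
               m2 = c(1:4, 5:8, 9:12, 15, 16),
               m3 = c(1:4, 5:8, 9:12, 17),
               m4 = c(1:4, 5:8, 18, 19),
               m5 = c(1:4, 20, 21))
  tally_votes(sets, n_items = 40)
}

# The four class-size-68/61 confusion matrices of the published
# comparison table, keyed by classifier x item set.
published_matrices <- function() {
  list(plsda_8 = confusion_matrix(56, 12, 5, 56),
       plsda_40 = confusion_matrix(54, 14, 9, 52),
       tree_8 = confusion_matrix(49, 19, 9, 52),
       tree_40 = confusion_matrix(44, 24, 12, 49))
}
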