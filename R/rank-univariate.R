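#' Two-sided Fisher exact p-value for an item table
#'
#' Exact conditional test of association between class and item
#' correctness: with all margins fixed, the p-value is the sum of
#' hypergeometric probabilities of every table whose point probability
#' does not exceed that of the observed table (the minimum-likelihood
#' two-sided rule, as implemented by [stats::fisher.test()]).
#'
#' A degenerate column margin (every subject correct, or every subject
#' incorrect) carries no information; the p-value is 1 by convention and
#' the result is flagged with `attr(, "degenerate")`.
#'
#' @param tab a [contingency_table()].
#' @return p-value in (0, 1], with attribute `degenerate` (logical).
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  degenerate <- (tab$incorrect_pd + tab$incorrect_hs == 0L) ||
    (tab$correct_pd + tab$correct_hs == 0L)
  if (degenerate) {
    return(structure(1, degenerate = TRUE))
  }
  m <- matrix(c(tab$incorrect_pd, tab$correct_pd,
                tab$incorrect_hs, tab$correct_hs), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  structure(min(p, 1), degenerate = FALSE)
}

#' Diagnostic odds ratio of an item
#'
#' Odds of an incorrect response (the "positive" screening state for PD)
#' in PD divided by the same odds in HS:
#' `(incorrect_pd * correct_hs) / (correct_pd * incorrect_hs)`.
#' When any cell is zero, the Haldane–Anscombe correction adds 0.5 to all
#' four cells before taking the ratio, so the DOR is always finite and
#' positive; the correction is recorded in `attr(, "corrected")`.
#'
#' @param tab a [contingency_table()].
#' @return positive DOR with attribute `corrected` (logical).
#' @export
diagnostic_odds_ratio <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  a <- tab$incorrect_pd; b <- tab$correct_pd
  c <- tab$incorrect_hs; d <- tab$correct_hs
  corrected <- any(c(a, b, c, d) == 0L)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  structure((a * d) / (b * c), corrected = corrected)
}

#' Single-item AUC
#'
#' Area under the ROC curve of the binary rule "incorrect response implies
#' PD". For a binary predictor the ROC has a single interior vertex, so
#' AUC = (sensitivity + specificity) / 2 with
#' sensitivity = incorrect_pd / n_PD and specificity = correct_hs / n_HS;
#' this equals the Mann–Whitney rank statistic on the 0/1 predictor.
#'
#' @param tab a [contingency_table()].
#' @return AUC in \[0, 1\].
#' @export
item_auc <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  tpr <- tab$incorrect_pd / (tab$incorrect_pd + tab$correct_pd)
  tnr <- tab$correct_hs / (tab$incorrect_hs + tab$correct_hs)
  (tpr + tnr) / 2
}

#' Rank battery items by discriminative power
#'
#' Computes one of the five item-ranking statistics for every item of the
#' battery and returns the items ordered from most to least
#' discriminative:
#'
#' * `"fisher"` — two-sided Fisher exact p-value ([fisher_exact_p()]);
#'   ascending p.
#' * `"dor"` — diagnostic odds ratio ([diagnostic_odds_ratio()]), with
#'   Haldane–Anscombe correction on zero cells; descending.
#' * `"auc"` — single-item AUC ([item_auc()]); descending.
#' * `"logistic"` — absolute coefficient in a ridge-penalised logistic
#'   regression on all items jointly; descending (see
#'   [logistic_ranking()]).
#' * `"lda"` — absolute weight in the regularised Fisher linear
#'   discriminant direction; descending (see [lda_ranking()]).
#'
#' Ties are always broken by ascending item number, so every ranking is
#' fully deterministic.
#'
#' @param x a [cohort()].
#' @param method one of `"fisher"`, `"dor"`, `"auc"`, `"logistic"`, `"lda"`.
#' @param ... passed on to [logistic_ranking()] or [lda_ranking()].
#' @return An object of class `"item_ranking"`: list with `method`,
#'   per-item `scores`, `order` (a permutation of item indices, most
#'   discriminative first) and `direction` (the sort sense).
#' @examples
#' co <- simulate_cohort(default_spec(), seed = 1)
#' rank_items(co, "auc")
#' @export
rank_items <- function(x, method = c("fisher", "dor", "auc", "logistic", "lda"),
                       ...) {
  stopifnot(inherits(x, "cohort"))
  method <- match.arg(method)
  if (method %in% c("logistic", "lda")) {
    return(switch(method,
                  logistic = logistic_ranking(x, ...),
                  lda = lda_ranking(x, ...)))
  }
  p <- ncol(x$responses)
  stat <- switch(method, fisher = fisher_exact_p,
                 dor = diagnostic_odds_ratio, auc = item_auc)
  scores <- vapply(seq_len(p),
                   function(j) as.numeric(stat(contingency_for_item(x, j))),
                   numeric(1))
  decreasing <- method != "fisher"
  new_item_ranking(method, scores, decreasing,
                   direction = if (decreasing) "descending score" else "ascending p")
}

# shared constructor: deterministic ordering with ascending-index tie-break
new_item_ranking <- function(method, scores, decreasing, direction) {
  idx <- seq_along(scores)
  ord <- order(if (decreasing) -scores else scores, idx)
  structure(list(method = method, scores = scores, order = ord,
                 direction = direction),
            class = "item_ranking")
}

#' @export
print.item_ranking <- function(x, ...) {
  cat(sprintf("Item ranking by %s (%s, ties to lower item number)\n",
              x$method, x$direction))
  top <- utils::head(x$order, 12)
  cat("Top items:", paste(sprintf("%d (%.3g)", top, x$scores[top]),
                          collapse = ", "), "\n")
  invisible(x)
}
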