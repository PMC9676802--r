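#' Stratified cross-validation of a panel classifier
#'
#' Evaluates a classifier (PLS-DA or the classification tree) on a chosen
#' item subset by stratified k-fold cross-validation: fold labels are
#' dealt within each class from a seeded shuffle, every subject is scored
#' exactly once out-of-fold, and the single pooled confusion matrix —
#' not per-fold averages — yields the diagnostic report. The AUROC comes
#' from the pooled out-of-fold scores by the Mann–Whitney rank statistic
#' with mid-rank tie handling.
#'
#' @param x a [cohort()].
#' @param items item subset (see [fit_plsda()]); `NULL` = full battery.
#' @param classifier `"plsda"` or `"tree"`.
#' @param n_folds number of folds (default 10); must be between 2 and the
#'   smaller class size.
#' @param seed integer seed for the fold shuffle; `NULL` uses the current
#'   RNG state.
#' @param ... passed to [fit_plsda()] or [fit_tree()].
#' @return An object of class `"cv_result"`: `folds` (per-subject fold),
#'   `scores` and `labels` (out-of-fold), `cm` (pooled
#'   [confusion_matrix()]), `report` (a [metrics_from_confusion()]
#'   report carrying the AUROC), `auroc`, `classifier`, `items`.
#' @examples
#' co <- simulate_cohort(default_spec(), seed = 1)
#' cv <- cross_validate(co, items = c(3, 7, 8, 10, 17, 22, 30, 36),
#'                      classifier = "plsda", seed = 42)
#' cv
#' @export
cross_validate <- function(x, items = NULL, classifier = c("plsda", "tree"),
                           n_folds = 10, seed = NULL, ...) {
  stopifnot(inherits(x, "cohort"))
  classifier <- match.arg(classifier)
  if (n_folds < 2 || n_folds > min(x$n_pd, x$n_hs)) {
    stop(sprintf("n_folds must lie in 2..%d (smaller class size)",
                 min(x$n_pd, x$n_hs)))
  }
  items <- resolve_items(x, items)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x$responses)
  folds <- integer(n)
  for (cls in c("PD", "HS")) {
    idx <- sample(which(x$labels == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  scores <- numeric(n)
  labels <- character(n)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    train <- subset_cohort(x, !test)
    fit <- switch(classifier,
                  plsda = fit_plsda(train, items = items, ...),
                  tree = fit_tree(train, items = items, ...))
    held <- subset_cohort(x, test)
    pr <- predict(fit, held)
    scores[test] <- pr$score
    labels[test] <- pr$label
  }
  is_pd <- x$labels == "PD"
  cm <- confusion_matrix(tp = sum(is_pd & labels == "PD"),
                         fn = sum(is_pd & labels == "HS"),
                         fp = sum(!is_pd & labels == "PD"),
                         tn = sum(!is_pd & labels == "HS"))
  auroc <- rank_auc(scores, is_pd)
  structure(
    list(folds = folds, scores = scores, labels = labels, cm = cm,
         report = metrics_from_confusion(cm, auroc = auroc),
         auroc = auroc, classifier = classifier, items = items,
         n_folds = as.integer(n_folds)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV of %s on %d items\n",
              x$n_folds, x$classifier, length(x$items)))
  cat("Pooled confusion matrix:\n")
  print(x$cm)
  print(x$report)
  invisible(x)
}

# Mann-Whitney AUC with mid-rank ties: higher score => PD
rank_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)  # average ranks for ties
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# row subset keeping cohort structure
subset_cohort <- function(x, keep) {
  cohort(x$responses[keep, , drop = FALSE], x$labels[keep],
         subject_ids = x$subject_ids[keep], item_names = x$item_names)
}
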