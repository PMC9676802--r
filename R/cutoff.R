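#' Panel sum score per subject
#'
#' Number of correct responses among the panel items — the quantity a
#' clinician would compute with the paper form of an abbreviated test.
#' Disease lowers it, so the screening rule is "score <= cut-off calls
#' PD".
#'
#' @param x a [cohort()].
#' @param panel item numbers (or a [select_panel()] result); `NULL` = all
#'   items (the full-battery total score).
#' @return Integer vector of per-subject scores in `0..length(panel)`.
#' @export
sum_score <- function(x, panel = NULL) {
  stopifnot(inherits(x, "cohort"))
  panel <- resolve_items(x, panel)
  as.integer(rowSums(x$responses[, panel, drop = FALSE]))
}

#' ROC of the sum score over integer cut-offs
#'
#' For every integer threshold `t` from -1 to the maximum score, applies
#' the rule "score <= t implies PD" and records sensitivity (fraction of
#' PD at or below `t`), specificity (fraction of HS above `t`) and the
#' Youden index J = sensitivity + specificity - 1. The AUC is the
#' trapezoidal area over the resulting ROC points, which for integer
#' scores equals the Mann–Whitney statistic with mid-rank ties.
#'
#' @param scores integer scores from [sum_score()].
#' @param labels class labels (`"PD"`/`"HS"`), one per score.
#' @return An object of class `"sumscore_roc"`: data frame `points`
#'   (threshold, sensitivity, specificity, youden), plus `auc`.
#' @examples
#' co <- simulate_cohort(default_spec(), seed = 1)
#' roc <- roc_over_cutoffs(sum_score(co, c(3, 7, 8, 10, 17, 22, 30, 36)),
#'                         co$labels)
#' youden_cutoff(roc)
#' @export
roc_over_cutoffs <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  is_pd <- labels == "PD"
  if (!any(is_pd) || all(is_pd)) stop("both classes must be present")
  ts <- (-1):max(scores)
  sens <- vapply(ts, function(t) mean(scores[is_pd] <= t), numeric(1))
  spec <- vapply(ts, function(t) mean(scores[!is_pd] > t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(
    list(points = data.frame(threshold = ts, sensitivity = sens,
                             specificity = spec, youden = sens + spec - 1),
         auc = auc),
    class = "sumscore_roc"
  )
}

#' @export
print.sumscore_roc <- function(x, ...) {
  best <- youden_cutoff(x)
  cat(sprintf("Sum-score ROC: AUC %.3f; best cut-off <= %d (J = %.3f, sens %.3f, spec %.3f)\n",
              x$auc, best$threshold, best$youden, best$sensitivity,
              best$specificity))
  invisible(x)
}

#' @export
plot.sumscore_roc <- function(x, ...) {
  with(x$points, {
    graphics::plot(1 - specificity, sensitivity, type = "b", pch = 16,
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("Sum-score ROC (AUC %.3f)", x$auc), ...)
    graphics::abline(0, 1, lty = 3)
  })
  best <- youden_cutoff(x)
  graphics::points(1 - best$specificity, best$sensitivity, col = 2, cex = 2)
  invisible(x)
}

#' Youden-optimal screening cut-off
#'
#' Picks the integer threshold maximising J = sensitivity +
#' specificity - 1; among equal maxima the lowest threshold is chosen
#' (favouring specificity — fewer healthy subjects called PD).
#'
#' @param roc a [roc_over_cutoffs()] result.
#' @return One-row data frame: `threshold`, `youden`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "sumscore_roc"))
  p <- roc$points
  best <- which(p$youden >= max(p$youden) - 1e-12)[1L]
  p[best, c("threshold", "youden", "sensitivity", "specificity")]
}
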