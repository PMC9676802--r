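#' Construct a 2x2 classification confusion matrix
#'
#' Orientation: PD is the positive class. `tp` = PD called PD,
#' `fn` = PD called HS, `fp` = HS called PD, `tn` = HS called HS.
#'
#' @param tp,fn,fp,tn non-negative integer counts; each class must be
#'   non-empty.
#' @return A `"confusion_matrix"` object.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cnt <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("confusion counts must be non-negative integers")
  }
  if (tp + fn < 1 || fp + tn < 1) stop("each true class must be non-empty")
  cnt <- as.integer(cnt)
  structure(list(tp = cnt[1L], fn = cnt[2L], fp = cnt[3L], tn = cnt[4L]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(true = c("PD", "HS"), called = c("PD", "HS")))
  print(m)
  invisible(x)
}

#' Binomial standard error of a proportion
#'
#' `sqrt(p (1 - p) / n)` — the standard error attached to every
#' proportion-type metric in a diagnostic report.
#'
#' @param p proportion in \[0, 1\].
#' @param n denominator of the proportion, `n >= 1`.
#' @return Non-negative standard error.
#' @export
proportion_se <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  sqrt(p * (1 - p) / n)
}

#' Full diagnostic-accuracy metric suite of a confusion matrix
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, accuracy (each with its binomial standard error over its own
#' denominator), and the positive and negative likelihood ratios
#' LR+ = sens/(1 - spec), LR- = (1 - sens)/spec.
#'
#' When `fp = 0` the LR+ is infinite: it is reported with an explicit
#' `lr_pos_infinite` flag together with a continuity-corrected value
#' (0.5 added to all four cells), never as a silent sentinel. When
#' `tp + fp = 0` the PPV is undefined and reported as `NA` (likewise NPV
#' when `tn + fn = 0`).
#'
#' @param cm a [confusion_matrix()].
#' @param auroc optional area under the ROC curve computed from
#'   continuous scores (labels alone cannot provide one).
#' @return A `"diagnostic_report"`: list of metric estimates, their
#'   standard errors (`se_*`), the likelihood ratios and flags, `auroc`
#'   (or `NA`), and the source matrix in `$cm`.
#' @examples
#' metrics_from_confusion(confusion_matrix(56, 12, 5, 56))
#' @export
metrics_from_confusion <- function(cm, auroc = NA_real_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n_pd <- cm$tp + cm$fn
  n_hs <- cm$fp + cm$tn
  n <- n_pd + n_hs
  sens <- cm$tp / n_pd
  spec <- cm$tn / n_hs
  ppv <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  npv <- if (cm$tn + cm$fn > 0) cm$tn / (cm$tn + cm$fn) else NA_real_
  acc <- (cm$tp + cm$tn) / n
  lr_pos_infinite <- cm$fp == 0L
  lr_pos <- if (lr_pos_infinite) {
    # continuity-corrected companion value, reported beside the flag
    ((cm$tp + 0.5) / (n_pd + 1)) / ((cm$fp + 0.5) / (n_hs + 1))
  } else {
    sens / (1 - spec)
  }
  lr_neg <- (1 - sens) / spec
  structure(
    list(sensitivity = sens, se_sensitivity = proportion_se(sens, n_pd),
         specificity = spec, se_specificity = proportion_se(spec, n_hs),
         ppv = ppv,
         se_ppv = if (is.na(ppv)) NA_real_ else proportion_se(ppv, cm$tp + cm$fp),
         npv = npv,
         se_npv = if (is.na(npv)) NA_real_ else proportion_se(npv, cm$tn + cm$fn),
         accuracy = acc, se_accuracy = proportion_se(acc, n),
         lr_pos = lr_pos, lr_pos_infinite = lr_pos_infinite,
         lr_neg = lr_neg,
         auroc = auroc, cm = cm),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, digits = 3, ...) {
  fmt <- function(v, se) sprintf("%.*f +/- %.*f", digits, v, digits, se)
  cat("Diagnostic report (PD positive)\n")
  cat("  sensitivity:", fmt(x$sensitivity, x$se_sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity, x$se_specificity), "\n")
  cat("  PPV:        ", if (is.na(x$ppv)) "undefined" else fmt(x$ppv, x$se_ppv), "\n")
  cat("  NPV:        ", if (is.na(x$npv)) "undefined" else fmt(x$npv, x$se_npv), "\n")
  cat("  accuracy:   ", fmt(x$accuracy, x$se_accuracy), "\n")
  cat("  LR+:        ", if (x$lr_pos_infinite)
    sprintf("infinite (continuity-corrected %.2f)", x$lr_pos)
    else sprintf("%.2f", x$lr_pos), "\n")
  cat("  LR-:        ", sprintf("%.2f", x$lr_neg), "\n")
  if (!is.na(x$auroc)) cat("  AUROC:      ", sprintf("%.3f", x$auroc), "\n")
  invisible(x)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Display rounding used for published two-decimal metrics (base
#' `round()` rounds half to even, which does not match such tables).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Reconstruct the integer confusion matrix behind rounded metrics
#'
#' Published accuracy tables print sensitivity and specificity rounded to
#' two decimals; given the class sizes, the underlying integer confusion
#' matrix can usually be recovered exactly. The search is exhaustive over
#' `tp in 0..n_pd` and `tn in 0..n_hs`, accepting counts whose exact
#' proportion lies in the half-open rounding interval
#' `[x - 5e-(digits+1), x + 5e-(digits+1))` — membership that is robust
#' to the publisher's rounding convention.
#'
#' @param sens_rounded,spec_rounded rounded sensitivity and specificity.
#' @param n_pd,n_hs true class sizes.
#' @param digits decimals the published values were rounded to.
#' @return The unique [confusion_matrix()]. If no integer matrix or more
#'   than one is consistent, an error lists the candidates.
#' @examples
#' reconstruct_confusion(0.82, 0.92, 68, 61)  # -> tp 56, tn 56
#' @export
reconstruct_confusion <- function(sens_rounded, spec_rounded, n_pd, n_hs,
                                  digits = 2) {
  stopifnot(sens_rounded >= 0, sens_rounded <= 1,
            spec_rounded >= 0, spec_rounded <= 1, n_pd >= 1, n_hs >= 1)
  half <- 0.5 * 10^(-digits)
  in_interval <- function(exact, target) {
    exact >= target - half - 1e-12 & exact < target + half - 1e-12
  }
  tp <- which(in_interval((0:n_pd) / n_pd, sens_rounded)) - 1L
  tn <- which(in_interval((0:n_hs) / n_hs, spec_rounded)) - 1L
  if (length(tp) == 0L || length(tn) == 0L) {
    stop(sprintf("no integer matrix has sens %.2f (n_PD=%d) and spec %.2f (n_HS=%d)",
                 sens_rounded, n_pd, spec_rounded, n_hs))
  }
  if (length(tp) > 1L || length(tn) > 1L) {
    cand <- expand.grid(tp = tp, tn = tn)
    stop(sprintf("rounded metrics are ambiguous; candidate (tp, tn) pairs: %s",
                 paste(sprintf("(%d,%d)", cand$tp, cand$tn), collapse = " ")))
  }
  confusion_matrix(tp, n_pd - tp, n_hs - tn, tn)
}
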