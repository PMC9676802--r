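#' Pipeline configuration
#'
#' Collects every knob of the end-to-end panel-selection procedure. The
#' defaults mirror the published protocol: top lists of k = 12 items from
#' each of the M = 5 ranking methods, a consensus threshold of m = 4
#' votes, 10-fold stratified cross-validation, 2 PLS components.
#'
#' @param k top-list size per ranking method.
#' @param m consensus vote threshold.
#' @param methods ranking methods to use (see [rank_items()]).
#' @param n_comp PLS-DA components.
#' @param max_depth,min_leaf tree growth parameters (see [fit_tree()]).
#' @param n_folds cross-validation folds.
#' @param cv_seed seed for the fold shuffles.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(k = 12, m = 4,
                            methods = c("fisher", "dor", "auc", "logistic", "lda"),
                            n_comp = 2, max_depth = 10, min_leaf = 2,
                            n_folds = 10, cv_seed = 1L) {
  stopifnot(k >= 1, m >= 1, m <= length(methods), length(methods) >= 1)
  structure(list(k = as.integer(k), m = as.integer(m), methods = methods,
                 n_comp = n_comp, max_depth = max_depth, min_leaf = min_leaf,
                 n_folds = n_folds, cv_seed = cv_seed),
            class = "pipeline_config")
}

#' Run the full panel-selection pipeline
#'
#' End-to-end procedure on one cohort: rank all items by each configured
#' method, take the top-k lists, tally consensus votes, select the panel
#' of items with at least m votes, cross-validate PLS-DA and the
#' classification tree on both the panel and the full battery, and
#' derive the Youden-optimal sum-score cut-off for the panel. All
#' randomness (fold shuffles) is governed by `config$cv_seed`, so the
#' result is deterministic given the cohort and configuration.
#'
#' @param x a [cohort()]; if `NULL`, one is simulated from `spec` with
#'   `sim_seed`.
#' @param config a [pipeline_config()].
#' @param spec a [cohort_spec()] used when `x` is `NULL`.
#' @param sim_seed seed for the simulated cohort.
#' @return An object of class `"panel_pipeline"`: `rankings` (one per
#'   method), `tally`, `panel`, `combinations` (the UpSet-style
#'   combination matrix), `cv` (list of four [cross_validate()] results:
#'   `plsda_panel`, `plsda_full`, `tree_panel`, `tree_full`), `roc` and
#'   `cutoff` for the panel sum score, the `config`, and the cohort.
#' @examples
#' res <- run_pipeline(spec = default_spec(), sim_seed = 7)
#' res
#' @export
run_pipeline <- function(x = NULL, config = pipeline_config(),
                         spec = default_spec(), sim_seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(x)) x <- simulate_cohort(spec, seed = sim_seed)
  stopifnot(inherits(x, "cohort"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage \"%s\" failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  rankings <- stage("rank", {
    r <- lapply(config$methods, function(m) rank_items(x, m))
    names(r) <- config$methods
    r
  })
  tally <- stage("select", {
    tally_votes(lapply(rankings, top_k, k = config$k),
                n_items = ncol(x$responses))
  })
  panel <- select_panel(tally, config$m)
  if (!length(panel$items)) {
    stop(sprintf("pipeline stage \"select\" failed: no item reached %d votes",
                 config$m))
  }
  combos <- combination_matrix(tally)

  cv <- stage("evaluate", {
    run <- function(items, cls) {
      if (cls == "plsda") {
        cross_validate(x, items = items, classifier = "plsda",
                       n_folds = config$n_folds, seed = config$cv_seed,
                       n_comp = config$n_comp)
      } else {
        cross_validate(x, items = items, classifier = "tree",
                       n_folds = config$n_folds, seed = config$cv_seed,
                       max_depth = config$max_depth, min_leaf = config$min_leaf)
      }
    }
    list(plsda_panel = run(panel$items, "plsda"),
         plsda_full = run(NULL, "plsda"),
         tree_panel = run(panel$items, "tree"),
         tree_full = run(NULL, "tree"))
  })

  roc <- stage("cutoff", {
    roc_over_cutoffs(sum_score(x, panel$items), x$labels)
  })

  structure(
    list(cohort = x, rankings = rankings, tally = tally, panel = panel,
         combinations = combos, cv = cv, roc = roc,
         cutoff = youden_cutoff(roc), config = config),
    class = "panel_pipeline"
  )
}

#' @export
print.panel_pipeline <- function(x, ...) {
  cat("Panel-selection pipeline\n")
  print(x$cohort)
  print(x$panel)
  cat(sprintf("Panel sum-score cut-off: <= %d (J = %.3f), ROC AUC %.3f\n",
              x$cutoff$threshold, x$cutoff$youden, x$roc$auc))
  cat("\nCross-validated comparison:\n")
  print(render_table(x$cv))
  invisible(x)
}

#' @export
summary.panel_pipeline <- function(object, ...) print(object, ...)

#' Render the four-way classifier comparison table
#'
#' Formats the pooled cross-validation metrics of the four runs (PLS-DA
#' and tree, each on the panel and the full battery) in the row order
#' and display conventions of a published accuracy table: proportions as
#' "estimate ± SE" at two decimals, likelihood ratios at two decimals,
#' accuracy at three. An infinite LR+ renders as `Inf`.
#'
#' @param cv a list of four [cross_validate()] results (or bare
#'   [metrics_from_confusion()] reports) in column order; list names
#'   become column names.
#' @return A character data frame with metric rows.
#' @examples
#' cms <- list(`8-item` = confusion_matrix(56, 12, 5, 56),
#'             `40-item` = confusion_matrix(54, 14, 9, 52))
#' render_table(lapply(cms, metrics_from_confusion))
#' @export
render_table <- function(cv) {
  reports <- lapply(cv, function(r) {
    if (inherits(r, "cv_result")) r$report
    else if (inherits(r, "diagnostic_report")) r
    else stop("render_table expects cv_result or diagnostic_report objects")
  })
  ns <- vapply(reports, function(r) with(r$cm, tp + fn + fp + tn), numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("reports cover cohorts of different sizes; refusing to tabulate")
  }
  pm <- function(v, se) sprintf("%.2f ± %.2f", round_half_up(v, 2),
                                round_half_up(se, 2))
  lr <- function(v, inf) if (inf) "Inf" else sprintf("%.2f", round_half_up(v, 2))
  col <- function(r) c(
    Sensitivity = pm(r$sensitivity, r$se_sensitivity),
    Specificity = pm(r$specificity, r$se_specificity),
    `Positive likelihood ratio` = lr(r$lr_pos, r$lr_pos_infinite),
    `Negative likelihood ratio` = sprintf("%.2f", round_half_up(r$lr_neg, 2)),
    `Negative predictive value` = pm(r$npv, r$se_npv),
    `Positive predictive value` = pm(r$ppv, r$se_ppv),
    Accuracy = sprintf("%.3f", round_half_up(r$accuracy, 3)))
  out <- as.data.frame(lapply(reports, col), check.names = FALSE)
  rownames(out) <- c("Sensitivity", "Specificity", "Positive likelihood ratio",
                     "Negative likelihood ratio", "Negative predictive value",
                     "Positive predictive value", "Accuracy")
  out
}
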