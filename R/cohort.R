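#' Construct a cohort of binary item responses
#'
#' A `cohort` holds a subjects-by-items matrix of binary responses
#' (1 = correct identification, 0 = incorrect) together with a two-level
#' class label per subject: `"PD"` (Parkinson's disease patients) or
#' `"HS"` (healthy subjects). It is the universal input of the panel
#' selection pipeline.
#'
#' @param responses numeric or integer matrix, subjects in rows, items in
#'   columns, every entry 0 or 1. No missing values are allowed: the
#'   analyses assume complete data, and imputation would silently change
#'   every downstream statistic.
#' @param labels character vector of class labels, one per row of
#'   `responses`, each `"PD"` or `"HS"`. Both classes must be present.
#' @param subject_ids optional character vector of unique subject
#'   identifiers; defaults to `"S1"`, `"S2"`, ...
#' @param item_names optional character vector naming the items (e.g. odor
#'   names); defaults to `"item_1"`, ..., `"item_<p>"`.
#'
#' @return An object of class `"cohort"`: a list with elements
#'   `responses` (integer matrix with subject ids as row names and item
#'   names as column names), `labels`, `subject_ids`, `item_names`,
#'   `n_pd` and `n_hs`.
#'
#' @examples
#' x <- cohort(matrix(c(0, 1, 1, 1, 0, 1), nrow = 3), c("PD", "PD", "HS"))
#' x
#' contingency_for_item(x, 1)
#' @seealso [read_cohort()], [simulate_cohort()], [contingency_for_item()]
#' @export
cohort <- function(responses, labels, subject_ids = NULL, item_names = NULL) {
  if (!is.matrix(responses)) {
    stop("`responses` must be a matrix (subjects x items)")
  }
  n <- nrow(responses)
  p <- ncol(responses)
  if (n < 2L || p < 1L) {
    stop("cohort needs at least 2 subjects and 1 item")
  }
  if (anyNA(responses)) {
    bad <- which(is.na(responses), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing response at row %d, item %d: missing data are not supported",
                 bad[1L], bad[2L]))
  }
  if (!all(responses %in% c(0, 1))) {
    bad <- which(!(responses %in% c(0, 1)))[1L]
    idx <- arrayInd(bad, dim(responses))
    stop(sprintf("response at row %d, item %d is %s; responses must be 0 or 1",
                 idx[1L], idx[2L], format(responses[bad])))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("`labels` must have one entry per subject")
  }
  if (!all(labels %in% c("PD", "HS"))) {
    bad <- which(!(labels %in% c("PD", "HS")))[1L]
    stop(sprintf("label at row %d is \"%s\"; labels must be \"PD\" or \"HS\"",
                 bad, labels[bad]))
  }
  if (!all(c("PD", "HS") %in% labels)) {
    stop("both classes (PD and HS) must be present")
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n || anyDuplicated(subject_ids)) {
    stop("`subject_ids` must be unique, one per subject")
  }
  if (is.null(item_names) || length(item_names) == 0L) {
    item_names <- paste0("item_", seq_len(p))
  }
  item_names <- as.character(item_names)
  if (length(item_names) != p || anyDuplicated(item_names)) {
    stop("`item_names` must be unique, one per item")
  }
  storage.mode(responses) <- "integer"
  dimnames(responses) <- list(subject_ids, item_names)
  structure(
    list(responses = responses, labels = labels, subject_ids = subject_ids,
         item_names = item_names,
         n_pd = sum(labels == "PD"), n_hs = sum(labels == "HS")),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Binary-response cohort: %d subjects (%d PD, %d HS) x %d items\n",
              nrow(x$responses), x$n_pd, x$n_hs, ncol(x$responses)))
  cat(sprintf("Mean total score: PD %.2f, HS %.2f (of %d)\n",
              mean(rowSums(x$responses)[x$labels == "PD"]),
              mean(rowSums(x$responses)[x$labels == "HS"]),
              ncol(x$responses)))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  rates_pd <- colMeans(object$responses[object$labels == "PD", , drop = FALSE])
  rates_hs <- colMeans(object$responses[object$labels == "HS", , drop = FALSE])
  out <- data.frame(item = seq_along(object$item_names),
                    name = object$item_names,
                    p_correct_pd = rates_pd, p_correct_hs = rates_hs,
                    row.names = NULL)
  print.cohort(object)
  cat("Per-item correct rates:\n")
  print(utils::head(out, 10))
  if (nrow(out) > 10) cat(sprintf("... (%d more items)\n", nrow(out) - 10))
  invisible(out)
}

#' Read a cohort from CSV
#'
#' Expects a header `subject_id,group,<item columns...>` with `group` in
#' `{PD, HS}` and responses in `{0, 1}`. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @return A validated [cohort()] object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(default_spec(), seed = 1), f)
#' x <- read_cohort(f)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L || names(df)[1L] != "subject_id" || names(df)[2L] != "group") {
    stop("cohort CSV must start with columns `subject_id`, `group`, then item columns")
  }
  item_cols <- names(df)[-(1:2)]
  resp <- as.matrix(df[, -(1:2), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(resp), nrow = nrow(resp)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(num))
    stop(sprintf("invalid response \"%s\" at data row %d, column \"%s\": must be 0 or 1",
                 resp[bad[1L]], idx[1L], item_cols[idx[2L]]))
  }
  grp <- df$group
  if (!all(grp %in% c("PD", "HS"))) {
    bad <- which(!(grp %in% c("PD", "HS")))[1L]
    stop(sprintf("invalid group \"%s\" at data row %d: must be PD or HS", grp[bad], bad))
  }
  cohort(num, grp, subject_ids = df$subject_id, item_names = item_cols)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes `subject_id,group,<items>` with stable
#' column order so that `read_cohort(write_cohort(x))` reproduces `x`.
#'
#' @param x a [cohort()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- data.frame(subject_id = x$subject_ids, group = x$labels,
                   x$responses, check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-item 2x2 contingency table
#'
#' Cross-classifies one item's correct/incorrect responses by class. All
#' univariate item statistics ([fisher_exact_p()], [diagnostic_odds_ratio()],
#' [item_auc()]) consume this table. An incorrect response is the
#' "test-positive" state for PD throughout, so larger odds ratios and AUCs
#' mean more discriminative items.
#'
#' @param x a [cohort()].
#' @param item 1-based item index.
#' @return A `"contingency_table"`: list with integer counts
#'   `incorrect_pd`, `correct_pd`, `incorrect_hs`, `correct_hs`.
#' @export
contingency_for_item <- function(x, item) {
  stopifnot(inherits(x, "cohort"))
  if (length(item) != 1L || item < 1L || item > ncol(x$responses)) {
    stop(sprintf("item index %s out of range 1..%d", format(item), ncol(x$responses)))
  }
  r <- x$responses[, item]
  pd <- x$labels == "PD"
  contingency_table(incorrect_pd = sum(r[pd] == 0L),
                    correct_pd   = sum(r[pd] == 1L),
                    incorrect_hs = sum(r[!pd] == 0L),
                    correct_hs   = sum(r[!pd] == 1L))
}

#' Construct a 2x2 item contingency table directly from counts
#'
#' @param incorrect_pd,correct_pd,incorrect_hs,correct_hs non-negative
#'   integer counts; each class must contain at least one subject.
#' @return A `"contingency_table"` object.
#' @export
contingency_table <- function(incorrect_pd, correct_pd, incorrect_hs, correct_hs) {
  cnt <- c(incorrect_pd = incorrect_pd, correct_pd = correct_pd,
           incorrect_hs = incorrect_hs, correct_hs = correct_hs)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("contingency counts must be non-negative integers")
  }
  if (incorrect_pd + correct_pd < 1 || incorrect_hs + correct_hs < 1) {
    stop("each class must contain at least one subject")
  }
  cnt <- as.integer(cnt)
  structure(list(incorrect_pd = cnt[1L], correct_pd = cnt[2L],
                 incorrect_hs = cnt[3L], correct_hs = cnt[4L]),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$incorrect_pd, x$correct_pd, x$incorrect_hs, x$correct_hs),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("PD", "HS"), c("incorrect", "correct")))
  print(m)
  invisible(x)
}
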