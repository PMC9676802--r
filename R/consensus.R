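#' Top-k item set of a ranking
#'
#' @param ranking an `"item_ranking"` from [rank_items()].
#' @param k list length, `1 <= k <= n_items`.
#' @return Integer vector of the `k` most discriminative item numbers
#'   (ranking order; ties were already resolved deterministically).
#' @export
top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "item_ranking"))
  n <- length(ranking$order)
  if (length(k) != 1L || k < 1L || k > n) {
    stop(sprintf("k must lie in 1..%d", n))
  }
  ranking$order[seq_len(k)]
}

#' Tally item votes across method top-k sets
#'
#' Counts, for every item, how many ranking methods placed it in their
#' top-k list — the vote counts behind the consensus panel and the
#' UpSet-style combination matrix.
#'
#' @param topk_sets named list of integer item sets, one per method.
#' @param n_items total number of items in the battery.
#' @return A `"vote_tally"`: list with `counts` (length `n_items`),
#'   `sets`, `M` (number of methods) and `set_sizes`.
#' @examples
#' co <- simulate_cohort(default_spec(), seed = 1)
#' sets <- lapply(c("fisher", "dor", "auc", "logistic", "lda"),
#'                function(m) top_k(rank_items(co, m), 12))
#' tally <- tally_votes(sets, n_items = 40)
#' select_panel(tally, m = 4)
#' @export
tally_votes <- function(topk_sets, n_items) {
  if (!length(topk_sets)) stop("need at least one top-k set")
  if (is.null(names(topk_sets)) || any(names(topk_sets) == "")) {
    names(topk_sets) <- paste0("method_", seq_along(topk_sets))
  }
  topk_sets <- lapply(topk_sets, function(s) {
    s <- as.integer(s)
    if (anyDuplicated(s)) stop("a top-k set contains duplicate items")
    if (any(s < 1L) || any(s > n_items)) stop("item number out of range in a top-k set")
    s
  })
  counts <- integer(n_items)
  for (s in topk_sets) counts[s] <- counts[s] + 1L
  structure(list(counts = counts, sets = topk_sets,
                 M = length(topk_sets),
                 set_sizes = lengths(topk_sets)),
            class = "vote_tally")
}

#' @export
print.vote_tally <- function(x, ...) {
  cat(sprintf("Vote tally: %d methods, set sizes %s\n", x$M,
              paste(x$set_sizes, collapse = "/")))
  tab <- table(factor(x$counts[x$counts > 0], levels = seq_len(x$M)))
  cat("Items by vote count:",
      paste(sprintf("%s votes: %d", names(tab), tab), collapse = "; "), "\n")
  invisible(x)
}

#' Select the consensus panel
#'
#' Items placed in the top-k list by at least `m` of the `M` ranking
#' methods form the screening panel.
#'
#' @param tally a [tally_votes()] result.
#' @param m vote threshold, `1 <= m <= M`.
#' @return A `"selected_panel"`: list with `items` (ascending item
#'   numbers), their `votes`, and `m`.
#' @export
select_panel <- function(tally, m) {
  stopifnot(inherits(tally, "vote_tally"))
  if (length(m) != 1L || m < 1L || m > tally$M) {
    stop(sprintf("m must lie in 1..%d", tally$M))
  }
  items <- which(tally$counts >= m)
  structure(list(items = items, votes = tally$counts[items], m = as.integer(m)),
            class = "selected_panel")
}

#' @export
print.selected_panel <- function(x, ...) {
  cat(sprintf("Consensus panel (>= %d votes): %d items\n", x$m, length(x$items)))
  if (length(x$items)) {
    cat(paste(sprintf("item %d (%d votes)", x$items, x$votes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' UpSet-style combination matrix of method co-selection
#'
#' Partitions the union of the top-k sets by each item's exact set of
#' selecting methods — the rows of an UpSet plot — together with the
#' per-method set sizes (its side bars).
#'
#' @param tally a [tally_votes()] result.
#' @return A data frame with columns `methods` (comma-joined method
#'   names), `degree`, `n_items` and `items` (comma-joined item numbers),
#'   sorted by descending degree; per-method set sizes in
#'   `attr(, "set_sizes")`.
#' @export
combination_matrix <- function(tally) {
  stopifnot(inherits(tally, "vote_tally"))
  n_items <- length(tally$counts)
  members <- vapply(seq_len(n_items), function(i) {
    paste(names(tally$sets)[vapply(tally$sets, function(s) i %in% s, logical(1))],
          collapse = ",")
  }, character(1))
  keep <- members != ""
  combos <- split(which(keep), members[keep])
  df <- data.frame(
    methods = names(combos),
    degree = vapply(strsplit(names(combos), ",", fixed = TRUE), length, integer(1)),
    n_items = lengths(combos),
    items = vapply(combos, function(v) paste(v, collapse = ","), character(1)),
    row.names = NULL
  )
  df <- df[order(-df$degree, df$methods), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "set_sizes") <- tally$set_sizes
  df
}

#' Odor names of the published 8-item screening panel
#'
#' The eight odors the original study's consensus selection retained,
#' shipped purely for labelling reports; the package never assumes a
#' synthetic cohort reproduces this particular set.
#'
#' @format Character vector of length 8.
#' @export
published_panel_odors <- c("coconut", "apple", "lilac", "orange",
                           "motor oil", "banana", "clove", "watermelon")
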