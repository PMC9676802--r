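#' Fit a classification tree on binary items
#'
#' Greedy binary recursive partitioning (CART) specialised to 0/1 item
#' responses: each internal node splits on one item, sending incorrect
#' (0) responders left and correct (1) responders right. The split
#' minimises the weighted child impurity (Gini by default); growth stops
#' at class purity, the depth cap, the minimum leaf size, or when no
#' split reduces impurity. Along any root-to-leaf path each item is
#' tested at most once (a binary item carries no further information).
#' Equal-quality splits go to the lowest item number, so the tree is
#' fully deterministic.
#'
#' @param x a [cohort()].
#' @param items item numbers available for splitting; `NULL` = all.
#'   A [select_panel()] result is also accepted.
#' @param max_depth maximum number of splits on any path (default 10).
#' @param min_leaf minimum subjects in each child of a split (default 2).
#' @param criterion impurity measure, `"gini"` (default) or `"entropy"`.
#' @return An object of class `"odor_tree"`: the nested node structure in
#'   `$root` (each node carries `n_pd`, `n_hs`, and for internal nodes
#'   `item` plus `children$incorrect` / `children$correct`), plus the
#'   growth parameters.
#' @examples
#' co <- simulate_cohort(default_spec(), seed = 1)
#' tr <- fit_tree(co, items = c(3, 7, 8, 10, 17, 22, 30, 36))
#' tr
#' @export
fit_tree <- function(x, items = NULL, max_depth = 10, min_leaf = 2,
                     criterion = c("gini", "entropy")) {
  stopifnot(inherits(x, "cohort"))
  criterion <- match.arg(criterion)
  stopifnot(max_depth >= 1, min_leaf >= 1)
  items <- resolve_items(x, items)
  imp <- if (criterion == "gini") {
    function(n1, n0) {
      n <- n1 + n0
      if (n == 0) return(0)
      1 - (n1 / n)^2 - (n0 / n)^2
    }
  } else {
    function(n1, n0) {
      n <- n1 + n0
      if (n == 0) return(0)
      p <- c(n1, n0) / n
      p <- p[p > 0]
      -sum(p * log2(p))
    }
  }
  resp <- x$responses
  is_pd <- x$labels == "PD"

  grow <- function(idx, avail, depth) {
    n1 <- sum(is_pd[idx]); n0 <- length(idx) - n1
    node <- list(n_pd = n1, n_hs = n0)
    node_imp <- imp(n1, n0)
    if (node_imp == 0 || depth >= max_depth || !length(avail) ||
        length(idx) < 2 * min_leaf) {
      return(node)
    }
    n <- length(idx)
    best <- NULL; best_quality <- Inf
    for (j in avail) {
      right <- resp[idx, j] == 1L
      nr <- sum(right); nl <- n - nr
      if (nl < min_leaf || nr < min_leaf) next
      n1r <- sum(is_pd[idx] & right)
      quality <- (nl * imp(n1 - n1r, n0 - (nr - n1r)) + nr * imp(n1r, nr - n1r)) / n
      if (quality < best_quality - 1e-12) {  # ties keep the lowest item number
        best_quality <- quality
        best <- j
      }
    }
    if (is.null(best) || best_quality >= node_imp - 1e-12) return(node)
    right <- resp[idx, best] == 1L
    avail2 <- setdiff(avail, best)
    node$item <- best
    node$children <- list(incorrect = grow(idx[!right], avail2, depth + 1),
                          correct = grow(idx[right], avail2, depth + 1))
    node
  }

  structure(
    list(root = grow(seq_len(nrow(resp)), sort(items), 0L),
         items = items, max_depth = max_depth, min_leaf = min_leaf,
         criterion = criterion),
    class = "odor_tree"
  )
}

tree_depth <- function(node) {
  if (is.null(node$item)) return(0L)
  1L + max(tree_depth(node$children$incorrect), tree_depth(node$children$correct))
}

#' @export
print.odor_tree <- function(x, ...) {
  cat(sprintf("Classification tree (%s impurity, depth %d)\n",
              x$criterion, tree_depth(x$root)))
  show <- function(node, indent, branch) {
    lab <- sprintf("%s%s[PD %d | HS %d]", strrep("  ", indent), branch,
                   node$n_pd, node$n_hs)
    if (!is.null(node$item)) {
      cat(lab, sprintf("split on item %d\n", node$item))
      show(node$children$incorrect, indent + 1, "0: ")
      show(node$children$correct, indent + 1, "1: ")
    } else {
      cat(lab, sprintf("-> %s\n", if (node$n_pd >= node$n_hs) "PD" else "HS"))
    }
  }
  show(x$root, 0, "")
  invisible(x)
}

#' Predict class membership from a fitted tree
#'
#' Each subject is routed by its item responses to a leaf; the score is
#' the leaf's PD fraction and the label the leaf majority, with an exact
#' tie called PD (a screening rule favouring sensitivity).
#'
#' @param object an `"odor_tree"`.
#' @param newdata a [cohort()] containing the model's items.
#' @param ... unused.
#' @return Data frame with per-subject `score` (leaf PD fraction) and
#'   `label`.
#' @export
predict.odor_tree <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort"))
  if (max(object$items) > ncol(newdata$responses)) {
    stop("newdata lacks items the model was trained on")
  }
  route <- function(node, responses) {
    while (!is.null(node$item)) {
      node <- if (responses[node$item] == 1L) node$children$correct
              else node$children$incorrect
    }
    node$n_pd / (node$n_pd + node$n_hs)
  }
  score <- apply(newdata$responses, 1, function(r) route(object$root, r))
  data.frame(subject_id = newdata$subject_ids, score = as.numeric(score),
             label = ifelse(score >= 0.5, "PD", "HS"),
             row.names = NULL)
}
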