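#' Fit a PLS-DA classifier on a subset of items
#'
#' Partial least squares discriminant analysis with a single 0/1 class
#' response (PD = 1): PLS1 extracted by the classical NIPALS recursion.
#' With column-centred `X` and centred response `y`, each component's
#' weight vector is `w = X'y / ||X'y||` on the current deflated data,
#' the score is `t = X w`, the X-loading `p = X't / t't` and the
#' y-loading `q = y't / t't`; `X` is deflated by `t p'` and `y` by
#' `q t`. The final regression coefficients on the original item scale
#' are `B = W (P'W)^{-1} q`, stored together with the centring means so
#' predictions are plain linear algebra.
#'
#' @param x a [cohort()].
#' @param items item numbers to use; `NULL` means the whole battery.
#'   A [select_panel()] result is also accepted.
#' @param n_comp number of latent components (default 2); must not
#'   exceed the rank of the centred predictor matrix.
#' @param threshold score threshold for calling PD on the 0/1 response
#'   scale (default 0.5).
#' @return An object of class `"plsda"` with elements `items`, `x_means`,
#'   `y_mean`, `weights` (p x A), `loadings` (p x A), `y_loadings`
#'   (length A), `coefficients`, `intercept`, `n_comp`, `threshold`.
#' @examples
#' co <- simulate_cohort(default_spec(), seed = 1)
#' fit <- fit_plsda(co, items = c(3, 7, 8, 10, 17, 22, 30, 36))
#' pr <- predict(fit, co)
#' table(pr$label, co$labels)
#' @export
fit_plsda <- function(x, items = NULL, n_comp = 2, threshold = 0.5) {
  stopifnot(inherits(x, "cohort"))
  items <- resolve_items(x, items)
  X <- x$responses[, items, drop = FALSE]
  storage.mode(X) <- "double"
  y <- as.numeric(x$labels == "PD")
  n <- nrow(X); p <- ncol(X)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_means)
  yc <- y - y_mean
  rk <- qr(Xc)$rank
  if (n_comp < 1 || n_comp > rk) {
    stop(sprintf("n_comp must lie in 1..%d (rank of the centred data)", rk))
  }
  W <- P <- matrix(0, p, n_comp)
  q <- numeric(n_comp)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_comp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop(sprintf("no residual covariance left at component %d; reduce n_comp", a))
    }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    P[, a] <- drop(crossprod(Xd, t_)) / tt
    q[a] <- sum(yd * t_) / tt
    W[, a] <- w
    Xd <- Xd - tcrossprod(t_, P[, a])
    yd <- yd - q[a] * t_
  }
  B <- drop(W %*% solve(crossprod(P, W), q))
  names(B) <- x$item_names[items]
  structure(
    list(items = items, x_means = x_means, y_mean = y_mean,
         weights = W, loadings = P, y_loadings = q,
         coefficients = B, intercept = y_mean - sum(x_means * B),
         n_comp = n_comp, threshold = threshold),
    class = "plsda"
  )
}

#' @export
coef.plsda <- function(object, ...) {
  c("(intercept)" = object$intercept, object$coefficients)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA classifier: %d items, %d components, threshold %.2f\n",
              length(x$items), x$n_comp, x$threshold))
  cat("Items:", paste(x$items, collapse = ", "), "\n")
  invisible(x)
}

#' Predict class membership from a PLS-DA fit
#'
#' @param object a `"plsda"` model.
#' @param newdata a [cohort()] containing the model's items.
#' @param ... unused.
#' @return A data frame with per-subject `score` (the fitted linear
#'   predictor on the 0/1 response scale) and `label` (`"PD"` when
#'   `score >= threshold`).
#' @export
predict.plsda <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort"))
  if (max(object$items) > ncol(newdata$responses)) {
    stop("newdata lacks items the model was trained on")
  }
  X <- newdata$responses[, object$items, drop = FALSE]
  score <- object$intercept + drop(X %*% object$coefficients)
  data.frame(subject_id = newdata$subject_ids, score = score,
             label = ifelse(score >= object$threshold, "PD", "HS"),
             row.names = NULL)
}

# items argument: NULL = all, selected_panel, or integer vector
resolve_items <- function(x, items) {
  if (is.null(items)) return(seq_len(ncol(x$responses)))
  if (inherits(items, "selected_panel")) items <- items$items
  items <- as.integer(items)
  if (!length(items) || any(items < 1L) || any(items > ncol(x$responses)) ||
      anyDuplicated(items)) {
    stop("`items` must be distinct item numbers within the battery")
  }
  items
}
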