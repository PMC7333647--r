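# Stability feature selection: repeated cross-validated L1-penalized linear
# regression on the 0/1 label, selection-frequency ranking, top-sqrt(n)
# truncation, and the feature correlation map.

# Stratified, shuffled fold assignment: within each class, indices are
# shuffled and folds dealt cyclically.
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fid
}

#' One run of cross-validated Lasso selection
#'
#' Linear-response Lasso on the 0/1 label (the procedure is literal Lasso,
#' not penalized logistic). The path is 100 log-spaced values from
#' `lambda_max = max|X'(y - mean(y))| / n` down to `1e-3 * lambda_max`;
#' lambda is chosen by minimum mean squared CV error over stratified,
#' shuffled `folds`-fold splits, then the model is refit on all samples at
#' the chosen lambda. Features with nonzero coefficients are returned.
#'
#' @param X column-standardized numeric matrix (samples x features).
#' @param y 0/1 labels; each class must have at least `folds` members
#'   (a constant `y` short-circuits to an empty selection).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling the fold shuffle.
#' @param n_lambda,lambda_min_ratio path geometry.
#' @return named numeric vector of nonzero coefficients (possibly empty).
#' @export
lasso_cv_once <- function(X, y, folds = 5L, seed = 1L,
                          n_lambda = 100L, lambda_min_ratio = 1e-3) {
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(unique(y)) == 1L) return(stats::setNames(numeric(0), character(0)))
  if (min(table(y)) < folds) {
    stop_data("each class needs at least `folds` members for stratified CV")
  }
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (lambda_max <= 0) return(stats::setNames(numeric(0), character(0)))
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  fid <- stratified_folds(y, folds, seed)
  cv_err <- matrix(NA_real_, folds, n_lambda)
  for (f in seq_len(folds)) {
    tr <- fid != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "gaussian",
                          lambda = lambdas, standardize = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    # glmnet may drop path tail; align on the lambdas it actually fit
    hit <- match(signif(fit$lambda, 8), signif(lambdas, 8))
    err <- colMeans((pred - y[!tr])^2)
    cv_err[f, hit[!is.na(hit)]] <- err[!is.na(hit)]
  }
  mean_err <- colMeans(cv_err, na.rm = TRUE)
  best <- which.min(mean_err)
  if (!length(best)) best <- n_lambda
  full <- glmnet::glmnet(X, y, family = "gaussian", lambda = lambdas,
                         standardize = FALSE)
  beta <- as.numeric(stats::coef(full, s = lambdas[best]))[-1]
  names(beta) <- colnames(X)
  beta <- beta[beta != 0]
  # coordinate descent leaves numerical dust on exactly collinear twins of a
  # selected feature; treat coefficients < 1e-3 of the largest as zero
  if (length(beta)) beta <- beta[abs(beta) >= 1e-3 * max(abs(beta))]
  beta
}

#' Repeated cross-validated Lasso selection
#'
#' Runs [lasso_cv_once()] `repetitions` times with re-shuffled stratified
#' folds (fold seeds derived from the master seed by a counter scheme) and
#' accumulates, per feature, the number of times it received a nonzero
#' coefficient and the sum of its coefficients.
#'
#' @param X numeric matrix (columns are features; z-scored internally).
#' @param y 0/1 labels.
#' @param repetitions number of repeats (default 100).
#' @param master_seed master seed.
#' @param folds CV folds.
#' @return a `selection_result` data.frame with columns `feature`,
#'   `selection_count`, `coefficient_sum`, sorted by count (descending, ties
#'   by |coefficient sum| then name).
#' @export
repeat_selection <- function(X, y, repetitions = 100L, master_seed = 1L,
                             folds = 5L) {
  X <- zscore_columns(X)
  cnt <- stats::setNames(numeric(ncol(X)), colnames(X))
  csum <- cnt
  for (rep_i in seq_len(repetitions)) {
    beta <- lasso_cv_once(X, y, folds = folds,
                          seed = derive_seed(master_seed, "lassocv", rep_i))
    if (length(beta)) {
      cnt[names(beta)] <- cnt[names(beta)] + 1
      csum[names(beta)] <- csum[names(beta)] + beta
    }
  }
  out <- data.frame(feature = names(cnt), selection_count = as.numeric(cnt),
                    coefficient_sum = as.numeric(csum),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$selection_count, -abs(out$coefficient_sum),
                   out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("selection_result", "data.frame")
  attr(out, "repetitions") <- repetitions
  out
}

#' Truncate a selection result to the top sqrt(n) features
#'
#' Keeps the top `round(sqrt(n))` features by selection count among features
#' with a nonzero coefficient sum (nearest-integer rounding reproduces the
#' published quotas: 11 at n = 120 and 6 at n = 35; the ceiling reading
#' agrees on both). Boundary ties break by |coefficient sum| descending,
#' then feature name. If fewer features are eligible than the quota, all
#' eligible features are returned with a warning.
#'
#' @param result a `selection_result` from [repeat_selection()].
#' @param n sample size that sets the quota.
#' @return character vector of retained feature names.
#' @export
truncate_top_sqrt_n <- function(result, n) {
  if (n < 1) stop_cfg("n must be >= 1")
  quota <- as.integer(round(sqrt(n)))
  elig <- result[result$selection_count > 0 & result$coefficient_sum != 0, ,
                 drop = FALSE]
  if (nrow(elig) < quota) {
    warning("only ", nrow(elig), " eligible features for quota ", quota)
    return(elig$feature)
  }
  elig$feature[seq_len(quota)]
}

#' Pearson correlation map with hierarchical ordering
#'
#' Pairwise Pearson correlations between feature columns, ordered by
#' average-linkage hierarchical clustering on the distance `1 - |r|`.
#' Zero-variance columns get correlation 0 with everything and are flagged.
#'
#' @param X numeric matrix with at least two feature columns.
#' @return list with `r` (reordered correlation matrix), `order` (column
#'   permutation), `flagged` (zero-variance column names).
#' @export
feature_correlation_map <- function(X) {
  if (ncol(X) < 2L) stop_data("need at least 2 features")
  sds <- apply(X, 2, stats::sd)
  flagged <- colnames(X)[sds == 0]
  r <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  ok <- sds > 0
  if (sum(ok) >= 2L) {
    r[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  }
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - abs(r)), method = "average")
  ord <- hc$order
  list(r = r[ord, ord], order = ord, flagged = flagged)
}
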