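#' ROC curve and AUC
#'
#' Standard threshold sweep. The AUC equals the normalized Mann-Whitney U
#' statistic (ties counted half), the identity the tests assert.
#'
#' @param scores real-valued classifier scores (larger = more disease-like).
#' @param labels 0/1, factor, or `disease`/`control` labels.
#' @return list: `roc` (data.frame `fpr`, `tpr`, monotone from (0,0) to (1,1)),
#'   `auc`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  # collapse tied thresholds
  idx <- which(!duplicated(ss))
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  cut_end <- c(idx[-1L] - 1L, length(ys))
  roc <- data.frame(fpr = c(0, fp[cut_end] / n0), tpr = c(0, tp[cut_end] / n1))
  # rank-based AUC (exact under ties)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, auc = auc)
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  l <- as.character(labels)
  if (all(l %in% c("disease", "control"))) return(as.integer(l == "disease"))
  f <- as.factor(l)
  if (nlevels(f) != 2) stop("labels must be binary")
  as.integer(f) - 1L
}

# Stratified fold assignment, deterministic under seed.
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

fit_forest <- function(x, y, params, seed) {
  ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                 num.trees = params$num_trees,
                 max.depth = params$max_depth,
                 min.node.size = params$min_node_size,
                 probability = TRUE, importance = "impurity",
                 num.threads = 1, seed = seed)
}

#' Cross-validated random-forest AUC
#'
#' Stratified k-fold split fixed by seed; per-fold ROC AUC on held-out
#' probability scores, averaged.
#'
#' @param x numeric matrix (samples x features) or [abundance_table].
#' @param labels binary labels (see [roc_points]).
#' @param n_folds default 5.
#' @param seed seed for the fold split and forests.
#' @param num_trees,max_depth,min_node_size forest hyperparameters
#'   (`max_depth = 0` means unlimited).
#' @return list: `mean_auc`, `fold_auc`, `oof_scores` (out-of-fold
#'   probabilities), `folds`.
#' @export
cv_auc <- function(x, labels, n_folds = 5, seed = 1L,
                   num_trees = 500, max_depth = 0, min_node_size = 1) {
  if (inherits(x, "abundance_table")) x <- x$values
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  if (min(table(y)) < n_folds)
    stop("need at least n_folds samples per class; use fewer folds")
  fold <- stratified_folds(y, n_folds, seed)
  params <- list(num_trees = num_trees, max_depth = max_depth,
                 min_node_size = min_node_size)
  oof <- numeric(length(y))
  aucs <- numeric(n_folds)
  imp <- matrix(0, ncol(x), n_folds, dimnames = list(colnames(x), NULL))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    if (length(unique(y[!tr])) < 2)
      stop("a fold lacks both classes; use fewer folds")
    fit <- fit_forest(x[tr, , drop = FALSE], y[tr], params,
                      seed = stream_seed(seed, paste0("fold", k)))
    pr <- stats::predict(fit, data = x[!tr, , drop = FALSE])$predictions[, "1"]
    oof[!tr] <- pr
    aucs[k] <- roc_points(pr, y[!tr])$auc
    imp[, k] <- fit$variable.importance[colnames(x)]
  }
  list(mean_auc = mean(aucs), fold_auc = aucs, oof_scores = oof, folds = fold,
       importance = rowMeans(imp))
}

#' Grid search over forest hyperparameters
#'
#' Exhaustive evaluation by mean cross-validated AUC; ties broken by fewer
#' trees, then shallower depth, then larger minimum node size (preferring the
#' simpler model).
#'
#' @param x,labels,n_folds,seed as in [cv_auc].
#' @param grid data.frame with columns `num_trees`, `max_depth`,
#'   `min_node_size`; default a small grid of trees {100, 500}, depth
#'   {unlimited, 5}, min leaf {1, 5}.
#' @return list: `best` (one-row data.frame), `grid` (with `mean_auc` column).
#' @export
grid_search <- function(x, labels, grid = NULL, n_folds = 5, seed = 1L) {
  if (is.null(grid))
    grid <- expand.grid(num_trees = c(100, 500), max_depth = c(0, 5),
                        min_node_size = c(1, 5))
  if (!nrow(grid)) stop("grid must be non-empty")
  grid$mean_auc <- vapply(seq_len(nrow(grid)), function(i) {
    cv_auc(x, labels, n_folds = n_folds, seed = seed,
           num_trees = grid$num_trees[i], max_depth = grid$max_depth[i],
           min_node_size = grid$min_node_size[i])$mean_auc
  }, numeric(1))
  depth_key <- ifelse(grid$max_depth == 0, Inf, grid$max_depth)
  ord <- order(-grid$mean_auc, grid$num_trees, depth_key, -grid$min_node_size)
  list(best = grid[ord[1L], c("num_trees", "max_depth", "min_node_size"),
                   drop = FALSE],
       grid = grid)
}

#' Recursive feature elimination with a cumulative-AUC curve
#'
#' Starting from all candidate features, iteratively drops the feature with the
#' lowest impurity importance (averaged over CV folds), recording the mean
#' cross-validated AUC at each feature count. The selected subset is the count
#' maximizing mean AUC, ties resolved toward fewer features. Classification
#' uses unique samples with their group labels (never the pair-expanded
#' cohort), so duplicated controls cannot leak across CV folds.
#'
#' @param x samples x candidate-features matrix or [abundance_table].
#' @param labels binary labels.
#' @param n_folds,seed as in [cv_auc].
#' @param num_trees,max_depth,min_node_size forest hyperparameters (e.g. the
#'   [grid_search] winner).
#' @return class `classifier_report`: `curve` (data.frame `n_features`,
#'   `mean_auc`, `features` list-column), `selected_features`, `selected_auc`,
#'   `hyperparameters`, `roc` (out-of-fold ROC on the selected subset),
#'   `final_auc`, `seed`.
#' @export
rfe_select <- function(x, labels, n_folds = 5, seed = 1L,
                       num_trees = 500, max_depth = 0, min_node_size = 1) {
  if (inherits(x, "abundance_table")) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 candidate features")
  current <- colnames(x)
  counts <- integer(0)
  aucs <- numeric(0)
  feats <- list()
  step <- 0L
  while (length(current) >= 1) {
    step <- step + 1L
    cv <- cv_auc(x[, current, drop = FALSE], labels, n_folds = n_folds,
                 seed = stream_seed(seed, paste0("rfe", step)),
                 num_trees = num_trees, max_depth = max_depth,
                 min_node_size = min_node_size)
    counts <- c(counts, length(current))
    aucs <- c(aucs, cv$mean_auc)
    feats <- c(feats, list(current))
    if (length(current) == 1) break
    drop_f <- names(which.min(cv$importance))
    current <- setdiff(current, drop_f)
  }
  best <- which(aucs >= max(aucs) - 1e-12)
  best <- best[which.min(counts[best])]
  sel <- feats[[best]]
  final <- cv_auc(x[, sel, drop = FALSE], labels, n_folds = n_folds,
                  seed = stream_seed(seed, "final"),
                  num_trees = num_trees, max_depth = max_depth,
                  min_node_size = min_node_size)
  roc <- roc_points(final$oof_scores, labels)
  structure(list(curve = data.frame(n_features = counts, mean_auc = aucs),
                 curve_features = feats,
                 selected_features = sel, selected_auc = aucs[best],
                 hyperparameters = list(num_trees = num_trees,
                                        max_depth = max_depth,
                                        min_node_size = min_node_size),
                 roc = roc$roc, final_auc = roc$auc, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "classifier_report: %d features selected of %d (mean CV AUC %.3f; pooled out-of-fold AUC %.3f)\n",
    length(x$selected_features), max(x$curve$n_features), x$selected_auc,
    x$final_auc))
  cat("selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a classifier report
#'
#' Left: cumulative-AUC curve over feature counts with the selected count
#' dashed; right: pooled out-of-fold ROC of the selected model.
#'
#' @param x a `classifier_report`.
#' @param ... ignored.
#' @export
plot.classifier_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$curve$n_features, x$curve$mean_auc, type = "b",
                 xlab = "number of features", ylab = "mean CV AUC",
                 main = "Recursive feature elimination")
  graphics::abline(v = length(x$selected_features), lty = 2)
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC %.3f)", x$final_auc))
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
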