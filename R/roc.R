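# Single-feature ROC discrimination: stratified 50/50 split, univariate
# logistic model, trapezoidal AUC with stratified bootstrap CI.

#' Stratified 50/50 train-test split
#'
#' Splits subjects of each class in half (odd counts put the extra subject
#' in the training half), deterministically for a fixed seed. Both halves
#' contain both classes.
#'
#' @param records data.frame with a `group` column restricted to two classes.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_half <- function(records, seed) {
  cls <- as.character(records$group)
  tab <- table(cls)
  if (length(tab) != 2L) stop("split requires exactly 2 classes, got ",
                              length(tab))
  if (any(tab < 2L))
    stop("split error: class '", names(tab)[which.min(tab)],
         "' has fewer than 2 members")
  train_idx <- integer(0)
  rng <- local({
    set.seed(seed)
    lapply(names(tab), function(cl) sample(which(cls == cl)))
  })
  for (perm in rng) {
    n_train <- ceiling(length(perm) / 2)
    train_idx <- c(train_idx, perm[seq_len(n_train)])
  }
  list(train = records[sort(train_idx), , drop = FALSE],
       test = records[sort(setdiff(seq_len(nrow(records)), train_idx)), ,
                      drop = FALSE])
}

# empirical ROC curve and trapezoidal AUC from scores; `labels` logical
# (TRUE = positive class)
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  labels <- labels[o]
  tp <- cumsum(labels); fp <- cumsum(!labels)
  # collapse threshold ties: keep the last point of each distinct score
  keep <- c(diff(scores[o]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(labels))
  fpr <- c(0, fp[keep] / sum(!labels))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' AUC of a raw score against binary labels
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 2-level factor; `TRUE`/second level is positive.
#' @return numeric AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  roc_points(scores, as.logical(labels))$auc
}

#' Fit a univariate logistic model and evaluate its ROC on held-out data
#'
#' Fits `group ~ feature` by logistic regression on the training half,
#' scores the test half, and summarizes discrimination with the trapezoidal
#' AUC, a stratified-bootstrap 95% CI over the test set, and a rank-sum
#' (Mann-Whitney) p-value against AUC = 0.5. A constant feature yields the
#' chance diagonal (AUC 0.5).
#'
#' @param train,test data.frames with `group` (two classes) and the feature
#'   column.
#' @param feature feature column name.
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param seed RNG seed recorded in the result.
#' @return object of class `roc_result`: `feature`, `contrast`, `auc`,
#'   `ci_low`, `ci_high`, `p`, `curve` (data.frame `fpr`, `tpr`),
#'   `split_seed`.
#' @export
fit_score_roc <- function(train, test, feature, n_boot = 2000, seed = 1L) {
  for (d in list(train, test))
    if (!feature %in% names(d)) stop("feature '", feature, "' missing")
  lev <- sort(unique(c(as.character(train$group), as.character(test$group))))
  if (length(lev) != 2L) stop("need exactly 2 classes")
  y_test <- as.character(test$group) == lev[2]
  if (all(y_test) || !any(y_test))
    stop("evaluation error: test half contains a single class")
  y_train <- as.character(train$group) == lev[2]

  x_train <- train[[feature]]; x_test <- test[[feature]]
  if (stats::sd(x_train) == 0) {
    scores <- rep(0.5, length(x_test))
  } else {
    fit <- suppressWarnings(
      stats::glm(y_train ~ x_train, family = stats::binomial()))
    scores <- as.numeric(stats::predict(
      fit, newdata = data.frame(x_train = x_test), type = "response"))
  }
  rp <- roc_points(scores, y_test)

  # rank-sum p for AUC = 0.5 on the test-half scores
  p <- if (length(unique(scores)) == 1L) 1 else
    suppressWarnings(stats::wilcox.test(scores[y_test],
                                        scores[!y_test])$p.value)

  set.seed(seed)
  pos <- which(y_test); neg <- which(!y_test)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    roc_points(scores[idx], y_test[idx])$auc
  }, 0)
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, na.rm = TRUE)

  structure(list(feature = feature, contrast = lev,
                 auc = rp$auc,
                 ci_low = min(ci[1], rp$auc), ci_high = max(ci[2], rp$auc),
                 p = p,
                 curve = data.frame(fpr = rp$fpr, tpr = rp$tpr),
                 split_seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s, %s vs %s: AUC %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$feature, x$contrast[1], x$contrast[2], x$auc,
              x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' ROC analysis over features and group contrasts
#'
#' For every feature and every pairwise group contrast: stratified 50/50
#' split, univariate logistic fit on the training half, ROC evaluation on
#' the test half.
#'
#' @param records data.frame with `group` and one column per feature.
#' @param features character vector of feature column names.
#' @param contrasts list of 2-element character vectors of group labels,
#'   e.g. `list(c("AD", "HC"))`.
#' @param seed integer seed controlling the split and bootstrap.
#' @param n_boot bootstrap resamples per CI.
#' @return data.frame with one row per feature x contrast (`feature`,
#'   `group_a`, `group_b`, `auc`, `ci_low`, `ci_high`, `p`); full
#'   `roc_result` objects in the `"results"` attribute.
#' @export
run_contrasts <- function(records, features, contrasts, seed = 1L,
                          n_boot = 2000) {
  results <- list()
  rows <- list()
  for (ct in contrasts) {
    miss <- setdiff(ct, unique(as.character(records$group)))
    if (length(miss)) stop("design error: unknown group(s) in contrast: ",
                           paste(miss, collapse = ", "))
    sub <- records[as.character(records$group) %in% ct, , drop = FALSE]
    sub$group <- factor(as.character(sub$group), levels = sort(ct))
    sp <- split_half(sub, seed)
    for (f in features) {
      rr <- fit_score_roc(sp$train, sp$test, f, n_boot = n_boot, seed = seed)
      key <- paste(f, ct[1], ct[2], sep = "|")
      results[[key]] <- rr
      rows[[key]] <- data.frame(feature = f, group_a = ct[1], group_b = ct[2],
                                auc = rr$auc, ci_low = rr$ci_low,
                                ci_high = rr$ci_high, p = rr$p,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Plot an ROC curve
#' @param x a `roc_result`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s: %s vs %s (AUC %.2f)", x$feature,
                                x$contrast[1], x$contrast[2], x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
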