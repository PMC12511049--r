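# Nonparametric group statistics: Kruskal-Wallis omnibus, Dunn's pairwise
# post-hoc, Holm-Bonferroni multiplicity control, Mann-Whitney U, and
# (partial) Pearson correlation.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square approximation on
#' `groups - 1` degrees of freedom.
#'
#' @param samples named list of numeric vectors, one per group.
#' @return list with `h_statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 groups")
  n_i <- lengths(samples)
  if (any(n_i < 1L)) stop("every group needs at least 1 observation")
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), n_i)
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / n_i) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  df <- length(samples) - 1L
  if (tie_corr == 0) {                         # all observations identical
    h <- 0
  } else {
    h <- h / tie_corr
  }
  list(h_statistic = h, df = df,
       p = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Dunn's pairwise post-hoc test
#'
#' Mean-rank differences over the pooled ranking, standardized with the
#' tie-corrected pooled-rank variance; two-sided p from the standard normal.
#'
#' @param samples named list of numeric vectors by group.
#' @param pairs list of 2-element character vectors naming group pairs;
#'   default: all pairs.
#' @return data.frame with columns `group_a`, `group_b`, `z`, `p`.
#' @export
dunn_posthoc <- function(samples, pairs = NULL) {
  if (any(lengths(samples) < 1L)) stop("every group needs at least 1 observation")
  gnames <- names(samples)
  if (is.null(gnames)) gnames <- as.character(seq_along(samples))
  if (is.null(pairs))
    pairs <- utils::combn(gnames, 2L, simplify = FALSE)
  x <- unlist(samples, use.names = FALSE)
  g <- rep(gnames, lengths(samples))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  out <- do.call(rbind, lapply(pairs, function(p) {
    a <- p[1]; b <- p[2]
    if (!a %in% gnames || !b %in% gnames)
      stop("unknown group in pair: ", a, " vs ", b)
    se <- sqrt(v0 * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    data.frame(group_a = a, group_b = b, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted p-values are multiplied by `m - rank + 1`, made monotone by a
#' running maximum and capped at 1; results are mapped back to the input
#' order, so the adjustment is invariant to input permutation.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m <= 1L) return(pvals)
  o <- order(pvals)
  adj <- pmin(1, cummax((m - seq_len(m) + 1L) * pvals[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test; exact for small samples without ties,
#' tie-corrected normal approximation otherwise (delegates to
#' [stats::wilcox.test()], whose W equals the U statistic of the first
#' sample).
#'
#' @param a,b numeric vectors.
#' @return list with `u_statistic`, `p`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  list(u_statistic = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation, optionally covariate-adjusted
#'
#' Plain Pearson r with the usual t-based p when `covariates` is `NULL`.
#' With covariates, both variables are residualized on the covariate matrix
#' (with intercept) and the residuals correlated; the t-test degrees of
#' freedom are reduced by the number of covariates (partial correlation).
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (rows aligned with `x`).
#' @return list with `r`, `p`, `df`, `covariates` (column names, possibly
#'   empty).
#' @export
pearson_cor <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    cov_names <- colnames(covariates) %||% paste0("c", seq_len(ncol(covariates)))
    ok <- stats::complete.cases(x, y, covariates)
  } else {
    ok <- stats::complete.cases(x, y)
  }
  x <- x[ok]; y <- y[ok]
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(x)
  if (n < 3L + k) stop("need at least ", 3L + k, " complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in x or y")
  if (k > 0L) {
    cv <- covariates[ok, , drop = FALSE]
    x <- stats::lm.fit(cbind(1, cv), x)$residuals
    y <- stats::lm.fit(cbind(1, cv), y)$residuals
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df,
       covariates = cov_names)
}

#' Group comparison of all (band, metric) variables
#'
#' For every band and metric in the long-format metrics table, runs a
#' Kruskal-Wallis omnibus across groups; Dunn's post-hoc pairwise tests are
#' computed only where the omnibus is significant at `alpha`. Holm-Bonferroni
#' adjustment of the omnibus p-values is applied within each band
#' (`family = "per_band"`, default) or across all cells
#' (`family = "global"`).
#'
#' @param metrics long-format data.frame with columns `subject_id`, `band`,
#'   `metric`, `value`.
#' @param subjects data.frame with `subject_id` and `group` (all three
#'   groups present).
#' @param alpha significance level (default 0.05, two-sided).
#' @param family Holm family rule: `"per_band"` or `"global"`.
#' @param adjust_dunn also Holm-adjust Dunn p-values within each omnibus
#'   (default `FALSE`: raw Dunn p-values are reported).
#' @return data.frame with one row per (band, metric): group means/SDs,
#'   `h_statistic`, `df`, `p_omnibus`, `p_adjusted`, and pairwise Dunn
#'   p-values (`NA` where the omnibus was not significant).
#' @export
run_group_analysis <- function(metrics, subjects, alpha = 0.05,
                               family = c("per_band", "global"),
                               adjust_dunn = FALSE) {
  family <- match.arg(family)
  need <- c("subject_id", "band", "metric", "value")
  if (!all(need %in% names(metrics)))
    stop("metrics table must have columns ", paste(need, collapse = ", "))
  groups <- levels(droplevels(factor(subjects$group)))
  if (length(groups) < 2L)
    stop("design error: need at least 2 groups with data")
  miss <- setdiff(groups, unique(as.character(subjects$group)))
  if (length(miss)) stop("design error: group(s) absent from data: ",
                         paste(miss, collapse = ", "))
  grp <- subjects$group[match(metrics$subject_id, subjects$subject_id)]
  if (anyNA(grp)) stop("metrics contain subjects missing from the subject table")
  metrics$group <- as.character(grp)

  cells <- unique(metrics[, c("band", "metric")])
  pair_names <- utils::combn(groups, 2L, paste, collapse = " vs ")
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    sub <- metrics[metrics$band == cells$band[k] &
                   metrics$metric == cells$metric[k], ]
    samples <- split(sub$value, factor(sub$group, levels = groups))
    kw <- kruskal_wallis(samples)
    row <- data.frame(band = cells$band[k], metric = cells$metric[k],
                      h_statistic = kw$h_statistic, df = kw$df,
                      p_omnibus = kw$p, stringsAsFactors = FALSE)
    for (g in groups) {
      row[[paste0("mean_", g)]] <- mean(samples[[g]])
      row[[paste0("sd_", g)]] <- stats::sd(samples[[g]])
    }
    for (pn in pair_names) row[[paste0("dunn_", pn)]] <- NA_real_
    if (kw$p < alpha) {
      dn <- dunn_posthoc(samples)
      p_dunn <- if (adjust_dunn) holm_adjust(dn$p) else dn$p
      for (q in seq_len(nrow(dn)))
        row[[paste0("dunn_", dn$group_a[q], " vs ", dn$group_b[q])]] <- p_dunn[q]
    }
    row
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- NA_real_
  if (family == "per_band") {
    for (b in unique(res$band)) {
      idx <- res$band == b
      res$p_adjusted[idx] <- holm_adjust(res$p_omnibus[idx])
    }
  } else {
    res$p_adjusted <- holm_adjust(res$p_omnibus)
  }
  res
}
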