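test_that("Kruskal-Wallis reproduces the direct rank computation", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(kw$h_statistic, 7.2)
  expect_equal(kw$df, 2L)

  same <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(same$h_statistic, 0)
  expect_equal(same$p, 1)

  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "at least 1")
})

test_that("Kruskal-Wallis agrees with the reference implementation, ties included", {
  set.seed(41)
  for (r in 1:10) {
    x <- list(round(rnorm(8), 1), round(rnorm(6), 1), round(rnorm(10), 1))
    kw <- kruskal_wallis(x)
    ref <- stats::kruskal.test(unlist(x), rep(1:3, lengths(x)))
    expect_equal(kw$h_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms of the data", {
  set.seed(42)
  x <- list(rnorm(10), rnorm(8, 1), rnorm(12, 2))
  h0 <- kruskal_wallis(x)$h_statistic
  expect_equal(kruskal_wallis(lapply(x, exp))$h_statistic, h0)
  expect_equal(kruskal_wallis(lapply(x, function(v) 3 * v - 7))$h_statistic, h0)
})

test_that("Dunn's z-based p-values match a permutation oracle", {
  set.seed(55)
  x <- list(a = rnorm(12), b = rnorm(10, 0.8), c = rnorm(14, 0.3))
  dn <- dunn_posthoc(x)
  # permutation oracle: redistribute pooled values over the group layout and
  # recompute the standardized mean-rank difference for pair (a, b)
  pooled <- unlist(x)
  sizes <- lengths(x)
  obs_z <- abs(dn$z[dn$group_a == "a" & dn$group_b == "b"])
  perm <- replicate(4000, {
    g <- sample(rep(names(sizes), sizes))
    r <- rank(pooled)
    rb <- tapply(r, g, mean)
    n <- length(pooled)
    v0 <- n * (n + 1) / 12
    abs((rb[["a"]] - rb[["b"]]) / sqrt(v0 * (1 / sizes[["a"]] + 1 / sizes[["b"]])))
  })
  p_perm <- mean(perm >= obs_z)
  p_param <- dn$p[dn$group_a == "a" & dn$group_b == "b"]
  expect_lt(abs(p_perm - p_param), 0.03)

  # n = 15 per group: mean-rank gaps large enough for z > 2.6 on every pair
  well <- list(a = 1:15, b = 31:45, c = 61:75)
  expect_true(all(dunn_posthoc(well)$p < 0.01))
  same <- dunn_posthoc(list(a = c(1, 5, 9, 2), b = c(1, 5, 9, 2)))
  expect_gt(same$p, 0.95)
  expect_error(dunn_posthoc(list(a = 1:3, b = numeric(0))), "at least 1")
})

test_that("Dunn p-values are calibrated under the null", {
  set.seed(77)
  rej <- mean(replicate(1000, {
    x <- list(a = rnorm(50), b = rnorm(50))
    dunn_posthoc(x)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Holm adjustment performs the step-down arithmetic and is order-invariant", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1.0, 1.0))

  set.seed(9)
  p <- runif(12)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"))
  perm <- sample(12)
  expect_equal(holm_adjust(p[perm]), holm_adjust(p)[perm])
  expect_true(all(holm_adjust(p) >= p))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney U behaves at separation, identity and against permutation", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_statistic, 0)
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.9)

  set.seed(23)
  a <- rnorm(9); b <- rnorm(11, 0.7)
  obs <- mann_whitney(a, b)
  pooled <- c(a, b)
  perm_u <- replicate(4000, {
    idx <- sample(20, 9)
    sum(rank(pooled)[idx]) - 9 * 10 / 2
  })
  mid <- 9 * 11 / 2
  p_perm <- mean(abs(perm_u - mid) >= abs(obs$u_statistic - mid))
  expect_lt(abs(p_perm - obs$p), 0.03)
})

test_that("Pearson correlation handles exact, partial and degenerate cases", {
  x <- 1:20
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(3, 20)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least")

  # empty covariate set equals plain Pearson exactly
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30) + 0.5 * a
  plain <- pearson_cor(a, b)
  expect_equal(plain$r, unname(cor(a, b)))
  expect_equal(plain$p, cor.test(a, b)$p.value, tolerance = 1e-12)

  # confound removal: x and y related only through z
  set.seed(12)
  z <- rnorm(200)
  x2 <- z + rnorm(200)
  y2 <- z + rnorm(200)
  raw <- pearson_cor(x2, y2)
  adj <- pearson_cor(x2, y2, covariates = data.frame(z = z))
  expect_gt(raw$r, 0.3)
  expect_lt(abs(adj$r), 0.15)
  expect_equal(adj$df, 200 - 3)
})

test_that("run_group_analysis flags injected effects and validates its design", {
  set.seed(61)
  subjects <- data.frame(
    subject_id = paste0("s", 1:45),
    group = factor(rep(c("HC", "MCI-AD", "AD"), each = 15),
                   levels = c("HC", "MCI-AD", "AD")))
  make_long <- function(shift_ad_theta) {
    rows <- expand.grid(subject_id = subjects$subject_id,
                        band = c("theta", "beta"),
                        metric = c("mean_pli", "kappa"),
                        stringsAsFactors = FALSE)
    rows$value <- rnorm(nrow(rows))
    sel <- rows$band == "theta" & rows$metric == "mean_pli" &
      rows$subject_id %in% subjects$subject_id[subjects$group == "AD"]
    rows$value[sel] <- rows$value[sel] + shift_ad_theta
    rows
  }
  res <- run_group_analysis(make_long(3), subjects)
  hit <- res[res$band == "theta" & res$metric == "mean_pli", ]
  expect_lt(hit$p_adjusted, 0.05)
  expect_false(is.na(hit$`dunn_HC vs AD`))
  expect_lt(hit$`dunn_HC vs AD`, 0.05)
  # non-shifted cells carry no post-hoc unless their omnibus fired
  quiet <- res[res$band == "beta" & res$metric == "kappa", ]
  expect_true(is.na(quiet$`dunn_HC vs AD`) || quiet$p_omnibus < 0.05)

  expect_error(run_group_analysis(make_long(0), subjects[1:15, ]),
               "design error|missing from the subject table")
  one_group <- subjects; one_group$group <- factor("HC")
  expect_error(run_group_analysis(make_long(0), one_group), "at least 2 groups")

  # Holm within band: adjusted values are a permutation-stable step-down of
  # the omnibus p-values
  for (b in unique(res$band)) {
    idx <- res$band == b
    expect_equal(res$p_adjusted[idx], holm_adjust(res$p_omnibus[idx]))
  }
})
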