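test_that("the default band set is the five classical bands", {
  b <- eeg_bands()
  expect_identical(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_identical(b$low,  c(0.5, 4, 8, 13, 30))
  expect_identical(b$high, c(4, 8, 13, 30, 48))
  expect_error(eeg_bands("mu"), "unknown band")
})

test_that("instantaneous phase of a cosine advances linearly at the tone frequency", {
  rate <- 250; f <- 10
  es <- lagged_epochs(0, n_ep = 1, rate = rate, f = f)
  ph <- instantaneous_phase(es)
  core <- 50:450
  dphi <- diff(ph$phases[1, 1, core])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - 2 * pi * f / rate)), 1e-3)
})

test_that("sine and cosine of the same tone are in quadrature", {
  rate <- 250; f <- 10
  tt <- seq(0, 2 - 1 / rate, by = 1 / rate)
  ep <- array(0, c(1, 2, length(tt)))
  ep[1, 1, ] <- cos(2 * pi * f * tt)
  ep[1, 2, ] <- sin(2 * pi * f * tt)
  ph <- instantaneous_phase(eeg_epochs(ep, rate, 2, c("c", "s")))
  core <- 50:450
  d <- ph$phases[1, 1, core] - ph$phases[1, 2, core]
  d <- (d + pi) %% (2 * pi) - pi
  expect_lt(max(abs(d - pi / 2)), 1e-2)
})

test_that("degenerate zero-variance channels are flagged, not propagated", {
  ep <- array(0, c(2, 2, 200))
  ep[, 1, ] <- matrix(rnorm(400), 2)
  es <- eeg_epochs(ep, 100, 2, c("a", "flat"))
  expect_warning(ph <- instantaneous_phase(es), "zero-variance")
  expect_true(all(ph$degenerate[, 2]))
  expect_false(any(ph$degenerate[, 1]))
  cm <- pli_matrix(ph)
  expect_equal(cm$values[1, 2], 0)
})

test_that("edge exclusion validates against the epoch length", {
  es <- lagged_epochs(pi / 2, n_ep = 1, rate = 50, dur = 2)
  expect_error(instantaneous_phase(es, edge_fraction = 0.5), "edge-exclusion")
})

test_that("PLI hits its defining extremes and intermediate values", {
  # constant quarter-cycle lag -> perfect phase locking
  cm <- pli_matrix(instantaneous_phase(lagged_epochs(pi / 2)))
  expect_equal(cm$values[1, 2], 1)
  # duplicated channel (zero lag) -> 0 by the sign(0) = 0 convention
  cm0 <- pli_matrix(instantaneous_phase(lagged_epochs(0)))
  expect_equal(cm0$values[1, 2], 0)

  # symmetric two-sided lag distribution cancels
  d <- rep(c(pi / 4, -pi / 4), each = 100)
  expect_equal(pli_matrix(phases_from_diff(d))$values[1, 2], 0)
  # 75% / 25% split -> |0.75 - 0.25| = 0.5
  d2 <- c(rep(pi / 4, 150), rep(-pi / 4, 50))
  expect_equal(pli_matrix(phases_from_diff(d2))$values[1, 2], 0.5)
})

test_that("the PLI matrix is symmetric, zero-diagonal and in [0, 1]", {
  set.seed(21)
  ep <- array(rnorm(5 * 4 * 200), c(5, 4, 200))
  cm <- pli_matrix(instantaneous_phase(eeg_epochs(ep, 100, 2, paste0("c", 1:4))))
  expect_identical(cm$values, t(cm$values))
  expect_identical(diag(cm$values), setNames(rep(0, 4), paste0("c", 1:4)))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
})

test_that("PLI ignores amplitude scaling and common phase offsets", {
  rate <- 250
  tt <- seq(0, 2 - 1 / rate, by = 1 / rate)
  set.seed(8)
  base <- replicate(10, {
    ph0 <- runif(1, 0, 2 * pi)
    rbind(cos(2 * pi * 6 * tt + ph0) + rnorm(length(tt), 0, 0.5),
          cos(2 * pi * 6 * tt + ph0 - pi / 3) + rnorm(length(tt), 0, 0.5))
  }, simplify = FALSE)
  as_epochs <- function(chunks) {
    ep <- array(0, c(length(chunks), 2, length(tt)))
    for (e in seq_along(chunks)) ep[e, , ] <- chunks[[e]]
    eeg_epochs(ep, rate, 2, c("a", "b"))
  }
  p1 <- pli_matrix(instantaneous_phase(as_epochs(base)))$values[1, 2]
  scaled <- lapply(base, function(m) m * c(5, 0.2))
  p2 <- pli_matrix(instantaneous_phase(as_epochs(scaled)))$values[1, 2]
  expect_equal(p1, p2)
})

test_that("PLI grows with SNR and approaches 1 as noise vanishes", {
  rate <- 250
  tt <- seq(0, 2 - 1 / rate, by = 1 / rate)
  set.seed(4)
  pli_at <- function(noise_sd) {
    ep <- array(0, c(20, 2, length(tt)))
    for (e in 1:20) {
      ph0 <- runif(1, 0, 2 * pi)
      ep[e, 1, ] <- cos(2 * pi * 6 * tt + ph0) + rnorm(length(tt), 0, noise_sd)
      ep[e, 2, ] <- cos(2 * pi * 6 * tt + ph0 - pi / 4) +
        rnorm(length(tt), 0, noise_sd)
    }
    pli_matrix(instantaneous_phase(eeg_epochs(ep, rate, 2, c("a", "b"))))$values[1, 2]
  }
  p <- vapply(c(3, 1, 0.3, 0), pli_at, 0)
  expect_true(all(diff(p) > 0))
  expect_equal(p[4], 1)
})

test_that("epoch averaging equals pooling when every epoch shares the lag distribution", {
  d <- rep(c(pi / 3, pi / 3, -pi / 3), 40)          # same stream every epoch
  ph4 <- phases_from_diff(d, n_ep = 4)
  a <- pli_matrix(ph4)$values[1, 2]
  b <- pli_matrix(ph4, pool_samples = TRUE)$values[1, 2]
  expect_equal(a, b)
  expect_equal(a, abs(mean(sign(sin(d)))))
})

test_that("mean PLI averages the strict upper triangle", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(0.1, 0.2, 0.6)
  m <- m + t(m)
  expect_equal(mean_pli(m), 0.3)
  cm <- matrix(0.3, 4, 4); diag(cm) <- 0
  expect_equal(mean_pli(cm), 0.3)
  expect_equal(mean_pli(matrix(0, 5, 5)), 0)
})

test_that("connectivity matrices round-trip through CSV + JSON sidecar", {
  cm <- pli_matrix(instantaneous_phase(lagged_epochs(pi / 3, n_ep = 3)),
                   band = "alpha")
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity(cm, path)
  back <- read_connectivity(path)
  expect_equal(back$values, cm$values, tolerance = 1e-12)
  expect_identical(back$band, "alpha")
  expect_equal(back$n_epochs, 3L)
})
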