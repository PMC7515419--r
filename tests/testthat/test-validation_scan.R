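test_that("interleaved split: odd frames train, even validate", {
  s <- split_interleaved(6)
  expect_equal(s$train, c(1L, 3L, 5L))
  expect_equal(s$validation, c(2L, 4L, 6L))
  s5 <- split_interleaved(5)
  expect_equal(s5$train, c(1L, 3L, 5L))
  expect_equal(s5$validation, c(2L, 4L))
  expect_error(split_interleaved(3), "4")
})

test_that("weighted Wasserstein-1: examples and the sorted-sample oracle", {
  expect_equal(wasserstein_weighted(c(1, 2, 5), c(.2, .3, .5),
                                    c(1, 2, 5), c(.2, .3, .5)), 0)
  expect_equal(wasserstein_weighted(0, 1, 3, 1), 3)
  expect_equal(wasserstein_weighted(c(0, 1), c(.5, .5), c(0, 1), c(.25, .75)), 0.25)

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    a <- rnorm(n, sd = runif(1, 0.1, 5)); b <- rnorm(n, mean = runif(1, -2, 2))
    u <- rep(1 / n, n)
    expect_equal(wasserstein_weighted(a, u, b, u),
                 mean(abs(sort(a) - sort(b))), tolerance = 1e-10)
  }
})

test_that("Wasserstein metric axioms on random weighted triples", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    mk <- function() list(x = rnorm(n, sd = 2), w = {
      w <- runif(n); w / sum(w)
    })
    A <- mk(); B <- mk(); C <- mk()
    dab <- wasserstein_weighted(A$x, A$w, B$x, B$w)
    dba <- wasserstein_weighted(B$x, B$w, A$x, A$w)
    dac <- wasserstein_weighted(A$x, A$w, C$x, C$w)
    dcb <- wasserstein_weighted(C$x, C$w, B$x, B$w)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_equal(wasserstein_weighted(A$x, A$w, A$x, A$w), 0)
    expect_lte(dab, dac + dcb + 1e-10)
  }
})

test_that("mean distribution distance averages per-column distances", {
  mA <- tiny_matrix(cbind(c(0, 0), c(0, 0)), tags = c("a", "b"))
  # point masses: column distances are exactly 0.2 and 0.4
  mB <- tiny_matrix(cbind(c(0.2, 0.2), c(0.4, 0.4)), tags = c("a", "b"))
  u <- rep(0.5, 2)
  expect_equal(mean_distribution_distance(mA, u, mB, u), 0.3)
  expect_equal(mean_distribution_distance(mA, u, mA, c(0.9, 0.1)), 0)
  # column permutation applied to both sets leaves the mean unchanged
  mA2 <- tiny_matrix(mA$values[, 2:1], tags = c("b", "a"))
  mB2 <- tiny_matrix(mB$values[, 2:1], tags = c("b", "a"))
  expect_equal(mean_distribution_distance(mA2, u, mB2, u), 0.3)
  expect_error(mean_distribution_distance(mA, u, mA2, u), "tags")
})

test_that("theta_scan: no-reweighting limit and monotone chi2_t", {
  case <- make_benchmark_case(small_config())
  calc <- align_by_tags(case$prior_cs, case$targets)
  one <- theta_scan(calc, case$targets, thetas = 1e8)
  sp <- split_interleaved(nrow(calc$values))
  ut <- uniform_weights(length(sp$train)); uv <- uniform_weights(length(sp$validation))
  mt <- observable_matrix(calc$values[sp$train, , drop = FALSE],
                          tags = case$targets$labels$tag)
  mv <- observable_matrix(calc$values[sp$validation, , drop = FALSE],
                          tags = case$targets$labels$tag)
  expect_equal(one$records$chi2_t, chi2_red(mt, ut, case$targets), tolerance = 1e-6)
  expect_equal(one$records$chi2_v, chi2_red(mv, uv, case$targets), tolerance = 1e-6)
  expect_equal(one$records$d_tv, mean_distribution_distance(mt, ut, mv, uv),
               tolerance = 1e-6)

  scan <- theta_scan(calc, case$targets, thetas = theta_grid(1e2, 1e-2, 10))
  expect_true(all(scan$records$converged))
  expect_true(all(diff(scan$records$chi2_t) <= 1e-8))
  # deterministic: rerun bit-matches
  scan2 <- theta_scan(calc, case$targets, thetas = theta_grid(1e2, 1e-2, 10))
  expect_identical(scan$records, scan2$records)
  # benchmark columns only exist in benchmark mode
  expect_false("d_tg" %in% names(scan$records))
  bench <- theta_scan(calc, case$targets, thetas = theta_grid(1, 0.5, 3),
                      target_matrix = align_by_tags(case$target_cs, case$targets))
  expect_true(all(c("d_tg", "d_vg") %in% names(bench$records)))
  # Wasserstein is a metric: triangle inequality across the three ensembles
  with(bench$records, expect_true(all(d_tg <= d_tv + d_vg + 1e-10)))
})

fake_scan <- function(theta, chi2_v, d_tv = rev(seq_along(theta)) * 0.01) {
  structure(list(records = data.frame(theta = theta, chi2_t = chi2_v / 2,
                                      chi2_v = chi2_v, neff_t = 0.5,
                                      lambda_rms = 0.1, d_tv = d_tv,
                                      converged = TRUE),
                 split = split_interleaved(10), lambdas = list(),
                 metadata = list()),
            class = "theta_scan_result")
}

test_that("select_theta: argmin, boundary and tie rules", {
  s <- fake_scan(c(100, 10, 3, 1, 0.1), c(10, 5, 3, 4, 6))
  expect_equal(select_theta(s, "min_chi2_v")$theta_star, 3)

  s2 <- fake_scan(c(100, 10, 3, 1, 0.1), c(10, 8, 6, 4, 2))
  sel2 <- select_theta(s2)
  expect_equal(sel2$theta_star, 0.1)
  expect_match(sel2$diagnostics, "no overfitting detected")

  s3 <- fake_scan(c(100, 10, 3, 1, 0.1), c(10, 5, 3, 3, 6))
  expect_equal(select_theta(s3)$theta_star, 3)  # tie -> larger theta

  # elbow rule: d_tv flat then kinking upward at the 4th point
  lt <- c(100, 10, 3, 1, 0.1)
  s4 <- fake_scan(lt, c(10, 5, 3, 4, 6), d_tv = c(0.01, 0.011, 0.012, 0.2, 1.2))
  expect_equal(select_theta(s4, "d_tv_elbow")$theta_star, 1)

  expect_error(select_theta(fake_scan(c(2, 1), c(1, 2))), "3")
})

test_that("runs test: counts, alternating case, degenerate input", {
  rt <- runs_test(c(1, 2, 3, -1, -2, -3))
  expect_equal(rt$n_runs, 2L)
  alt <- runs_test(rep(c(1, -1), 5))
  expect_equal(alt$n_runs, 10L)
  expect_gt(alt$z, 0)
  # zeros are dropped before dichotomizing
  expect_equal(runs_test(c(1, 0, 1, -1))$n_runs, 2L)
  expect_error(runs_test(c(0, 0, 0)), "nonzero")
  one_sided <- runs_test(c(1, 2, 3))
  expect_equal(one_sided$n_runs, 1L)
  expect_true(one_sided$p >= 0 && one_sided$p <= 1)
})

test_that("runs-test enumeration oracle matches the closed-form moments", {
  mom <- runs_enumeration(5, 5)
  n1 <- 5; n2 <- 5; n <- 10
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  expect_equal(unname(mom["mean"]), mu, tolerance = 1e-12)
  expect_equal(unname(mom["var"]), v, tolerance = 1e-12)
})

test_that("refit_full_ensemble accepts selections and recovers the prior at huge theta", {
  case <- make_benchmark_case(small_config())
  calc <- align_by_tags(case$prior_cs, case$targets)
  sol <- refit_full_ensemble(calc, case$targets, 1e8)
  expect_equal(sol$weights$weights, rep(1 / nrow(calc$values), nrow(calc$values)),
               tolerance = 1e-6)
  sel <- structure(list(theta_star = 1e8, rule = "min_chi2_v", diagnostics = ""),
                   class = "theta_selection")
  expect_equal(refit_full_ensemble(calc, case$targets, sel)$theta, 1e8)
})

test_that("lag-1 autocorrelation is near zero for i.i.d. frames and detects persistence", {
  cfg <- small_config(n_frames = 1500L)
  iid <- make_benchmark_case(cfg)
  ac <- lag1_autocorrelation(iid$prior_cs)
  expect_lt(max(abs(ac), na.rm = TRUE), 0.12)
  sticky <- make_benchmark_case(small_config(n_frames = 1500L,
                                             markov_persistence = 0.9))
  ac2 <- lag1_autocorrelation(sticky$prior_cs)
  expect_gt(mean(ac2, na.rm = TRUE), mean(ac, na.rm = TRUE))
})
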