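test_that("ss ensemble generation: degenerate, deterministic, calibrated", {
  zero <- generate_ss_ensemble(rep(0, 6), n_frames = 20, seed = 1)
  expect_true(all(zero$codes == "C"))

  a <- generate_ss_ensemble(rep(0.4, 6), 50, seed = 3)
  b <- generate_ss_ensemble(rep(0.4, 6), 50, seed = 3)
  c <- generate_ss_ensemble(rep(0.4, 6), 50, seed = 4)
  expect_identical(a$codes, b$codes)
  expect_false(identical(a$codes, c$codes))

  # with min_helix_run = 1 the empirical helicity is binomial around p
  p <- c(0.05, 0.2, 0.5, 0.8)
  n <- 5000
  ss <- generate_ss_ensemble(p, n, min_helix_run = 1, seed = 11)
  emp <- colMeans(ss$codes == "H")
  expect_true(all(abs(emp - p) <= 3 * sqrt(p * (1 - p) / n)))

  # min_helix_run flips short helices to coil
  ss3 <- generate_ss_ensemble(rep(0.3, 8), 200, min_helix_run = 3, seed = 5)
  runs <- apply(ss3$codes, 1, function(r) {
    rl <- rle(r); min(c(Inf, rl$lengths[rl$values == "H"]))
  })
  expect_true(all(runs >= 3))
})

test_that("predictor A: baseline, saturation, neighbour window", {
  cfg <- generator_config(n_frames = 2L, n_residues = 7L,
                          propensity_target = rep(0.5, 7),
                          propensity_prior = rep(0.5, 7),
                          thermal_sd = 1e-12, cb_exclude = integer(0))
  allC <- ss_matrix(matrix("C", 2, 7))
  csC <- predict_shifts_A(allC, cfg)
  for (a in c("CA", "CB", "C")) {
    cols <- csC$labels$atom_kind == a
    expect_equal(unname(csC$values[, cols]),
                 matrix(cfg$coil_base[[a]], 2, sum(cols)), tolerance = 1e-9)
  }
  allH <- ss_matrix(matrix("H", 2, 7))
  csH <- predict_shifts_A(allH, cfg)
  for (a in c("CA", "CB", "C")) {
    cols <- csH$labels$atom_kind == a
    expect_equal(unname(csH$values[, cols]),
                 matrix(cfg$coil_base[[a]] + cfg$helix_delta[[a]], 2, sum(cols)),
                 tolerance = 1e-9)
  }
  # isolated H at residue 4 (window 1) raises f only at residues 3, 4, 5
  cfg1 <- generator_config(n_frames = 2L, n_residues = 7L,
                           propensity_target = rep(0.5, 7),
                           propensity_prior = rep(0.5, 7),
                           thermal_sd = 1e-12, cb_exclude = integer(0),
                           min_helix_run = 1L)
  iso <- matrix("C", 2, 7); iso[, 4] <- "H"
  csI <- predict_shifts_A(ss_matrix(iso), cfg1)
  ca <- csI$labels$atom_kind == "CA"
  f <- (csI$values[1, ca] - cfg1$coil_base[["CA"]]) / cfg1$helix_delta[["CA"]]
  names(f) <- csI$labels$residue_index[ca]
  expect_equal(unname(f[c("2", "6")]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(f[c("3", "5")]), c(1 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(unname(f["4"]), 1 / 3, tolerance = 1e-9)
})

test_that("predictor B: degenerate identity, mean offsets, state dependence", {
  cfg0 <- small_config()
  args <- unclass(cfg0)
  args$predB_systematic <- matrix(0, 3, 2, dimnames = list(c("CA", "CB", "C"), c("H", "C")))
  args$predB_random_sd <- 1e-12
  cfg_id <- do.call(generator_config, args)
  ss <- generate_ss_ensemble(cfg_id$propensity_prior, 50, cfg_id$min_helix_run, seed = 2)
  A <- predict_shifts_A(ss, cfg_id, seed = 9)
  B <- predict_shifts_B(ss, cfg_id, seed = 9)
  expect_equal(B$values, A$values, tolerance = 1e-9)

  # constant offset per atom shifts column means by that offset (up to noise)
  args$predB_systematic <- matrix(c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6), 3, 2,
                                  dimnames = list(c("CA", "CB", "C"), c("H", "C")))
  args$predB_random_sd <- 0.1
  args$n_frames <- 3000L
  cfg_c <- do.call(generator_config, args)
  ss2 <- generate_ss_ensemble(cfg_c$propensity_prior, 3000, cfg_c$min_helix_run, seed = 2)
  A2 <- predict_shifts_A(ss2, cfg_c, seed = 9)
  B2 <- predict_shifts_B(ss2, cfg_c, seed = 9)
  dmean <- colMeans(B2$values) - colMeans(A2$values)
  expect_true(all(abs(dmean - 0.6) < 4 * 0.1 / sqrt(3000) + 1e-9))

  # H-state-only offsets correlate the A-B residual with helicity
  args$predB_systematic <- cbind(H = c(1, 1, 1), C = c(0, 0, 0))
  rownames(args$predB_systematic) <- c("CA", "CB", "C")
  cfg_h <- do.call(generator_config, args)
  B3 <- predict_shifts_B(ss2, cfg_h, seed = 9)
  hel <- colMeans(ss2$codes == "H")
  dm <- colMeans(B3$values) - colMeans(A2$values)
  per_res <- tapply(dm, B3$labels$residue_index, mean)
  expect_gt(cor(per_res, hel[as.integer(names(per_res))]), 0.9)
})

test_that("target set construction: means and per-atom sigmas", {
  cfg <- small_config()
  cs <- tiny_matrix(cbind(c(55, 57), c(29, 31), c(175, 177)),
                    tags = c("res2_CA", "res2_CB", "res2_C"))
  ts <- make_target_set(cs, cfg)
  expect_equal(ts$values, c(56, 30, 176))
  expect_equal(ts$sigmas, unname(c(1.06, 1.23, 1.32)))
})

test_that("benchmark case: determinism, support check, stream independence", {
  cfg <- small_config()
  c1 <- make_benchmark_case(cfg)
  c2 <- make_benchmark_case(cfg)
  expect_identical(c1$prior_cs$values, c2$prior_cs$values)
  expect_identical(c1$target_ss$codes, c2$target_ss$codes)
  expect_identical(c1$targets$values, c2$targets$values)
  expect_true(all(c1$target_in_support))
  expect_false(c1$self_fit)

  # toggling predictor-B error must not perturb conformations or the targets
  args <- unclass(cfg); args$predB_random_sd <- 0.9
  c3 <- make_benchmark_case(do.call(generator_config, args))
  expect_identical(c3$target_cs$values, c1$target_cs$values)
  expect_identical(c3$prior_ss$codes, c1$prior_ss$codes)
  expect_identical(c3$targets$values, c1$targets$values)
  expect_false(identical(c3$prior_cs$values, c1$prior_cs$values))

  # self-fit reuses the very same conformations
  args <- unclass(cfg); args$propensity_prior <- args$propensity_target
  c4 <- make_benchmark_case(do.call(generator_config, args))
  expect_true(c4$self_fit)
  expect_identical(c4$prior_ss$codes, c4$target_ss$codes)
})

test_that("perfect-model control: self-fit without predictor error stays uniform", {
  args <- unclass(small_config(n_frames = 800L))
  args$propensity_prior <- args$propensity_target
  args$predB_systematic <- matrix(0, 3, 2, dimnames = list(c("CA", "CB", "C"), c("H", "C")))
  args$predB_random_sd <- 1e-6
  case <- make_benchmark_case(do.call(generator_config, args))
  calc <- align_by_tags(case$prior_cs, case$targets)
  scan <- theta_scan(calc, case$targets, thetas = theta_grid(1e2, 1e-2, 6))
  expect_true(all(scan$records$converged))
  # chi2 sits at the (tiny) half-sample noise floor and N_eff stays ~1
  expect_true(all(scan$records$chi2_t < 1e-3))
  expect_true(all(scan$records$neff_t > 0.95))
})

test_that("rg proxy: baseline, monotone trend, correlation scale", {
  allC <- ss_matrix(matrix("C", 10, 5))
  expect_equal(rg_proxy(allC, c0 = 26, c1 = 8, noise_sd = 1e-12, seed = 1),
               rep(26, 10), tolerance = 1e-9)
  set.seed(33)
  codes <- matrix(sample(c("H", "C"), 4000 * 5, TRUE), 4000, 5)
  ss <- ss_matrix(codes)
  h <- rowMeans(codes == "H")
  g <- rg_proxy(ss, c0 = 26, c1 = 8, noise_sd = 1, seed = 2)
  expect_lt(cor(g, h), 0)
  expect_equal(cor(g, h), -8 * sd(h) / sd(g), tolerance = 0.05)
})

test_that("config validation and JSON round trip", {
  expect_error(generator_config(n_residues = 10L,
                                propensity_target = rep(0.5, 4),
                                propensity_prior = rep(0.5, 10)),
               "propensity_target")
  expect_error(generator_config(thermal_sd = 0), "thermal_sd")
  cfg <- small_config()
  p <- tempfile(fileext = ".json")
  write_config_json(cfg, p)
  cfg2 <- read_config_json(p)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  # round-tripped config regenerates the identical case
  expect_identical(make_benchmark_case(cfg2)$prior_cs$values,
                   make_benchmark_case(cfg)$prior_cs$values)
})
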