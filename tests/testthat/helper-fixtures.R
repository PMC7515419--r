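# Shared fixtures and independent oracles. The oracles here deliberately
# avoid the package's dual-space solution path: the primal objective is
# minimised directly (simplex grid / softmax parameterisation via
# stats::optim), so they can arbitrate the dual derivation.

make_tags <- function(m) sprintf("res%d_CA", seq_len(m) + 1L)

tiny_matrix <- function(values, tags = NULL) {
  values <- as.matrix(values)
  if (is.null(tags)) tags <- make_tags(ncol(values))
  observable_matrix(values, tags = tags)
}

# Random small reweighting instance with the target inside the span of the
# per-column values (so every theta is feasible).
random_instance <- function(N = sample(3:20, 1), m = sample(1:3, 1)) {
  X <- matrix(rnorm(N * m, mean = sample(c(0, 5, 50), 1), sd = runif(1, 0.5, 2)), N, m)
  wmix <- runif(N); wmix <- wmix / sum(wmix)
  y <- drop(crossprod(X, wmix)) + rnorm(m, sd = 0.05)
  # keep y strictly inside each column's range
  y <- pmin(pmax(y, apply(X, 2, min) + 1e-6), apply(X, 2, max) - 1e-6)
  sig <- runif(m, 0.5, 2)
  list(matrix = tiny_matrix(X), targets = target_set(make_tags(m), y, sig),
       X = X, y = y, sig = sig)
}

# Primal objective L(w) = (m/2) chi2_red(w) - theta * S_REL(w), uniform prior.
primal_objective <- function(w, X, y, sig, theta) {
  N <- nrow(X); m <- ncol(X)
  mu <- drop(crossprod(X, w))
  chi2 <- mean(((mu - y) / sig)^2)
  pos <- w > 0
  srel <- -sum(w[pos] * log(w[pos] * N))
  m / 2 * chi2 - theta * srel
}

# Softmax-parameterised direct minimisation of the primal over the simplex.
primal_softmax_oracle <- function(X, y, sig, theta) {
  N <- nrow(X)
  obj <- function(z) {
    z <- z - max(z)
    w <- exp(z) / sum(exp(z))
    primal_objective(w, X, y, sig, theta)
  }
  best <- NULL
  for (start in list(rep(0, N), rnorm(N, sd = 0.5))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  z <- best$par - max(best$par)
  exp(z) / sum(exp(z))
}

# Two-stage exhaustive grid over the 2-simplex (N = 3, m = 1 only).
primal_grid_oracle_n3 <- function(X, y, sig, theta, coarse = 5e-3, fine = 5e-5) {
  eval_grid <- function(w1, w2) {
    keep <- outer(w1, w2, function(a, b) a + b <= 1)
    idx <- which(keep, arr.ind = TRUE)
    vals <- vapply(seq_len(nrow(idx)), function(k) {
      a <- w1[idx[k, 1]]; b <- w2[idx[k, 2]]
      primal_objective(c(a, b, 1 - a - b), X, y, sig, theta)
    }, numeric(1))
    k <- which.min(vals)
    c(w1[idx[k, 1]], w2[idx[k, 2]])
  }
  g <- eval_grid(seq(0, 1, by = coarse), seq(0, 1, by = coarse))
  lo1 <- max(0, g[1] - 2 * coarse); hi1 <- min(1, g[1] + 2 * coarse)
  lo2 <- max(0, g[2] - 2 * coarse); hi2 <- min(1, g[2] + 2 * coarse)
  g <- eval_grid(seq(lo1, hi1, by = fine), seq(lo2, hi2, by = fine))
  c(g[1], g[2], 1 - g[1] - g[2])
}

# Exact run-count distribution for n1 pluses and n2 minuses by enumeration
# of all distinct arrangements.
runs_enumeration <- function(n1, n2) {
  n <- n1 + n2
  pos_sets <- utils::combn(n, n1)
  counts <- apply(pos_sets, 2L, function(pos) {
    s <- rep(-1L, n); s[pos] <- 1L
    1L + sum(diff(s) != 0L)
  })
  c(mean = mean(counts), var = mean((counts - mean(counts))^2))
}

# A small, fast benchmark configuration for unit tests (not the acceptance
# world, which uses the package defaults).
small_config <- function(seed = 7L, n_frames = 600L, ...) {
  generator_config(n_frames = n_frames, n_residues = 15L,
                   propensity_target = helix_bump_profile(15L, 0.6, 5:10, 0.1),
                   propensity_prior = helix_bump_profile(15L, 0.25, 5:10, 0.1),
                   cb_exclude = 7L, seed = seed, ...)
}

expect_tsv_roundtrip <- function(write_fn, read_fn, obj) {
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_fn(obj, p1)
  write_fn(read_fn(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
}
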