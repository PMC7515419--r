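# Bayesian/Maximum-Entropy reweighting core.
#
# The primal problem minimises, over the probability simplex,
#     L(w) = (m/2) chi2_red(w) - theta * S_REL(w),
# where chi2_red is the reduced chi-squared of ensemble-averaged observables
# against targets and S_REL = -sum w log(w/w0) <= 0 is the (negative) KL
# divergence from the prior weights. The optimal weights are exponential
# tilts of the prior, w_i ∝ w0_i exp(-sum_j lambda_j CS_ji), with one
# Lagrange parameter per observable. The solver works in the dual:
#     Gamma(lambda) = ln Z(lambda) + sum_j lambda_j CS_EXP_j
#                     + (theta/2) sum_j sigma_j^2 lambda_j^2,
# which is smooth, convex and coercive for theta > 0, and is minimised by a
# damped Newton iteration with analytic gradient and Hessian
#     grad_j = CS_EXP_j - <CS_j>_w + theta sigma_j^2 lambda_j
#     Hess   = Cov_w(CS) + theta diag(sigma^2).

#' Solver settings for [solve_bme()]
#'
#' @param grad_tol convergence threshold: sup-norm of the dual gradient (ppm).
#' @param max_iter maximum Newton iterations.
#' @param lambda_init `"zeros"` or a numeric vector of starting Lagrange
#'   parameters (used for warm starts along a theta scan).
#' @param warm_start logical; scans reuse the previous theta's lambda when TRUE.
#' @return a `solver_settings` list.
#' @export
solver_settings <- function(grad_tol = 1e-8, max_iter = 200L,
                            lambda_init = "zeros", warm_start = TRUE) {
  stopifnot(is.numeric(grad_tol), grad_tol > 0, max_iter >= 1)
  if (!identical(lambda_init, "zeros")) stopifnot(is.numeric(lambda_init))
  structure(list(grad_tol = grad_tol, max_iter = as.integer(max_iter),
                 lambda_init = lambda_init, warm_start = isTRUE(warm_start)),
            class = "solver_settings")
}

check_aligned <- function(matrix, targets) {
  if (!identical(obs_tags(matrix), targets$labels$tag))
    stop_format("observable matrix and target set are not aligned; call align_by_tags() first")
}

#' Reduced chi-squared of weighted averages against targets
#'
#' `(1/m) sum_i (<CS_i>_w - CS_EXP_i)^2 / sigma_i^2`, the normalized residual
#' measure of the fit. Its absolute value is only as meaningful as the sigmas.
#'
#' @param matrix aligned [observable_matrix()].
#' @param w frame weights.
#' @param targets [target_set()].
#' @return nonnegative scalar.
#' @export
chi2_red <- function(matrix, w, targets) {
  check_aligned(matrix, targets)
  mu <- weighted_observable_means(matrix, w)
  mean(((mu - targets$values) / targets$sigmas)^2)
}

#' Relative entropy of weights against a prior
#'
#' `S_REL = -sum_i w_i log(w_i / w0_i)`, with `0 log 0 = 0`. Always <= 0 and
#' zero iff `w = w0`. Requires absolute continuity (`w_i > 0` implies
#' `w0_i > 0`).
#'
#' @param w posterior weights.
#' @param w0 prior weights.
#' @return nonpositive scalar.
#' @export
relative_entropy <- function(w, w0) {
  w <- as_weights(w); w0 <- as_weights(w0, n = length(w))
  pos <- w > 0
  if (any(pos & w0 <= 0))
    stop_format("support violation: w puts mass where the prior has none")
  s <- -sum(w[pos] * log(w[pos] / w0[pos]))
  min(s, 0)  # clamp +eps rounding at w == w0
}

#' Entropy-based effective sample size
#'
#' `N_eff = exp(S_REL)`: 1 when all frames keep their prior weight, towards 0
#' as the weight concentrates on few frames.
#'
#' @param s_rel nonpositive relative entropy.
#' @return scalar in (0, 1].
#' @export
effective_sample_size <- function(s_rel) {
  if (!is.numeric(s_rel) || length(s_rel) != 1L || is.na(s_rel) || s_rel > 0)
    stop_format("s_rel must be a single nonpositive number")
  exp(s_rel)
}

#' Weights induced by Lagrange parameters
#'
#' `w_i ∝ w0_i exp(-sum_j lambda_j CS_ji)`, normalized; computed with a
#' max-shift so large lambdas cannot overflow. Adding a constant to any
#' observable column leaves the weights unchanged (absorbed by Z).
#'
#' @param matrix [observable_matrix()] (columns in lambda order).
#' @param lambdas numeric vector, one per observable.
#' @param w0 prior weights (default uniform).
#' @return a [weight_vector()].
#' @export
apply_lambdas <- function(matrix, lambdas, w0 = NULL) {
  stopifnot(inherits(matrix, "observable_matrix"))
  X <- matrix$values
  if (length(lambdas) != ncol(X))
    stop_format("lambda length %d does not match %d observables",
                length(lambdas), ncol(X))
  if (is.null(w0)) w0 <- uniform_weights(nrow(X))
  w0 <- as_weights(w0, n = nrow(X))
  logw <- log(w0) - drop(X %*% lambdas)
  logw <- logw - max(logw)
  w <- exp(logw)
  if (any(!is.finite(w))) stop_format("non-finite weights from apply_lambdas")
  weight_vector(w / sum(w), description = "exponential tilt of prior")
}

#' Dual objective and gradient of the BME problem
#'
#' Returns `Gamma(lambda)` and its analytic gradient (see file header).
#' `Gamma` is convex in lambda for any theta > 0.
#'
#' @param lambdas numeric vector, one per observable.
#' @param matrix aligned [observable_matrix()].
#' @param targets [target_set()].
#' @param theta positive confidence hyperparameter.
#' @param w0 prior weights (default uniform).
#' @return list with elements `value` and `gradient`.
#' @export
dual_value_and_gradient <- function(lambdas, matrix, targets, theta, w0 = NULL) {
  check_aligned(matrix, targets)
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  X <- matrix$values
  if (is.null(w0)) w0 <- uniform_weights(nrow(X))
  w0 <- as_weights(w0, n = nrow(X))
  # Work with target-centered columns: ln Z(X - y) = ln Z(X) + sum(lambda * y)
  # exactly, so the value below IS Gamma, with O(1) conditioning instead of
  # O(|y| * |lambda|) cancellation.
  Xc <- sweep(X, 2L, targets$values, "-")
  a <- log(w0) - drop(Xc %*% lambdas)
  amax <- max(a)
  logZc <- amax + log(sum(exp(a - amax)))
  if (!is.finite(logZc)) stop_format("non-finite partition function")
  w <- exp(a - logZc)
  muc <- unname(drop(crossprod(Xc, w)))
  value <- logZc + theta / 2 * sum(targets$sigmas^2 * lambdas^2)
  gradient <- -muc + theta * targets$sigmas^2 * unname(as.numeric(lambdas))
  list(value = value, gradient = gradient)
}

#' Root-mean-square of the Lagrange parameters
#'
#' The magnitude of the lambdas, not theta, measures how strong the
#' reweighting is; a sharp growth of this RMS along a descending theta scan
#' marks the onset of strong, theta-sensitive fitting.
#'
#' @param lambdas numeric vector.
#' @return `sqrt(mean(lambdas^2))`.
#' @export
lambda_rms <- function(lambdas) {
  if (length(lambdas) < 1L) stop_format("lambda vector is empty")
  sqrt(mean(lambdas^2))
}

#' Solve the BME reweighting problem at a fixed theta
#'
#' Minimises the dual by damped Newton with backtracking line search; the
#' returned weights satisfy the stationarity relation
#' `<CS_j>_w - CS_EXP_j = theta sigma_j^2 lambda_j` to within `grad_tol`.
#' Non-convergence is reported via the `converged` flag, never silently.
#'
#' @inheritParams dual_value_and_gradient
#' @param settings a [solver_settings()].
#' @return object of class `reweight_solution`: fields `theta`, `lambdas`,
#'   `weights` ([weight_vector()]), `chi2_red`, `s_rel`, `n_eff`, `converged`,
#'   `n_iter`.
#' @export
solve_bme <- function(matrix, targets, theta, w0 = NULL,
                      settings = solver_settings()) {
  check_aligned(matrix, targets)
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (theta <= 0)
    stop_format("theta must be > 0 (pure maximum entropy is outside this model; use a small theta)")
  X <- matrix$values
  N <- nrow(X); m <- ncol(X)
  if (N < 2L) stop_format("need at least 2 frames to reweight")
  if (is.null(w0)) w0 <- uniform_weights(N)
  w0v <- as_weights(w0, n = N)
  y <- targets$values; s2 <- targets$sigmas^2
  logw0 <- log(w0v)
  # Target-centered columns: identical dual value/gradient (see
  # dual_value_and_gradient) but numerically well conditioned.
  Xc <- sweep(X, 2L, y, "-")

  lam <- if (identical(settings$lambda_init, "zeros")) numeric(m) else {
    li <- as.numeric(settings$lambda_init)
    if (length(li) != m) stop_format("lambda_init length %d != m = %d", length(li), m)
    li
  }

  gamma_at <- function(l) {
    a <- logw0 - drop(Xc %*% l)
    amax <- max(a)
    logZc <- amax + log(sum(exp(a - amax)))
    logZc + theta / 2 * sum(s2 * l^2)
  }

  converged <- FALSE
  iter <- 0L
  repeat {
    a <- logw0 - drop(Xc %*% lam)
    amax <- max(a)
    logZc <- amax + log(sum(exp(a - amax)))
    w <- exp(a - logZc)
    muc <- unname(drop(crossprod(Xc, w)))
    g <- -muc + theta * s2 * lam
    if (max(abs(g)) <= settings$grad_tol) { converged <- TRUE; break }
    if (iter >= settings$max_iter) break
    iter <- iter + 1L
    # Hessian: weighted covariance of the observables + quadratic term
    Xw <- Xc * w
    H <- crossprod(Xw, Xc) - tcrossprod(muc)
    diag(H) <- diag(H) + theta * s2
    step <- tryCatch(-solve(H, g), error = function(e) {
      diag(H) <- diag(H) + 1e-10 * max(diag(H), 1)
      -solve(H, g)
    })
    f0 <- logZc + theta / 2 * sum(s2 * lam^2)
    slope <- sum(g * step)
    if (abs(slope) < 1e-13 * (1 + abs(f0))) {
      # predicted decrease below the noise floor of the log-sum-exp: we are
      # deep in the quadratic basin, the undamped Newton step is safe
      lam <- lam + step
      next
    }
    t <- 1
    ok <- FALSE
    for (bt in 1:60) {
      if (gamma_at(lam + t * step) <= f0 + 1e-4 * t * slope) { ok <- TRUE; break }
      t <- t / 2
    }
    if (!ok) break  # line search failed; report non-convergence
    lam <- lam + t * step
  }

  weights <- apply_lambdas(matrix, lam, w0)
  srel <- relative_entropy(weights, w0v)
  structure(list(theta = theta,
                 lambdas = lam,
                 weights = weights,
                 chi2_red = chi2_red(matrix, weights, targets),
                 s_rel = srel,
                 n_eff = effective_sample_size(srel),
                 converged = converged,
                 n_iter = iter),
            class = "reweight_solution")
}

#' @export
print.reweight_solution <- function(x, ...) {
  cat(sprintf(paste0("<reweight_solution> theta=%.4g chi2_red=%.6g ",
                     "N_eff=%.4f S_REL=%.4g converged=%s (%d iter)\n"),
              x$theta, x$chi2_red, x$n_eff, x$s_rel, x$converged, x$n_iter))
  invisible(x)
}

#' Serialize a reweight solution to JSON
#'
#' Weights themselves go to TSV via [write_weights()]; the JSON carries theta,
#' lambdas and the scalar fit statistics.
#'
#' @param x a `reweight_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(x, path) {
  stopifnot(inherits(x, "reweight_solution"))
  jsonlite::write_json(
    list(theta = x$theta, lambdas = x$lambdas, chi2_red = x$chi2_red,
         s_rel = x$s_rel, n_eff = x$n_eff, converged = x$converged,
         n_iter = x$n_iter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
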