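# Theta selection by interleaved train/validation scanning.
#
# Procedure: (1) split frames into interleaved halves (odd -> training,
# even -> validation); (2) for each theta on a descending grid, fit the BME
# to the training half and transfer the optimized lambdas to the validation
# half; (3) track chi2(t), chi2(v), N_eff(t), the lambda RMS, and mean
# Wasserstein-1 distances between the reweighted train/validation
# distributions (and, when a ground-truth ensemble is available, between each
# of them and the truth). The optimal theta is where the validation chi2 is
# smallest; past it, chi2(v) grows and D(t,v) develops high curvature — both
# are overfitting signatures.

#' Interleaved train/validation split
#'
#' Odd frames (1-based) form the training set, even frames the validation
#' set. Deterministic — no RNG. Equal-size halves keep the standard error of
#' validated means comparable to the training means.
#'
#' @param n_frames total number of frames (>= 4).
#' @return object of class `split_indices` with integer fields `train`,
#'   `validation`.
#' @export
split_interleaved <- function(n_frames) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 4L)
    stop_format("need at least 4 frames to split (got %s)", n_frames)
  structure(list(train = seq(1L, n_frames, by = 2L),
                 validation = seq(2L, n_frames, by = 2L)),
            class = "split_indices")
}

#' Wasserstein-1 distance between two weighted empirical distributions
#'
#' Exact `integral |F_a(x) - F_b(x)| dx` over the merged support, where `F`
#' are the weighted empirical CDFs. For equal-size uniform-weight samples
#' this reduces to the mean absolute difference of the sorted values.
#'
#' @param values_a,values_b numeric sample values.
#' @param w_a,w_b weights (a [weight_vector()] or bare nonnegative numerics
#'   summing to 1).
#' @return nonnegative scalar distance.
#' @export
wasserstein_weighted <- function(values_a, w_a, values_b, w_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 1L || length(b) < 1L) stop_format("empty sample")
  wa <- as_weights(w_a, n = length(a))
  wb <- as_weights(w_b, n = length(b))
  x <- c(a, b)
  ord <- order(x)
  xs <- x[ord]
  ca <- cumsum(c(wa, numeric(length(b)))[ord])
  cb <- cumsum(c(numeric(length(a)), wb)[ord])
  k <- length(xs)
  sum(abs(ca[-k] - cb[-k]) * diff(xs))
}

#' Mean distribution distance over a set of observables
#'
#' The per-observable Wasserstein-1 distances averaged over columns: a single
#' similarity measure between two sets of weighted distributions.
#'
#' @param matrix_a,matrix_b [observable_matrix()] objects with identical tags.
#' @param w_a,w_b frame weights for each ensemble.
#' @return nonnegative scalar.
#' @export
mean_distribution_distance <- function(matrix_a, w_a, matrix_b, w_b) {
  stopifnot(inherits(matrix_a, "observable_matrix"),
            inherits(matrix_b, "observable_matrix"))
  if (!identical(obs_tags(matrix_a), obs_tags(matrix_b)))
    stop_format("observable tags differ between the two ensembles")
  wa <- as_weights(w_a, n = nrow(matrix_a$values))
  wb <- as_weights(w_b, n = nrow(matrix_b$values))
  d <- vapply(seq_len(ncol(matrix_a$values)), function(i) {
    wasserstein_weighted(matrix_a$values[, i], wa, matrix_b$values[, i], wb)
  }, numeric(1))
  mean(d)
}

#' Default theta grid
#'
#' Log-spaced descending grid; the default (1e2 down to 1e-3, 30 points)
#' brackets both the no-reweighting plateau and the strong-overfitting regime.
#'
#' @param theta_max,theta_min grid endpoints (positive).
#' @param n number of points.
#' @return numeric vector, strictly decreasing.
#' @export
theta_grid <- function(theta_max = 1e2, theta_min = 1e-3, n = 30L) {
  stopifnot(theta_max > 0, theta_min > 0, theta_max > theta_min, n >= 2)
  10^seq(log10(theta_max), log10(theta_min), length.out = n)
}

#' Scan a theta grid with interleaved cross-validation
#'
#' For each theta (descending, warm-started from the previous fit): fit the
#' training half with a uniform prior, record `chi2_t`, `neff_t` and the
#' lambda RMS; transfer the lambdas to the validation half (uniform prior,
#' no refit) and record `chi2_v`; record the mean Wasserstein distance
#' `d_tv` between the reweighted train and validation distributions. If a
#' ground-truth ensemble is supplied (benchmark mode), also record `d_tg`
#' and `d_vg` against it.
#'
#' @param matrix [observable_matrix()] aligned to `targets`.
#' @param targets [target_set()].
#' @param thetas positive theta grid (sorted descending internally).
#' @param w0 optional prior weights over all frames (default uniform); the
#'   train/validation subsets renormalize their slices.
#' @param settings [solver_settings()].
#' @param target_matrix optional ground-truth [observable_matrix()] with the
#'   same tags (benchmark mode).
#' @param target_weights optional weights for the ground-truth ensemble
#'   (default uniform).
#' @return object of class `theta_scan_result`: `records` (data.frame, one
#'   row per theta, descending), `split`, `lambdas` (list per theta), and
#'   `metadata`.
#' @export
theta_scan <- function(matrix, targets, thetas = theta_grid(), w0 = NULL,
                       settings = solver_settings(),
                       target_matrix = NULL, target_weights = NULL) {
  check_aligned(matrix, targets)
  thetas <- sort(unique(as.numeric(thetas)), decreasing = TRUE)
  if (any(thetas <= 0)) stop_format("theta grid must be strictly positive")
  N <- nrow(matrix$values)
  split <- split_interleaved(N)
  if (is.null(w0)) w0 <- uniform_weights(N)
  w0v <- as_weights(w0, n = N)

  subset_matrix <- function(idx) {
    observable_matrix(matrix$values[idx, , drop = FALSE], tags = obs_tags(matrix),
                      frame_ids = matrix$frame_ids[idx])
  }
  mt <- subset_matrix(split$train)
  mv <- subset_matrix(split$validation)
  w0t <- weight_vector(w0v[split$train], normalize = TRUE)
  w0vl <- weight_vector(w0v[split$validation], normalize = TRUE)

  benchmark <- !is.null(target_matrix)
  if (benchmark) {
    if (!identical(obs_tags(target_matrix), obs_tags(matrix)))
      stop_format("target ensemble tags differ from the fitted ensemble")
    if (is.null(target_weights))
      target_weights <- uniform_weights(nrow(target_matrix$values))
    wg <- as_weights(target_weights, n = nrow(target_matrix$values))
  }

  nt <- length(thetas)
  rec <- data.frame(theta = thetas, chi2_t = NA_real_, chi2_v = NA_real_,
                    neff_t = NA_real_, lambda_rms = NA_real_, d_tv = NA_real_,
                    converged = FALSE)
  if (benchmark) { rec$d_tg <- NA_real_; rec$d_vg <- NA_real_ }
  lambdas <- vector("list", nt)

  lam_prev <- NULL
  for (k in seq_len(nt)) {
    st <- settings
    if (settings$warm_start && !is.null(lam_prev)) st$lambda_init <- lam_prev
    sol <- solve_bme(mt, targets, thetas[k], w0 = w0t, settings = st)
    if (sol$converged) lam_prev <- sol$lambdas
    lambdas[[k]] <- sol$lambdas
    wv <- apply_lambdas(mv, sol$lambdas, w0 = w0vl)
    rec$chi2_t[k] <- sol$chi2_red
    rec$chi2_v[k] <- chi2_red(mv, wv, targets)
    rec$neff_t[k] <- sol$n_eff
    rec$lambda_rms[k] <- lambda_rms(sol$lambdas)
    rec$d_tv[k] <- mean_distribution_distance(mt, sol$weights, mv, wv)
    rec$converged[k] <- sol$converged
    if (benchmark) {
      rec$d_tg[k] <- mean_distribution_distance(mt, sol$weights, target_matrix, wg)
      rec$d_vg[k] <- mean_distribution_distance(mv, wv, target_matrix, wg)
    }
  }

  structure(list(records = rec, split = split, lambdas = lambdas,
                 metadata = list(n_frames = N, m = ncol(matrix$values),
                                 grid = thetas, benchmark = benchmark,
                                 grad_tol = settings$grad_tol)),
            class = "theta_scan_result")
}

#' @export
print.theta_scan_result <- function(x, ...) {
  cat(sprintf("<theta_scan_result> %d thetas [%.3g .. %.3g], %d frames, benchmark=%s\n",
              nrow(x$records), max(x$records$theta), min(x$records$theta),
              x$metadata$n_frames, x$metadata$benchmark))
  invisible(x)
}

#' Select the optimal theta from a scan
#'
#' Rule `min_chi2_v` (default, the operational signal): the LARGEST grid
#' theta attaining the minimum of the validation chi-squared — ties prefer
#' the least reweighting. Rule `d_tv_elbow` (advisory confirmation): the
#' theta of maximum discrete second difference of `d_tv` against `ln theta`,
#' i.e. where the train/validation distributions start diverging fastest.
#' Non-converged records are excluded.
#'
#' @param scan a [theta_scan_result][theta_scan()].
#' @param rule `"min_chi2_v"` or `"d_tv_elbow"`.
#' @return object of class `theta_selection`: `theta_star`, `rule`,
#'   `diagnostics` (text).
#' @export
select_theta <- function(scan, rule = c("min_chi2_v", "d_tv_elbow")) {
  stopifnot(inherits(scan, "theta_scan_result"))
  rule <- match.arg(rule)
  rec <- scan$records[scan$records$converged, , drop = FALSE]
  if (nrow(rec) < 3L)
    stop_format("need at least 3 converged scan points (got %d)", nrow(rec))
  # records are in descending theta order; the first argmin is the largest theta
  i_chi <- which.min(rec$chi2_v)
  theta_chi <- rec$theta[i_chi]
  lt <- log(rec$theta)
  d <- rec$d_tv
  n <- nrow(rec)
  # second divided difference of d_tv wrt ln(theta) at interior points
  curv <- rep(NA_real_, n)
  for (i in 2:(n - 1L)) {
    h1 <- lt[i - 1L] - lt[i]; h2 <- lt[i] - lt[i + 1L]
    curv[i] <- 2 * ((d[i - 1L] - d[i]) / h1 - (d[i] - d[i + 1L]) / h2) / (h1 + h2)
  }
  i_elb <- which.max(curv)
  theta_elb <- rec$theta[i_elb]
  notes <- sprintf("min_chi2_v: theta=%.6g (chi2_v=%.6g); d_tv_elbow: theta=%.6g",
                   theta_chi, rec$chi2_v[i_chi], theta_elb)
  if (i_chi == n)
    notes <- paste(notes, "; no overfitting detected in grid (chi2_v still decreasing)")
  theta_star <- if (rule == "min_chi2_v") theta_chi else theta_elb
  structure(list(theta_star = theta_star, rule = rule, diagnostics = notes),
            class = "theta_selection")
}

#' @export
print.theta_selection <- function(x, ...) {
  cat(sprintf("<theta_selection> theta*=%.6g (rule %s)\n  %s\n",
              x$theta_star, x$rule, x$diagnostics))
  invisible(x)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Dichotomizes the ordered residuals by sign (zeros dropped), counts runs,
#' and reports the normal-approximation z and two-sided p from the standard
#' run-count mean `mu = 2 n+ n- / n + 1` and variance
#' `(mu-1)(mu-2)/(n-1)`. Long same-sign stretches (few runs, z << 0)
#' indicate remaining systematic misfit.
#'
#' @param residuals numeric vector, ordered meaningfully (here: residue-major,
#'   atom CA/CB/C minor, so stretches are sequence-contiguous).
#' @return list with `n_runs`, `z`, `p`, plus the counts `n_pos`, `n_neg`.
#' @export
runs_test <- function(residuals) {
  r <- as.numeric(residuals)
  r <- r[r != 0]
  if (length(r) < 2L)
    stop_format("need at least 2 nonzero residuals for a runs test")
  s <- sign(r)
  n_runs <- 1L + sum(diff(s) != 0)
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) {  # all one sign: degenerate, runs always 1
    z <- 0; p <- 1
  } else {
    z <- (n_runs - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(n_runs = n_runs, z = z, p = p, n_pos = n1, n_neg = n2)
}

#' Refit the full ensemble at the selected theta
#'
#' The split scan only determines theta; the production weights come from a
#' fit of ALL frames, uniform prior, at theta*.
#'
#' @param matrix [observable_matrix()] aligned to `targets` (all frames).
#' @param targets [target_set()].
#' @param theta_star a positive scalar or a [theta_selection][select_theta()].
#' @param settings [solver_settings()].
#' @return a `reweight_solution` (see [solve_bme()]).
#' @export
refit_full_ensemble <- function(matrix, targets, theta_star,
                                settings = solver_settings()) {
  if (inherits(theta_star, "theta_selection")) theta_star <- theta_star$theta_star
  solve_bme(matrix, targets, theta_star, w0 = NULL, settings = settings)
}

#' Lag-1 autocorrelation of each observable across frames
#'
#' Diagnostic only: the interleaved split assumes neighbouring frames are
#' close to uncorrelated; large lag-1 autocorrelations mean the validation
#' half is not independent and overfitting may go undetected.
#'
#' @param matrix an [observable_matrix()].
#' @return named numeric vector (one value per observable; NA for constant
#'   columns).
#' @export
lag1_autocorrelation <- function(matrix) {
  stopifnot(inherits(matrix, "observable_matrix"))
  X <- matrix$values
  n <- nrow(X)
  if (n < 3L) stop_format("need at least 3 frames for a lag-1 autocorrelation")
  out <- vapply(seq_len(ncol(X)), function(i) {
    x <- X[, i]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x[-n], x[-1L])
  }, numeric(1))
  names(out) <- obs_tags(matrix)
  out
}

#' Write scan results
#'
#' The TSV holds one row per theta with all record columns; the JSON adds the
#' split and metadata.
#'
#' @param scan a [theta_scan_result][theta_scan()].
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_scan_result <- function(scan, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(scan, "theta_scan_result"))
  if (!is.null(tsv_path)) {
    rec <- scan$records
    num <- vapply(rec, is.numeric, logical(1))
    out <- rec
    out[num] <- lapply(rec[num], fmt_num)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(records = scan$records,
                              split = scan$split[c("train", "validation")],
                              metadata = scan$metadata),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
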