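# Seeded helix-coil benchmark generator. Emulates the paper-style design of
# reweighting studies on disordered proteins: a "target" ensemble whose
# predicted average shifts play the role of experimental data, and a
# mismatched "prior" ensemble (different per-residue helix propensity) whose
# shifts come from a second predictor carrying systematic (atom- and
# state-dependent) plus random error. All randomness flows from one base
# seed through documented, independent sub-streams (conformations, thermal
# noise, predictor-B noise), so toggling one error source leaves the others
# bit-identical.

# Sub-stream offsets from the base seed (kept < 2^31 for R's 32-bit seeds).
SEED_CONF_TARGET <- 101L
SEED_CONF_PRIOR  <- 202L
SEED_THERM_TARGET <- 303L
SEED_THERM_PRIOR  <- 404L
SEED_PREDB        <- 505L

#' Helix-propensity profile with a single bump
#'
#' Background propensity everywhere, raised to `bump` over `region` — the
#' shape of a disordered chain with one partially formed helix.
#'
#' @param n_residues chain length.
#' @param bump propensity inside the region.
#' @param region integer residue indices of the helical region.
#' @param background propensity elsewhere.
#' @return numeric vector of length `n_residues` in `[0, 1]`.
#' @export
helix_bump_profile <- function(n_residues = 71L, bump = 0.6, region = 25:45,
                               background = 0.1) {
  if (any(region < 1L | region > n_residues))
    stop_format("bump region must lie within 1..%d", n_residues)
  p <- rep(background, n_residues)
  p[region] <- bump
  stopifnot(all(p >= 0 & p <= 1))
  p
}

#' Generator configuration for synthetic benchmark cases
#'
#' Defaults state the package's reference world: a 71-residue chain (the
#' length of the ACTR benchmark system), 4000 frames, a target ensemble with
#' helix propensity 0.6 over residues 25-45 on a 0.1 coil background, a
#' prior ensemble with the same region at only 0.25, coil baselines / helix
#' deltas following the standard helix secondary-shift convention
#' (CA +2.6, CB -0.5, C +1.8 ppm on coil baselines 56 / 30 / 176 ppm),
#' thermal spread 0.3 ppm, and a second predictor whose systematic error
#' (0.4 ppm on helical residues, signed along the helix delta) plus random
#' error (0.3 ppm) stands in for the disagreement between two real
#' chemical-shift predictors. Target sigmas are the published forward-model
#' errors 1.06 / 1.23 / 1.32 ppm for CA / CB / C.
#'
#' @param n_frames frames per ensemble.
#' @param n_residues chain length R.
#' @param propensity_target,propensity_prior per-residue helix propensities
#'   in `[0,1]`, length R.
#' @param min_helix_run H-runs shorter than this are flipped to coil
#'   (helices need several consecutive residues to count as helix).
#' @param coil_base,helix_delta named (CA, CB, C) baselines and helix
#'   increments, ppm.
#' @param neighbor_window shifts respond to the helical fraction in a window
#'   of +/- this many residues (chemical shifts feel neighbouring residues).
#' @param thermal_sd per-frame random spread of predictor A, ppm.
#' @param predB_systematic 3 x 2 matrix (rows CA, CB, C; columns H, C):
#'   systematic offset of predictor B by atom kind and conformational state.
#' @param predB_random_sd extra random error of predictor B, ppm.
#' @param target_sigmas named (CA, CB, C) uncertainties for the target set.
#' @param cb_exclude residues with no CB observable (stand-in for glycines).
#' @param markov_persistence probability that a residue copies its previous
#'   frame's state instead of redrawing (0 = i.i.d. frames; > 0 stresses the
#'   correlated-validation-set caveat).
#' @param seed base seed for all sub-streams.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_frames = 4000L,
                             n_residues = 71L,
                             propensity_target = helix_bump_profile(n_residues, 0.6),
                             propensity_prior = helix_bump_profile(n_residues, 0.25),
                             min_helix_run = 3L,
                             coil_base = c(CA = 56.0, CB = 30.0, C = 176.0),
                             helix_delta = c(CA = 2.6, CB = -0.5, C = 1.8),
                             neighbor_window = 1L,
                             thermal_sd = 0.3,
                             predB_systematic = default_predB_systematic(helix_delta),
                             predB_random_sd = 0.3,
                             target_sigmas = c(CA = 1.06, CB = 1.23, C = 1.32),
                             cb_exclude = c(8L, 15L, 29L, 40L, 55L),
                             markov_persistence = 0,
                             seed = 1L) {
  cfg <- list(n_frames = as.integer(n_frames), n_residues = as.integer(n_residues),
              propensity_target = as.numeric(propensity_target),
              propensity_prior = as.numeric(propensity_prior),
              min_helix_run = as.integer(min_helix_run),
              coil_base = coil_base, helix_delta = helix_delta,
              neighbor_window = as.integer(neighbor_window),
              thermal_sd = thermal_sd,
              predB_systematic = predB_systematic,
              predB_random_sd = predB_random_sd,
              target_sigmas = target_sigmas,
              cb_exclude = as.integer(cb_exclude),
              markov_persistence = markov_persistence,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

default_predB_systematic <- function(helix_delta = c(CA = 2.6, CB = -0.5, C = 1.8)) {
  # 0.4 ppm on helical residues, signed like the helix delta: the predictor
  # "sees" extra helicity, so fitting it pushes weights toward lower helicity.
  m <- cbind(H = 0.4 * sign(helix_delta), C = c(0, 0, 0))
  rownames(m) <- c("CA", "CB", "C")
  m
}

validate_generator_config <- function(cfg) {
  R <- cfg$n_residues
  if (length(cfg$propensity_target) != R)
    stop_format("propensity_target must have length n_residues = %d (got %d)",
                R, length(cfg$propensity_target))
  if (length(cfg$propensity_prior) != R)
    stop_format("propensity_prior must have length n_residues = %d (got %d)",
                R, length(cfg$propensity_prior))
  for (p in c("propensity_target", "propensity_prior"))
    if (any(cfg[[p]] < 0 | cfg[[p]] > 1)) stop_format("%s must lie in [0,1]", p)
  for (nm in c("coil_base", "helix_delta", "target_sigmas"))
    if (!all(c("CA", "CB", "C") %in% names(cfg[[nm]])))
      stop_format("%s must be named with CA, CB, C", nm)
  if (cfg$thermal_sd <= 0 || cfg$predB_random_sd <= 0)
    stop_format("thermal_sd and predB_random_sd must be > 0")
  if (cfg$min_helix_run < 1L) stop_format("min_helix_run must be >= 1")
  if (cfg$neighbor_window < 0L) stop_format("neighbor_window must be >= 0")
  if (!is.matrix(cfg$predB_systematic) ||
      !all(rownames(cfg$predB_systematic) == c("CA", "CB", "C")) ||
      ncol(cfg$predB_systematic) != 2L)
    stop_format("predB_systematic must be a 3x2 matrix with rows CA, CB, C and columns H, C")
  if (cfg$markov_persistence < 0 || cfg$markov_persistence >= 1)
    stop_format("markov_persistence must be in [0, 1)")
  if (cfg$n_frames < 2L) stop_format("n_frames must be >= 2")
  invisible(cfg)
}

# Flip H-runs shorter than min_run to C, rowwise.
enforce_min_run <- function(codes, min_run) {
  if (min_run <= 1L) return(codes)
  for (j in seq_len(nrow(codes))) {
    r <- rle(codes[j, ])
    short <- r$values == "H" & r$lengths < min_run
    if (any(short)) {
      r$values[short] <- "C"
      codes[j, ] <- inverse.rle(r)
    }
  }
  codes
}

#' Sample a helix/coil secondary-structure ensemble
#'
#' Each residue is helical with its propensity, independently per frame
#' (or with Markov persistence across frames when `persistence > 0`); then
#' H-runs shorter than `min_helix_run` are flipped to coil. Deterministic
#' given the seed.
#'
#' @param propensity per-residue helix probability in `[0,1]`.
#' @param n_frames number of frames.
#' @param min_helix_run minimum surviving H-run length.
#' @param seed RNG seed for this stream.
#' @param persistence Markov copy probability across consecutive frames.
#' @return an [ss_matrix()].
#' @export
generate_ss_ensemble <- function(propensity, n_frames, min_helix_run = 1L,
                                 seed = 1L, persistence = 0) {
  stopifnot(all(propensity >= 0 & propensity <= 1), n_frames >= 1)
  R <- length(propensity)
  set.seed(as.integer(seed))
  H <- matrix(stats::runif(n_frames * R) < rep(propensity, each = n_frames),
              nrow = n_frames)
  if (persistence > 0 && n_frames > 1L) {
    keep <- matrix(stats::runif(n_frames * R) < persistence, nrow = n_frames)
    for (j in 2:n_frames) {
      cp <- keep[j, ]
      H[j, cp] <- H[j - 1L, cp]
    }
  }
  codes <- matrix("C", n_frames, R)
  codes[H] <- "H"
  codes <- enforce_min_run(codes, min_helix_run)
  ss_matrix(codes, frame_ids = seq_len(n_frames))
}

# Windowed helical fraction per (frame, residue): mean of the H indicator over
# residues r-w .. r+w, clipped at chain ends.
windowed_helicity <- function(codes, window) {
  H <- (codes == "H") * 1
  if (window == 0L) return(H)
  N <- nrow(H); R <- ncol(H)
  S <- cbind(0, t(apply(H, 1L, cumsum)))  # N x (R+1) prefix sums
  out <- matrix(0, N, R)
  for (r in seq_len(R)) {
    lo <- max(1L, r - window); hi <- min(R, r + window)
    out[, r] <- (S[, hi + 1L] - S[, lo]) / (hi - lo + 1L)
  }
  out
}

# The observable roster: CA and C for residues 2..R-1; CB for residues
# 2..R-1 minus the cb_exclude mask. Columns are residue-major, atom minor
# (CA, CB, C), so residual sequences are sequence-contiguous.
observable_roster <- function(cfg) {
  R <- cfg$n_residues
  inner <- 2:(R - 1L)
  rows <- list()
  for (r in inner) {
    atoms <- c("CA", if (!(r %in% cfg$cb_exclude)) "CB", "C")
    rows[[length(rows) + 1L]] <- data.frame(residue = r, atom = atoms,
                                            stringsAsFactors = FALSE)
  }
  ros <- do.call(rbind, rows)
  ros$tag <- sprintf("res%d_%s", ros$residue, ros$atom)
  ros
}

#' Parametric forward model A (reference predictor)
#'
#' For residue r, atom a, frame j:
#' `CS = coil_base[a] + helix_delta[a] * f_jr + eps`, where `f_jr` is the
#' helical fraction in the window `r +/- neighbor_window` and
#' `eps ~ N(0, thermal_sd)`. Plays the role of the predictor used to make
#' the target data.
#'
#' @param ss an [ss_matrix()].
#' @param config a [generator_config()].
#' @param seed base seed for this prediction's noise stream.
#' @return an [observable_matrix()] (residue-major, atom CA/CB/C minor).
#' @export
predict_shifts_A <- function(ss, config, seed = config$seed) {
  stopifnot(inherits(ss, "ss_matrix"), inherits(config, "generator_config"))
  if (ncol(ss$codes) != config$n_residues)
    stop_format("ss matrix has %d residues, config says %d",
                ncol(ss$codes), config$n_residues)
  ros <- observable_roster(config)
  f <- windowed_helicity(ss$codes, config$neighbor_window)
  N <- nrow(ss$codes)
  vals <- matrix(NA_real_, N, nrow(ros))
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(N * nrow(ros), sd = config$thermal_sd), N)
  for (i in seq_len(nrow(ros))) {
    a <- ros$atom[i]; r <- ros$residue[i]
    vals[, i] <- config$coil_base[[a]] + config$helix_delta[[a]] * f[, r] + noise[, i]
  }
  observable_matrix(vals, tags = ros$tag, frame_ids = ss$frame_ids)
}

#' Parametric forward model B (error-bearing predictor)
#'
#' Predictor A's value (same thermal stream for the same base seed) plus a
#' systematic offset depending on atom kind and the residue's own state
#' (H vs not-H), plus independent noise `eta ~ N(0, predB_random_sd)` from
#' its own stream. With zero systematic offsets and vanishing random sd it
#' degenerates to predictor A.
#'
#' @inheritParams predict_shifts_A
#' @return an [observable_matrix()].
#' @export
predict_shifts_B <- function(ss, config, seed = config$seed) {
  base <- predict_shifts_A(ss, config, seed = seed)
  ros <- observable_roster(config)
  N <- nrow(ss$codes)
  helical <- ss$codes == "H"
  set.seed(as.integer(seed) + SEED_PREDB)
  eta <- matrix(stats::rnorm(N * nrow(ros), sd = config$predB_random_sd), N)
  vals <- base$values
  for (i in seq_len(nrow(ros))) {
    a <- ros$atom[i]; r <- ros$residue[i]
    off <- ifelse(helical[, r],
                  config$predB_systematic[a, "H"],
                  config$predB_systematic[a, "C"])
    vals[, i] <- vals[, i] + off + eta[, i]
  }
  observable_matrix(vals, tags = ros$tag, frame_ids = ss$frame_ids)
}

#' Build the target set from the target ensemble's predictions
#'
#' Values are uniform-weight column means of the target ensemble's predictor-A
#' matrix; sigmas are assigned by atom kind from `config$target_sigmas`
#' (defaults 1.06 / 1.23 / 1.32 ppm for CA / CB / C).
#'
#' @param target_cs_A [observable_matrix()] from [predict_shifts_A()] on the
#'   target ensemble.
#' @param config a [generator_config()].
#' @return a [target_set()].
#' @export
make_target_set <- function(target_cs_A, config) {
  stopifnot(inherits(target_cs_A, "observable_matrix"))
  mu <- colMeans(target_cs_A$values)
  kinds <- target_cs_A$labels$atom_kind
  if (any(kinds == "OTHER")) stop_format("unresolvable atom kind in target matrix")
  target_set(obs_tags(target_cs_A), mu, config$target_sigmas[kinds])
}

#' Assemble a complete benchmark case
#'
#' Target ensemble (target propensity, predictor A, producing the target set)
#' plus a prior ensemble to reweight (prior propensity, predictor B). When
#' the two propensity profiles are identical the case is a self-fit: the
#' SAME conformations and the same predictor-A thermal stream are reused, so
#' predictor B differs from the target predictions by exactly its systematic
#' offsets plus its own noise — the pure predictor-error experiment.
#'
#' Also verifies the reweightability precondition that every target value
#' lies inside the min-max range of the prior ensemble's column values, and
#' records the result in `target_in_support`.
#'
#' @param config a [generator_config()].
#' @return object of class `benchmark_case`: `target_cs`, `target_ss`,
#'   `prior_cs`, `prior_ss`, `targets`, `truth` (the config),
#'   `target_in_support` (logical per observable), `self_fit` flag.
#' @export
make_benchmark_case <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  s <- config$seed
  self_fit <- identical(config$propensity_target, config$propensity_prior)
  target_ss <- generate_ss_ensemble(config$propensity_target, config$n_frames,
                                    config$min_helix_run, seed = s + SEED_CONF_TARGET,
                                    persistence = config$markov_persistence)
  prior_ss <- if (self_fit) target_ss else
    generate_ss_ensemble(config$propensity_prior, config$n_frames,
                         config$min_helix_run, seed = s + SEED_CONF_PRIOR,
                         persistence = config$markov_persistence)
  target_cs <- predict_shifts_A(target_ss, config, seed = s + SEED_THERM_TARGET)
  prior_cs <- predict_shifts_B(prior_ss, config,
                               seed = if (self_fit) s + SEED_THERM_TARGET
                                      else s + SEED_THERM_PRIOR)
  targets <- make_target_set(target_cs, config)
  lo <- apply(prior_cs$values, 2L, min)
  hi <- apply(prior_cs$values, 2L, max)
  in_support <- targets$values >= lo & targets$values <= hi
  if (!all(in_support))
    warning(sprintf("%d target value(s) outside the prior ensemble's value range; reweighting may not converge",
                    sum(!in_support)), call. = FALSE)
  structure(list(target_cs = target_cs, target_ss = target_ss,
                 prior_cs = prior_cs, prior_ss = prior_ss,
                 targets = targets, truth = config,
                 target_in_support = in_support, self_fit = self_fit),
            class = "benchmark_case")
}

#' @export
print.benchmark_case <- function(x, ...) {
  cat(sprintf("<benchmark_case> N=%d frames, R=%d residues, m=%d observables, self_fit=%s\n",
              x$truth$n_frames, x$truth$n_residues, length(x$targets$values),
              x$self_fit))
  invisible(x)
}

#' Radius-of-gyration proxy per frame
#'
#' A scalar per-frame stand-in for a compaction observable:
#' `c0 - c1 * (global helical fraction of the frame) + noise`. Helical
#' structures are compact, so higher helicity gives a smaller proxy. Used
#' only to demonstrate that an observable weakly coupled to the fitted data
#' is a poor cross-validation signal.
#'
#' @param ss an [ss_matrix()].
#' @param c0 baseline value (arbitrary units; default 26, an expanded-coil
#'   scale).
#' @param c1 compaction per unit helicity (default 8).
#' @param noise_sd random spread (default 1).
#' @param seed RNG seed.
#' @return numeric vector, one value per frame.
#' @export
rg_proxy <- function(ss, c0 = 26, c1 = 8, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(ss, "ss_matrix"))
  h <- rowMeans(ss$codes == "H")
  set.seed(as.integer(seed))
  c0 - c1 * h + stats::rnorm(nrow(ss$codes), sd = noise_sd)
}

#' Write a benchmark case to a directory
#'
#' Emits the four ensemble files, the target TSV and a truth JSON (full
#' config echo) — the plain-text interchange layout consumed by the CLI.
#'
#' @param case a [make_benchmark_case()] result.
#' @param dir output directory (created if missing).
#' @return character vector of the six file paths, invisibly.
#' @export
write_benchmark_case <- function(case, dir) {
  stopifnot(inherits(case, "benchmark_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    write_observable_matrix(case$target_cs, file.path(dir, "target_cs.tsv")),
    write_ss_matrix(case$target_ss, file.path(dir, "target_ss.tsv")),
    write_observable_matrix(case$prior_cs, file.path(dir, "prior_cs.tsv")),
    write_ss_matrix(case$prior_ss, file.path(dir, "prior_ss.tsv")),
    write_target_set(case$targets, file.path(dir, "targets.tsv")),
    write_config_json(case$truth, file.path(dir, "truth.json")))
  invisible(paths)
}

#' Read / write a generator config as JSON
#'
#' The JSON echoes every field (defaults included) so a written config fully
#' reproduces its case.
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @return `write_config_json`: `path` invisibly; `read_config_json`: a
#'   [generator_config()].
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$predB_systematic <- list(H = unname(x$predB_systematic[, "H"]),
                             C = unname(x$predB_systematic[, "C"]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(generator_config)
  args <- list()
  for (nm in names(x)) {
    if (nm == "predB_systematic") {
      m <- cbind(H = x$predB_systematic$H, C = x$predB_systematic$C)
      rownames(m) <- c("CA", "CB", "C")
      args$predB_systematic <- m
    } else if (nm %in% c("coil_base", "helix_delta", "target_sigmas")) {
      v <- unlist(x[[nm]])
      if (is.null(names(v)) || !all(c("CA", "CB", "C") %in% names(v)))
        names(v) <- c("CA", "CB", "C")
      args[[nm]] <- v
    } else if (nm %in% names(defaults)) {
      args[[nm]] <- x[[nm]]
    }
  }
  do.call(generator_config, args)
}
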