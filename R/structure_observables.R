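# Secondary-structure-derived quantities: per-residue helicity under weights,
# the random-coil chemical-shift reference, and secondary chemical shifts
# (shift minus the coil reference). Subtracting each ensemble's own coil
# reference cancels constant per-atom predictor baselines — the mechanism by
# which secondary shifts suppress spurious reweighting from predictor offsets.

#' Weighted per-residue helical content
#'
#' Fraction of ensemble weight on frames where each residue carries code `H`.
#' Affine in the weights and bounded in `[0, 1]`; with uniform weights it is
#' the plain frame count over N.
#'
#' @param ss an [ss_matrix()].
#' @param w frame weights.
#' @return numeric vector of length R (residues) in `[0, 1]`.
#' @export
helical_fraction <- function(ss, w) {
  stopifnot(inherits(ss, "ss_matrix"))
  w <- as_weights(w, n = nrow(ss$codes))
  drop(crossprod(ss$codes == "H", w))
}

#' Random-coil chemical-shift reference from an ensemble
#'
#' For each observable (residue position, atom kind): the prior-weighted mean
#' of its calculated shifts over the frames in which that residue is in coil
#' (`C`). Computed with the PRIOR weights, never reweighted ones, so the
#' observable map stays fixed across the whole theta scan. Cells whose
#' residue is never in coil fall back to the atom kind's pooled coil mean and
#' are reported with coverage 0.
#'
#' @param cs [observable_matrix()] whose tags resolve to (residue, atom).
#' @param ss [ss_matrix()] covering those residues.
#' @param w0 prior weights (default uniform).
#' @param pool `"position"` (default): one reference per residue position;
#'   `"atom_kind"`: a single pooled value per atom kind for every position.
#' @return object of class `coil_reference`: data.frame `table` with columns
#'   `tag`, `residue_index`, `atom_kind`, `ref`, `coverage`, plus `pooled`
#'   (named per-atom-kind fallback means).
#' @export
coil_reference <- function(cs, ss, w0 = NULL, pool = c("position", "atom_kind")) {
  stopifnot(inherits(cs, "observable_matrix"), inherits(ss, "ss_matrix"))
  pool <- match.arg(pool)
  lab <- cs$labels
  if (anyNA(lab$residue_index) || any(lab$atom_kind == "OTHER"))
    stop_format("coil reference needs tags of the form res<k>_<CA|CB|C>; offending: %s",
                paste(utils::head(lab$tag[is.na(lab$residue_index)], 5), collapse = ", "))
  R <- ncol(ss$codes)
  if (any(lab$residue_index > R))
    stop_format("observable residue index exceeds %d residues in ss matrix", R)
  N <- nrow(cs$values)
  if (nrow(ss$codes) != N) stop_format("cs and ss frame counts differ")
  if (is.null(w0)) w0 <- uniform_weights(N)
  w0 <- as_weights(w0, n = N)

  coil <- ss$codes == "C"
  m <- ncol(cs$values)
  ref <- numeric(m); cov <- integer(m)
  num_k <- c(CA = 0, CB = 0, C = 0); den_k <- c(CA = 0, CB = 0, C = 0)
  for (i in seq_len(m)) {
    r <- lab$residue_index[i]
    sel <- coil[, r]
    cov[i] <- sum(sel)
    wsum <- sum(w0[sel])
    ref[i] <- if (wsum > 0) sum(w0[sel] * cs$values[sel, i]) / wsum else NA_real_
    a <- lab$atom_kind[i]
    num_k[a] <- num_k[a] + sum(w0[sel] * cs$values[sel, i])
    den_k[a] <- den_k[a] + wsum
  }
  pooled <- ifelse(den_k > 0, num_k / den_k, NA_real_)
  used_kinds <- unique(lab$atom_kind)
  dead <- used_kinds[den_k[used_kinds] == 0]
  if (length(dead))
    stop_format("no coil frames anywhere for atom kind(s): %s", paste(dead, collapse = ", "))
  if (pool == "atom_kind") {
    ref <- pooled[lab$atom_kind]
  } else {
    fall <- is.na(ref) | cov == 0
    ref[fall] <- pooled[lab$atom_kind[fall]]
  }
  structure(list(table = data.frame(tag = lab$tag,
                                    residue_index = lab$residue_index,
                                    atom_kind = lab$atom_kind,
                                    ref = as.numeric(ref), coverage = cov,
                                    stringsAsFactors = FALSE),
                 pooled = pooled, pool = pool),
            class = "coil_reference")
}

#' @export
print.coil_reference <- function(x, ...) {
  cat(sprintf("<coil_reference> %d observables (pool=%s), %d zero-coverage fallback(s)\n",
              nrow(x$table), x$pool, sum(x$table$coverage == 0)))
  invisible(x)
}

ref_lookup <- function(ref, tags) {
  idx <- match(tags, ref$table$tag)
  if (anyNA(idx))
    stop_format("coil reference does not cover tag(s): %s",
                paste(tags[is.na(idx)], collapse = ", "))
  ref$table$ref[idx]
}

#' Secondary chemical shifts of an ensemble
#'
#' Subtracts the random-coil reference from every frame's calculated shift:
#' `delta CS[j, i] = CS[j, i] - ref(residue_i, atom_i)`. Coil frames then
#' average to ~0 in each column by construction of the reference.
#'
#' @param cs [observable_matrix()].
#' @param ref a [coil_reference()] covering all of `cs`'s tags.
#' @return an [observable_matrix()] of secondary shifts (same tags/frames).
#' @export
secondary_shifts <- function(cs, ref) {
  stopifnot(inherits(cs, "observable_matrix"), inherits(ref, "coil_reference"))
  r <- ref_lookup(ref, obs_tags(cs))
  observable_matrix(sweep(cs$values, 2L, r, "-"), tags = obs_tags(cs),
                    frame_ids = cs$frame_ids)
}

#' Secondary-shift version of a target set
#'
#' In benchmark mode the target values are ensemble averages of the truth
#' ensemble, so their coil reference must come from the TARGET ensemble's own
#' frames (uniform weights), mirroring how the fitted ensemble's secondary
#' shifts are built. Sigmas are unchanged (a constant subtraction).
#'
#' @param target_cs a [target_set()].
#' @param target_ensemble_cs [observable_matrix()] of the target ensemble.
#' @param target_ss [ss_matrix()] of the target ensemble.
#' @param pool passed to [coil_reference()].
#' @return a [target_set()] of secondary target values.
#' @export
secondary_target_set <- function(target_cs, target_ensemble_cs, target_ss,
                                 pool = "position") {
  stopifnot(inherits(target_cs, "target_set"))
  ref <- coil_reference(target_ensemble_cs, target_ss, w0 = NULL, pool = pool)
  r <- ref_lookup(ref, target_cs$labels$tag)
  target_set(target_cs$labels$tag, target_cs$values - r, target_cs$sigmas)
}

#' Write a per-residue helicity profile as TSV
#'
#' @param fractions numeric vector (one per residue) or a matrix/data.frame of
#'   named profiles with R rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_helicity <- function(fractions, path) {
  df <- if (is.null(dim(fractions))) data.frame(fraction = as.numeric(fractions))
        else as.data.frame(fractions)
  out <- cbind(residue = seq_len(nrow(df)), df)
  num <- vapply(out, is.numeric, logical(1)); num["residue"] <- FALSE
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coil reference as TSV
#' @param ref a [coil_reference()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coil_reference <- function(ref, path) {
  stopifnot(inherits(ref, "coil_reference"))
  out <- ref$table
  out$ref <- fmt_num(out$ref)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
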