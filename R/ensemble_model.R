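# Atom kinds recognised in observable tags; everything else is OTHER.
ATOM_KINDS <- c("CA", "CB", "C", "OTHER")

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

#' Parse observable tags into residue/atom metadata
#'
#' Tags of the form `res<k>_<ATOM>` (e.g. `res12_CA`) yield
#' `residue_index = k` and `atom_kind` in `CA`, `CB`, `C`; anything else gets
#' `atom_kind = "OTHER"` and `residue_index = NA`. The tag string is the join
#' key between calculated and target data; the parsed metadata is only used by
#' the secondary-structure layer.
#'
#' @param tags character vector of observable tags.
#' @return data.frame with columns `tag`, `residue_index`, `atom_kind`.
#' @export
parse_observable_labels <- function(tags) {
  stopifnot(is.character(tags))
  m <- regmatches(tags, regexec("^res([0-9]+)_(CA|CB|C)$", tags))
  residue <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[2L]) else NA_integer_,
                    integer(1))
  atom <- vapply(m, function(x) if (length(x) == 3L) x[3L] else "OTHER", character(1))
  bad <- !is.na(residue) & residue < 1L
  if (any(bad)) stop_format("residue index must be >= 1 in tag(s): %s",
                            paste(tags[bad], collapse = ", "))
  data.frame(tag = tags, residue_index = residue, atom_kind = atom,
             stringsAsFactors = FALSE)
}

#' Calculated-observable matrix (one row per ensemble frame)
#'
#' Container for per-frame calculated observables, the `CS_ji` of the
#' reweighting model: `N` frames by `m` observables, in ppm for chemical
#' shifts. Columns are identified by unique tags which are the join key
#' against a [target_set()].
#'
#' @param values numeric matrix, frames in rows, observables in columns.
#' @param tags character vector of column tags (defaults to `colnames(values)`).
#' @param frame_ids integer frame identifiers, one per row.
#' @return object of class `observable_matrix` with fields `values`, `labels`
#'   (see [parse_observable_labels()]) and `frame_ids`.
#' @export
observable_matrix <- function(values, tags = colnames(values),
                              frame_ids = seq_len(nrow(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(tags)) stop_format("observable tags are required")
  tags <- as.character(tags)
  if (ncol(values) < 1L) stop_format("need at least one observable column")
  if (nrow(values) < 1L) stop_format("need at least one frame")
  if (length(tags) != ncol(values)) stop_format("tag count does not match columns")
  if (anyDuplicated(tags)) stop_format("duplicate observable tags: %s",
                                       paste(unique(tags[duplicated(tags)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop_format("observable values must be finite (missing values unsupported)")
  frame_ids <- as.integer(frame_ids)
  if (length(frame_ids) != nrow(values)) stop_format("frame id count does not match rows")
  colnames(values) <- tags
  structure(list(values = values, labels = parse_observable_labels(tags),
                 frame_ids = frame_ids),
            class = "observable_matrix")
}

#' @export
print.observable_matrix <- function(x, ...) {
  cat(sprintf("<observable_matrix> %d frames x %d observables\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.observable_matrix <- function(x) dim(x$values)

obs_tags <- function(x) x$labels$tag

#' Target (experimental) observable set
#'
#' Target values `CS_EXP_i` with their uncertainties `sigma_i` (ppm), keyed by
#' tag. Sigmas default, in the synthetic pipeline, to the forward-model errors
#' 1.06 (CA), 1.23 (CB), 1.32 (C) ppm.
#'
#' @param tags character tags, unique.
#' @param values numeric target values.
#' @param sigmas strictly positive uncertainties.
#' @return object of class `target_set` with fields `labels`, `values`, `sigmas`.
#' @export
target_set <- function(tags, values, sigmas) {
  tags <- as.character(tags)
  values <- as.numeric(values)
  sigmas <- as.numeric(sigmas)
  n <- length(tags)
  if (n < 1L) stop_format("target set is empty")
  if (length(values) != n || length(sigmas) != n)
    stop_format("tags, values and sigmas must have equal length")
  if (anyDuplicated(tags)) stop_format("duplicate target tags: %s",
                                       paste(unique(tags[duplicated(tags)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) stop_format("non-finite target value")
  if (anyNA(sigmas) || any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop_format("sigmas must be strictly positive")
  structure(list(labels = parse_observable_labels(tags), values = values,
                 sigmas = sigmas),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %d observables\n", length(x$values)))
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$values)

#' Normalized ensemble weight vector
#'
#' @param weights nonnegative numeric vector summing to 1 (within 1e-12 unless
#'   `normalize = TRUE`, in which case it is rescaled).
#' @param description free-text provenance.
#' @param normalize rescale to sum 1 instead of validating the sum.
#' @return object of class `weight_vector`.
#' @export
weight_vector <- function(weights, description = "", normalize = FALSE) {
  w <- as.numeric(weights)
  if (length(w) < 1L) stop_format("empty weight vector")
  if (anyNA(w) || any(!is.finite(w))) stop_format("non-finite weight")
  if (any(w < 0)) stop_format("weights must be nonnegative")
  s <- sum(w)
  if (normalize) {
    if (s <= 0) stop_format("weights sum to zero; cannot normalize")
    w <- w / s
  } else if (abs(s - 1) > 1e-12) {
    stop_format("weights must sum to 1 (got %.17g); use normalize = TRUE", s)
  }
  structure(list(weights = w, description = as.character(description)),
            class = "weight_vector")
}

#' Uniform prior weights over n frames
#' @param n number of frames.
#' @return a [weight_vector()] with all entries `1/n`.
#' @export
uniform_weights <- function(n) {
  weight_vector(rep(1 / n, n), description = sprintf("uniform prior over %d frames", n))
}

#' @export
length.weight_vector <- function(x) length(x$weights)

# Accept either a weight_vector or a bare numeric vector in computational code.
as_weights <- function(w, n = NULL) {
  if (inherits(w, "weight_vector")) w <- w$weights
  w <- as.numeric(w)
  if (!is.null(n) && length(w) != n)
    stop_format("weight length %d does not match %d frames", length(w), n)
  w
}

#' Per-frame secondary-structure code matrix
#'
#' Simplified three-letter alphabet: `H` (alpha helix), `E` (strand), `C`
#' (everything else). When converting real DSSP strings upstream, only DSSP
#' 'H' maps to `H` (alpha-helical content specifically), `E`/`B` map to `E`,
#' the rest to `C`.
#'
#' @param codes character matrix `[N frames x R residues]` over `{H,E,C}`.
#' @param frame_ids integer frame identifiers.
#' @return object of class `ss_matrix`.
#' @export
ss_matrix <- function(codes, frame_ids = seq_len(nrow(codes))) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 1L || ncol(codes) < 1L) stop_format("empty secondary-structure matrix")
  bad <- !(codes %in% c("H", "E", "C"))
  if (any(bad)) {
    off <- unique(codes[bad])
    stop_format("invalid secondary-structure code(s): %s", paste(off, collapse = ", "))
  }
  frame_ids <- as.integer(frame_ids)
  if (length(frame_ids) != nrow(codes)) stop_format("frame id count does not match rows")
  structure(list(codes = codes, frame_ids = frame_ids), class = "ss_matrix")
}

#' @export
dim.ss_matrix <- function(x) dim(x$codes)

#' @export
print.ss_matrix <- function(x, ...) {
  cat(sprintf("<ss_matrix> %d frames x %d residues\n", nrow(x$codes), ncol(x$codes)))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------
# TSV dialect: tab or any run of spaces on read; single tab on write; numbers
# written with 17 significant digits so write -> read -> write is the identity.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1L]]

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  readLines(path, warn = FALSE)
}

parse_numeric <- function(tok, path, lineno) {
  x <- suppressWarnings(as.numeric(tok))
  if (anyNA(x)) stop_format("%s line %d: non-numeric value '%s'",
                            path, lineno, tok[which(is.na(x))[1L]])
  x
}

#' Read a calculated-observable matrix from TSV
#'
#' Expected layout: a header line `frame <tag1> <tag2> ...`, then one line per
#' frame holding the frame id followed by `m` numeric values.
#'
#' @param path file path.
#' @return an [observable_matrix()].
#' @export
read_observable_matrix <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_format("%s: need a header and at least one frame row", path)
  header <- split_fields(lines[1L])
  if (tolower(header[1L]) != "frame")
    stop_format("%s line 1: first header column must be 'frame'", path)
  tags <- header[-1L]
  if (length(tags) < 1L) stop_format("%s: no observable columns", path)
  if (anyDuplicated(tags)) stop_format("%s: duplicate observable tags: %s", path,
                                       paste(unique(tags[duplicated(tags)]), collapse = ", "))
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, length(tags))
  ids <- integer(n)
  for (i in seq_len(n)) {
    tok <- split_fields(lines[i + 1L])
    if (length(tok) != length(tags) + 1L)
      stop_format("%s line %d: expected %d fields, found %d",
                  path, i + 1L, length(tags) + 1L, length(tok))
    row <- parse_numeric(tok, path, i + 1L)
    ids[i] <- as.integer(row[1L])
    vals[i, ] <- row[-1L]
  }
  observable_matrix(vals, tags = tags, frame_ids = ids)
}

#' Write a calculated-observable matrix to TSV
#' @param x an [observable_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observable_matrix <- function(x, path) {
  stopifnot(inherits(x, "observable_matrix"))
  header <- paste(c("frame", obs_tags(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(as.character(x$frame_ids[i]), fmt_num(x$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a target set from TSV
#'
#' Columns: tag, value, sigma. Lines starting with `#` are comments. The sigma
#' column is mandatory and must be strictly positive.
#'
#' @param path file path.
#' @return a [target_set()].
#' @export
read_target_set <- function(path) {
  lines <- read_lines_checked(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  linenos <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop_format("%s: empty target set", path)
  tags <- character(length(lines)); vals <- numeric(length(lines)); sig <- numeric(length(lines))
  for (i in seq_along(lines)) {
    tok <- split_fields(lines[i])
    if (length(tok) != 3L)
      stop_format("%s line %d: expected 3 fields (tag value sigma), found %d",
                  path, linenos[i], length(tok))
    tags[i] <- tok[1L]
    num <- parse_numeric(tok[2:3], path, linenos[i])
    vals[i] <- num[1L]; sig[i] <- num[2L]
  }
  target_set(tags, vals, sig)
}

#' Write a target set to TSV
#' @param x a [target_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_target_set <- function(x, path) {
  stopifnot(inherits(x, "target_set"))
  writeLines(paste(x$labels$tag, fmt_num(x$values), fmt_num(x$sigmas), sep = "\t"), path)
  invisible(path)
}

#' Read a secondary-structure matrix from TSV
#'
#' One line per frame: frame id, whitespace, a string over `{H,E,C}` of
#' constant length R.
#'
#' @param path file path.
#' @return an [ss_matrix()].
#' @export
read_ss_matrix <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop_format("%s: empty secondary-structure file", path)
  n <- length(lines)
  ids <- integer(n); strs <- character(n)
  for (i in seq_len(n)) {
    tok <- split_fields(lines[i])
    if (length(tok) != 2L)
      stop_format("%s line %d: expected 'frame_id SSSTRING'", path, i)
    ids[i] <- as.integer(parse_numeric(tok[1L], path, i))
    strs[i] <- tok[2L]
  }
  lens <- nchar(strs)
  if (length(unique(lens)) != 1L)
    stop_format("%s: inconsistent string lengths (line %d has %d, line 1 has %d)",
                path, which(lens != lens[1L])[1L], lens[lens != lens[1L]][1L], lens[1L])
  codes <- matrix(unlist(strsplit(strs, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  bad <- matrix(!(codes %in% c("H", "E", "C")), nrow = n)
  if (any(bad)) {
    pos <- which(bad, arr.ind = TRUE)[1L, ]
    stop_format("%s line %d: invalid code '%s' (alphabet is H, E, C)",
                path, pos[1L], codes[pos[1L], pos[2L]])
  }
  ss_matrix(codes, frame_ids = ids)
}

#' Write a secondary-structure matrix to TSV
#' @param x an [ss_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ss_matrix <- function(x, path) {
  stopifnot(inherits(x, "ss_matrix"))
  strs <- apply(x$codes, 1L, paste, collapse = "")
  writeLines(paste(x$frame_ids, strs, sep = "\t"), path)
  invisible(path)
}

#' Read / write frame weights
#'
#' Weights are stored as TSV `frame weight` with 17 significant digits so that
#' normalization survives a round trip.
#'
#' @param path file path.
#' @return `read_weights`: a [weight_vector()].
#' @export
read_weights <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) >= 1L && identical(tolower(split_fields(lines[1L])[1L]), "frame"))
    lines <- lines[-1L]
  if (length(lines) < 1L) stop_format("%s: empty weights file", path)
  w <- vapply(seq_along(lines), function(i) {
    tok <- split_fields(lines[i])
    if (length(tok) != 2L) stop_format("%s line %d: expected 'frame weight'", path, i)
    parse_numeric(tok[2L], path, i)
  }, numeric(1))
  weight_vector(w, description = sprintf("read from %s", path))
}

#' @rdname read_weights
#' @param x a [weight_vector()].
#' @export
write_weights <- function(x, path) {
  stopifnot(inherits(x, "weight_vector"))
  writeLines(c("frame\tweight",
               paste(seq_along(x$weights), fmt_num(x$weights), sep = "\t")), path)
  invisible(path)
}

# ---- alignment and averaging ------------------------------------------------

#' Restrict and reorder an observable matrix to a target set
#'
#' @param matrix an [observable_matrix()].
#' @param targets a [target_set()].
#' @return an [observable_matrix()] whose columns are exactly the target tags,
#'   in target order.
#' @export
align_by_tags <- function(matrix, targets) {
  stopifnot(inherits(matrix, "observable_matrix"), inherits(targets, "target_set"))
  want <- targets$labels$tag
  have <- obs_tags(matrix)
  missing <- setdiff(want, have)
  if (length(missing))
    stop_format("target tags missing from observable matrix: %s",
                paste(missing, collapse = ", "))
  idx <- match(want, have)
  observable_matrix(matrix$values[, idx, drop = FALSE], tags = want,
                    frame_ids = matrix$frame_ids)
}

#' Weighted ensemble averages of each observable
#'
#' The inner sum of the chi-squared statistic: per column,
#' `sum_j w_j CS_ji`.
#'
#' @param matrix an [observable_matrix()].
#' @param w a [weight_vector()] (or bare numeric weights) over frames.
#' @return named numeric vector of length m.
#' @export
weighted_observable_means <- function(matrix, w) {
  stopifnot(inherits(matrix, "observable_matrix"))
  w <- as_weights(w, n = nrow(matrix$values))
  out <- drop(crossprod(matrix$values, w))
  names(out) <- obs_tags(matrix)
  out
}
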