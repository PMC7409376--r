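# Semiglobal gene-order alignment over circular rotations and both
# orientations, and the score -> distance conversion
# D_AB = 1 - (G_AB + G_BA) / (G_AA + G_BB).

#' Alignment parameters
#'
#' Parameters of the gene-order alignment. End gaps are always free
#' (semiglobal alignment); internal gaps pay a linear per-position penalty.
#' When `gap_penalty` is `NULL` it defaults to half the median diagonal of the
#' substitution matrix in use, which keeps distances invariant under rescaling
#' of the hit scores.
#'
#' @param gap_penalty Nonnegative cost per internal gap position, or `NULL`
#'   for the matrix-relative default.
#' @param search_rotations Search all circular rotations of circular profiles?
#' @param search_antisense Also align against the reversed gene order?
#' @param extend_orfans Automatically extend the substitution matrix with
#'   `ORFAN:` singleton labels (see [build_substitution_matrix()])? If
#'   `FALSE`, labels absent from the matrix raise an error.
#' @return An object of class `goat_params`.
#' @export
alignment_params <- function(gap_penalty = NULL, search_rotations = TRUE,
                             search_antisense = TRUE, extend_orfans = TRUE) {
  if (!is.null(gap_penalty)) {
    stopifnot(is.numeric(gap_penalty), length(gap_penalty) == 1L,
              gap_penalty >= 0)
  }
  structure(list(gap_penalty = gap_penalty, free_end_gaps = TRUE,
                 search_rotations = isTRUE(search_rotations),
                 search_antisense = isTRUE(search_antisense),
                 extend_orfans = isTRUE(extend_orfans)),
            class = "goat_params")
}

.resolve_gap <- function(m, params) {
  if (!is.null(params$gap_penalty)) return(params$gap_penalty)
  0.5 * median(diag(m))
}

# Check profile labels against the matrix, extending with ORFANs if allowed.
.prepare_matrix <- function(m, profiles, params) {
  labs <- unique(unlist(lapply(profiles, `[[`, "families")))
  missing <- setdiff(labs, rownames(m))
  if (length(missing) > 0L) {
    non_orfan <- missing[!startsWith(missing, "ORFAN:")]
    if (length(non_orfan) > 0L || !params$extend_orfans)
      stop("label(s) missing from substitution matrix: ",
           paste(if (params$extend_orfans) non_orfan else missing,
                 collapse = ", "))
    m <- extend_matrix_orfans(m, labs)
  }
  m
}

.encode <- function(profile, labels) match(profile$families, labels)

.rotate <- function(v, off) {
  n <- length(v)
  if (off == 0L || n == 0L) return(v)
  v[((seq_len(n) - 1L + off) %% n) + 1L]
}

.transform <- function(v, off, antisense) {
  v <- .rotate(v, off)
  if (antisense) rev(v) else v
}

.alignment_result <- function(a, b, score, offset_a, offset_b, orientation,
                              pairs, gap_penalty) {
  colnames(pairs) <- c("pos_a", "pos_b")
  structure(list(genome_a = a$genome_id, genome_b = b$genome_id,
                 score = score, rotation_offset_a = offset_a,
                 rotation_offset_b = offset_b, orientation = orientation,
                 aligned_pairs = pairs, gap_penalty = gap_penalty),
            class = "goat_alignment")
}

#' @export
print.goat_alignment <- function(x, ...) {
  cat(sprintf("Gene-order alignment %s vs %s\n", x$genome_a, x$genome_b))
  cat(sprintf("  score %.4g | rotation offsets (a=%d, b=%d) | %s | %d pair(s)\n",
              x$score, x$rotation_offset_a, x$rotation_offset_b,
              x$orientation, nrow(x$aligned_pairs)))
  invisible(x)
}

#' Semiglobal gene-order alignment at a fixed rotation and orientation
#'
#' Aligns the two profiles as given (no rotation or reversal search): free
#' leading/trailing gaps on both sequences, internal gap positions costing
#' `gap_penalty` each, pairs scored by the substitution matrix. The traceback
#' is deterministic: diagonal moves are preferred, then gaps consuming `a`,
#' then gaps consuming `b`; among equal-scoring end cells the one with the
#' largest position in `a`, then `b`, is used.
#'
#' @param a,b `genome_profile` objects.
#' @param m Substitution matrix (see [build_substitution_matrix()]).
#' @param params [alignment_params()].
#' @return A `goat_alignment` with `score` and 1-based `aligned_pairs`.
#' @export
semiglobal_align <- function(a, b, m, params = alignment_params()) {
  m <- .prepare_matrix(m, list(a, b), params)
  gap <- .resolve_gap(m, params)
  ai <- .encode(a, rownames(m))
  bi <- .encode(b, rownames(m))
  res <- goat_dp_full(ai, bi, m, gap)
  .alignment_result(a, b, res$score, 0L, 0L, "sense", res$pairs, gap)
}

#' Optimal gene-order alignment over rotations and orientations
#'
#' The maximum semiglobal alignment score over all circular rotations of each
#' circular profile (when `search_rotations`) and over sense/antisense
#' orientation of `b` (when `search_antisense`). Rotating a linearization of
#' a circular genome carries no biological signal (assemblies are cut at
#' arbitrary positions), so both profiles' rotations are searched; this makes
#' the score exactly invariant to the linearization origin of either genome.
#' Ties are broken towards the smallest rotation offset of `a`, then of `b`,
#' then sense before antisense.
#'
#' @inheritParams semiglobal_align
#' @return A `goat_alignment`; `aligned_pairs` are positions in the rotated
#'   (and, for antisense, reversed) coordinates, recoverable through
#'   `rotation_offset_a`, `rotation_offset_b` and `orientation`.
#' @export
best_alignment <- function(a, b, m, params = alignment_params()) {
  m <- .prepare_matrix(m, list(a, b), params)
  gap <- .resolve_gap(m, params)
  labs <- rownames(m)
  ai <- .encode(a, labs)
  bi <- .encode(b, labs)
  rot_a <- params$search_rotations && a$circular
  rot_b <- params$search_rotations && b$circular
  hit <- goat_best_search(ai, bi, m, gap, rot_a, rot_b,
                          params$search_antisense)
  ta <- .rotate(ai, hit$offset_a)
  tb <- .transform(bi, hit$offset_b, hit$antisense)
  full <- goat_dp_full(ta, tb, m, gap)
  if (abs(full$score - hit$score) > 1e-8)
    stop("internal error: traceback score differs from search score")
  .alignment_result(a, b, hit$score, hit$offset_a, hit$offset_b,
                    if (hit$antisense) "antisense" else "sense",
                    full$pairs, gap)
}

#' Gene-order (GOAT) distance between two genomes
#'
#' Converts optimal alignment scores into a normalized distance
#' `D_AB = 1 - (G_AB + G_BA) / (G_AA + G_BB)`, where `G_XY` is the optimal
#' gene-order alignment score of X against Y and `G_XX` the self-alignment
#' score. Identical gene orders give 0; genomes sharing no alignable families
#' give 1. Values outside `[0, 1]` (possible only with exotic substitution
#' matrices whose cross-scores exceed self-scores) are clamped with a warning.
#'
#' @inheritParams semiglobal_align
#' @return A single numeric distance in `[0, 1]`.
#' @export
goat_distance <- function(a, b, m, params = alignment_params()) {
  m <- .prepare_matrix(m, list(a, b), params)
  gaa <- best_alignment(a, a, m, params)$score
  gbb <- best_alignment(b, b, m, params)$score
  if (gaa <= 0 || gbb <= 0)
    stop("degenerate profile: zero self-alignment score for ",
         if (gaa <= 0) a$genome_id else b$genome_id)
  gab <- best_alignment(a, b, m, params)$score
  gba <- best_alignment(b, a, m, params)$score
  d <- 1 - (gab + gba) / (gaa + gbb)
  if (d < 0 || d > 1) {
    warning(sprintf("distance %.4g outside [0, 1] clamped (%s vs %s)", d,
                    a$genome_id, b$genome_id))
    d <- min(max(d, 0), 1)
  }
  d
}

#' Pairwise gene-order distance matrix
#'
#' Applies [goat_distance()] to every pair of profiles.
#'
#' @param profiles List of `genome_profile` objects (length >= 2).
#' @inheritParams semiglobal_align
#' @param verbose Log each computed pair? Default `FALSE`.
#' @return Symmetric numeric matrix with zero diagonal and genome ids as
#'   dimnames.
#' @export
goat_distance_matrix <- function(profiles, m, params = alignment_params(),
                                 verbose = FALSE) {
  stopifnot(length(profiles) >= 2L)
  ids <- vapply(profiles, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) stop("duplicate genome ids in profiles")
  m <- .prepare_matrix(m, profiles, params)
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- tryCatch(
        goat_distance(profiles[[i]], profiles[[j]], m, params),
        error = function(e) stop("pair (", ids[i], ", ", ids[j], "): ",
                                 conditionMessage(e), call. = FALSE))
      d[i, j] <- d[j, i] <- dij
      if (verbose)
        message(sprintf("distance(%s, %s) = %.4f", ids[i], ids[j], dij))
    }
  }
  d
}

#' Exhaustive reference for the optimal alignment score
#'
#' Independent brute-force computation of [best_alignment()]'s score: it
#' enumerates every monotone set of aligned pairs (via index combinations,
#' not dynamic programming) for every rotation/orientation in the search
#' space, scoring matches by the substitution matrix and internal gaps by the
#' linear penalty. Feasible only for short profiles (lengths up to ~10);
#' intended for validation.
#'
#' @inheritParams semiglobal_align
#' @return The optimal score (single numeric).
#' @export
best_alignment_exhaustive <- function(a, b, m, params = alignment_params()) {
  m <- .prepare_matrix(m, list(a, b), params)
  gap <- .resolve_gap(m, params)
  labs <- rownames(m)
  ai <- .encode(a, labs)
  bi <- .encode(b, labs)
  offs_a <- if (params$search_rotations && a$circular)
    seq.int(0L, length(ai) - 1L) else 0L
  offs_b <- if (params$search_rotations && b$circular)
    seq.int(0L, length(bi) - 1L) else 0L
  orients <- if (params$search_antisense) c(FALSE, TRUE) else FALSE
  best <- 0
  for (ka in offs_a) {
    x <- .rotate(ai, ka)
    for (kb in offs_b) {
      for (anti in orients) {
        y <- .transform(bi, kb, anti)
        s <- .enum_monotone_best(x, y, m, gap)
        if (s > best) best <- s
      }
    }
  }
  best
}

# Best score over all monotone matchings of x and y: choose k increasing
# positions in each sequence, pair them in order; unmatched positions inside
# the matched span are internal gaps, the rest are free end gaps.
.enum_monotone_best <- function(x, y, m, gap) {
  n <- length(x)
  p <- length(y)
  best <- 0  # empty matching
  for (k in seq_len(min(n, p))) {
    ca <- combn(n, k)
    cb <- combn(p, k)
    s <- 0
    for (t in seq_len(k))
      s <- s + m[x[ca[t, ]], y[cb[t, ]], drop = FALSE]
    gap_a <- ca[k, ] - ca[1, ] + 1L - k
    gap_b <- cb[k, ] - cb[1, ] + 1L - k
    tot <- s - gap * outer(gap_a, gap_b, "+")
    mx <- max(tot)
    if (mx > best) best <- mx
  }
  best
}
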