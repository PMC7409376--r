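# Percent-scale genome similarity from tabular BLAST-style hits (Dice score
# from reciprocal translated hits, symmetrical identity from nucleotide hits)
# and similarity-threshold taxon demarcation.

#' Read 12-column tabular alignment hits
#'
#' Standard BLAST-style tabular output (`-outfmt 6`): `qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`, no
#' header.
#'
#' @param path File path.
#' @return Data frame with those column names.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 tab-separated columns in ", path)
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Filter alignment hits
#'
#' Keeps hits with identity >= `min_identity` percent, alignment length >=
#' `min_length` and E-value <= `max_evalue` (defaults: 30 / 30 / 0.01, the
#' standard filters for reciprocal tBLASTx genome comparison). Input order is
#' preserved; the number of removed hits is reported via a message.
#'
#' @param hits Data frame with columns `pident`, `length`, `evalue` (e.g.
#'   from [read_blast_tab()]).
#' @param min_identity,min_length,max_evalue Thresholds as above.
#' @return The passing subset of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 30, min_length = 30,
                        max_evalue = 0.01) {
  keep <- hits$pident >= min_identity & hits$length >= min_length &
    hits$evalue <= max_evalue
  removed <- sum(!keep)
  if (removed > 0L) message(removed, " hit(s) removed by filters")
  hits[keep, , drop = FALSE]
}

# Identity-weighted covered length: each genome position covered by at least
# one hit interval contributes its maximum fractional identity. Intervals are
# normalized to ascending order (minus-strand hits have start > end).
weighted_coverage <- function(starts, ends, pident) {
  if (length(starts) == 0L) return(0)
  lo <- pmin(starts, ends)
  hi <- pmax(starts, ends)
  w <- pident / 100
  # atomic segments between sorted breakpoints; [lo, hi] inclusive integer
  # coordinates mapped to half-open [lo, hi + 1)
  bp <- sort(unique(c(lo, hi + 1L)))
  if (length(bp) < 2L) return(0)
  seg_lo <- bp[-length(bp)]
  seg_len <- diff(bp)
  cov <- numeric(length(seg_lo))
  for (i in seq_along(lo)) {
    inside <- seg_lo >= lo[i] & seg_lo < hi[i] + 1L
    cov[inside] <- pmax(cov[inside], w[i])
  }
  sum(cov * seg_len)
}

#' Dice similarity score between two genomes
#'
#' Aggregates filtered reciprocal translated hits into a percent-scale
#' similarity: `100 * (C_AB + C_BA) / (len_a + len_b)`, where `C_XY` is the
#' identity-weighted length of X covered by merged hits of X against Y
#' (query coordinates). Apply [filter_hits()] first.
#'
#' @param hits_ab Hits of genome A queried against B (query coordinates on A).
#' @param hits_ba Hits of B against A.
#' @param len_a,len_b Genome lengths in bp (> 0).
#' @return Similarity in `[0, 100]`.
#' @export
dice_score <- function(hits_ab, hits_ba, len_a, len_b) {
  if (len_a <= 0 || len_b <= 0) stop("genome lengths must be positive")
  cab <- weighted_coverage(hits_ab$qstart, hits_ab$qend, hits_ab$pident)
  cba <- weighted_coverage(hits_ba$qstart, hits_ba$qend, hits_ba$pident)
  100 * (cab + cba) / (len_a + len_b)
}

#' Symmetrical identity (SI) between two genomes
#'
#' The arithmetic mean of the two directional identity-weighted coverage
#' fractions: `SI = 100 * (C_AB/len_a + C_BA/len_b) / 2`.
#'
#' @inheritParams dice_score
#' @return Similarity in `[0, 100]`.
#' @export
symmetrical_identity <- function(hits_ab, hits_ba, len_a, len_b) {
  if (len_a <= 0 || len_b <= 0) stop("genome lengths must be positive")
  cab <- weighted_coverage(hits_ab$qstart, hits_ab$qend, hits_ab$pident)
  cba <- weighted_coverage(hits_ba$qstart, hits_ba$qend, hits_ba$pident)
  100 * (cab / len_a + cba / len_b) / 2
}

#' Pairwise genome similarity matrix from a hit table
#'
#' Splits a combined hit table by (query genome, subject genome), applies the
#' hit filters and aggregates each ordered pair with [dice_score()] or
#' [symmetrical_identity()]. The diagonal is set to 100.
#'
#' @param hits Data frame of hits between genomes (`qseqid`/`sseqid` name
#'   genomes).
#' @param lengths Named vector of genome lengths in bp.
#' @param kind `"dice"` or `"si"`.
#' @param ... Passed to [filter_hits()].
#' @return Symmetric percent-scale matrix with diagonal 100.
#' @export
similarity_matrix <- function(hits, lengths, kind = c("dice", "si"), ...) {
  kind <- match.arg(kind)
  ids <- sort(names(lengths))
  stopifnot(length(ids) >= 2L)
  hits <- filter_hits(hits, ...)
  fun <- if (kind == "dice") dice_score else symmetrical_identity
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq.int(i + 1L, length(ids))) {
      ab <- hits[hits$qseqid == ids[i] & hits$sseqid == ids[j], , drop = FALSE]
      ba <- hits[hits$qseqid == ids[j] & hits$sseqid == ids[i], , drop = FALSE]
      m[i, j] <- m[j, i] <- fun(ab, ba, lengths[[ids[i]]], lengths[[ids[j]]])
    }
  }
  m
}

#' Demarcate taxa at a similarity threshold
#'
#' Single-linkage clustering of genomes: two genomes are linked when their
#' similarity is strictly greater than `threshold`, and clusters are the
#' connected components of the resulting graph (the only linkage under which
#' ">X% similarity" edges are transitive). Conventional percent thresholds
#' for phage genomes: 95 (species, nucleotide identity), 50 (genus, SI),
#' 25 (subfamily, translated SI).
#'
#' @param m Symmetric similarity matrix (percent scale, diagonal 100).
#' @param threshold Percent similarity cutoff; edges require `> threshold`.
#' @return Named character vector mapping each genome id to its cluster
#'   label, the lexicographically smallest member id of the cluster.
#' @export
demarcate <- function(m, threshold) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            !is.null(rownames(m)))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("similarity matrix must be symmetric")
  adj <- (m > threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- rownames(m)
  labels <- vapply(split(ids, comp), min, character(1))
  out <- labels[as.character(comp)]
  names(out) <- ids
  out
}
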