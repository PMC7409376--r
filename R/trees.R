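# Distance matrix -> BioNJ tree, outgroup rooting, Robinson-Foulds topology
# comparison, Newick and PHYLIP I/O. Trees are ape "phylo" objects.

#' BioNJ tree from a distance matrix
#'
#' Runs the BioNJ agglomeration (variance-weighted neighbor joining) on a
#' symmetric distance matrix. Negative estimated branch lengths are set to
#' zero with the difference transferred to the sister branch, so path lengths
#' between leaves are preserved as far as possible.
#'
#' @param d Symmetric numeric matrix (zero diagonal) or `dist` object,
#'   n >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
bionj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("BioNJ needs at least 3 taxa")
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix contains NA/NaN")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  tree <- ape::bionj(d)
  tree$tip.label <- unname(tree$tip.label)
  .fix_negative_branches(tree)
}

# Zero out negative branch lengths, adding the (negative) difference to the
# sister branch at the same node; repeated until stable, then clamped.
.fix_negative_branches <- function(tree) {
  if (is.null(tree$edge.length)) return(tree)
  for (pass in seq_len(nrow(tree$edge))) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sisters) > 0L) {
      s <- sisters[1L]
      tree$edge.length[s] <- tree$edge.length[s] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Root a tree at an outgroup leaf
#'
#' Places the root at the midpoint of the outgroup's pendant edge; the
#' topology is otherwise unchanged.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Tip label to root at.
#' @return A rooted `phylo` tree with the outgroup as a child of the root.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  tip <- match(outgroup, tree$tip.label)
  if (is.na(tip)) stop("outgroup leaf not found in tree: ", outgroup)
  edge <- which(tree$edge[, 2L] == tip)
  len <- if (is.null(tree$edge.length)) 0 else tree$edge.length[edge]
  phytools::reroot(tree, tip, position = len / 2)
}

# Canonical non-trivial bipartitions of an (un)rooted tree: each internal
# edge splits the leaves in two; the side not containing the reference leaf
# (first of the sorted leaf universe) is serialized as a sorted string.
.bipartitions <- function(tree, universe) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(universe)
  out <- character(0)
  for (p in pp) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (universe[1L] %in% side) side <- setdiff(universe, side)
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial bipartitions (internal edges) present in exactly
#' one of the two trees. The normalized form divides by the total number of
#' non-trivial bipartitions across both trees — the fraction of data
#' partitions present in only one tree — which handles multifurcating trees
#' and lies in `[0, 1]` (two star trees compare as 0).
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @param normalized Return the normalized fraction (default) or the raw
#'   count?
#' @return A single number.
#' @export
robinson_foulds <- function(t1, t2, normalized = TRUE) {
  l1 <- unname(sort(t1$tip.label))
  l2 <- unname(sort(t2$tip.label))
  if (!identical(l1, l2))
    stop("trees have different leaf sets; only in first: ",
         paste(setdiff(l1, l2), collapse = ", "), "; only in second: ",
         paste(setdiff(l2, l1), collapse = ", "))
  b1 <- .bipartitions(t1, l1)
  b2 <- .bipartitions(t2, l1)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (!normalized) return(rf)
  denom <- length(b1) + length(b2)
  if (denom == 0L) 0 else rf / denom
}

#' Read / write Newick trees
#'
#' Thin wrappers around ape's Newick parser that additionally reject
#' duplicate tip labels and preserve quoted labels containing spaces, with
#' round-trip stability of topology, labels and branch lengths.
#'
#' @param path File path.
#' @return `read_newick` returns a `phylo`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in ", path)
  tree$tip.label <- .unquote_label(tree$tip.label)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L)
    stop("duplicate tip label(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  tree
}

# ape keeps surrounding single quotes as part of the label; strip them and
# undo doubled-quote escaping
.unquote_label <- function(x) {
  quoted <- startsWith(x, "'") & endsWith(x, "'") & nchar(x) >= 2L
  x[quoted] <- gsub("''", "'", substr(x[quoted], 2L, nchar(x[quoted]) - 1L))
  x
}

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  labs <- tree$tip.label
  need <- grepl("[][ '():;,]", labs)
  if (any(need)) {
    # ape would replace spaces by underscores; route such labels through
    # placeholders and splice the quoted originals into the Newick string
    tokens <- sprintf("xQLBLx%dx", seq_along(labs))[need]
    tree$tip.label[need] <- tokens
    txt <- ape::write.tree(tree, digits = 12)
    quoted <- paste0("'", gsub("'", "''", labs[need]), "'")
    for (i in seq_along(tokens))
      txt <- sub(tokens[i], quoted[i], txt, fixed = TRUE)
    writeLines(txt, path)
  } else {
    ape::write.tree(tree, file = path, digits = 12)
  }
  invisible(path)
}

#' Write / read a lower-triangle PHYLIP distance matrix
#'
#' The classic PHYLIP format: first line the number of taxa, then one row per
#' taxon with its label followed by the distances to all previous taxa.
#'
#' @param d Symmetric matrix with dimnames.
#' @param path File path.
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  n <- nrow(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    vals <- if (i > 1L) paste(sprintf("%.9f", d[i, seq_len(i - 1L)]),
                              collapse = "  ") else ""
    writeLines(trimws(sprintf("%-10s  %s", rownames(d)[i], vals),
                      which = "right"), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @return `read_phylip_dist` returns the full symmetric matrix.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || n < 2L) stop("invalid PHYLIP distance file: ", path)
  toks <- unlist(strsplit(trimws(lines[-1L]), "[[:space:]]+"))
  d <- matrix(0, n, n)
  labels <- character(n)
  pos <- 1L
  for (i in seq_len(n)) {
    labels[i] <- toks[pos]
    pos <- pos + 1L
    if (i > 1L) {
      vals <- as.numeric(toks[seq.int(pos, pos + i - 2L)])
      d[i, seq_len(i - 1L)] <- vals
      d[seq_len(i - 1L), i] <- vals
      pos <- pos + i - 1L
    }
  }
  dimnames(d) <- list(labels, labels)
  d
}
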