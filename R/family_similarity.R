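# Family-vs-family substitution matrix from reciprocal profile-profile
# (HHsearch-style) hit scores.

#' Read profile-profile hit scores
#'
#' Parses a tabular file of directed family-vs-family similarity scores
#' (e.g. HHsearch output reduced to query, target, score). Duplicate
#' (query, target) rows keep the maximum score; rows with negative scores are
#' rejected with a warning.
#'
#' @param path Tabular file.
#' @param columns Length-3 vector (names `query`, `target`, `score`) giving
#'   the column indices or names holding the three fields.
#' @param header Does the file have a header line? Default `TRUE`.
#' @return Data frame with columns `query`, `target`, `score`.
#' @export
read_profile_hits <- function(path,
                              columns = c(query = 1, target = 2, score = 3),
                              header = TRUE) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  if (file.size(path) == 0L ||
      (header && length(readLines(path, n = 2L)) < 2L)) {
    warning("empty hit file: ", path)
    return(data.frame(query = character(0), target = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  raw <- read.delim(path, header = header, stringsAsFactors = FALSE)
  pick <- function(key) {
    col <- columns[[key]]
    if (is.character(col)) raw[[col]] else raw[[as.integer(col)]]
  }
  df <- data.frame(query = as.character(pick("query")),
                   target = as.character(pick("target")),
                   score = as.numeric(pick("score")),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$score) | df$score < 0
  if (any(bad)) {
    warning(sum(bad), " hit row(s) with negative/invalid score rejected")
    df <- df[!bad, , drop = FALSE]
  }
  # duplicates keep the maximum score
  o <- order(df$query, df$target, -df$score)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[, c("query", "target")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the family substitution matrix
#'
#' Symmetrizes directed hit scores into substitution scores for the gene-order
#' alignment: `scores[i, j] = (hit(i -> j) + hit(j -> i)) / 2`, a missing
#' direction counting as 0. Pairs with no hits score 0. A label with no
#' self-hit gets its diagonal set to the maximum of its row (with a warning),
#' or to 1 if the whole row is zero, so that self-alignments are always
#' positive.
#'
#' @param hits Data frame from [read_profile_hits()] (columns `query`,
#'   `target`, `score`).
#' @param labels Character vector of family labels for the matrix; defaults to
#'   all labels occurring in `hits`.
#' @return Symmetric numeric matrix with `labels` as dimnames.
#' @export
build_substitution_matrix <- function(hits, labels = NULL) {
  if (is.null(labels))
    labels <- sort(unique(c(hits$query, hits$target)))
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("no labels for substitution matrix")
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  keep <- hits$query %in% labels & hits$target %in% labels
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) > 0L) {
    d <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    d[cbind(h$query, h$target)] <- h$score
    m <- (d + t(d)) / 2
  }
  noself <- diag(m) <= 0
  if (any(noself)) {
    if (nrow(h) > 0L)
      warning(sum(noself), " label(s) without self-hit; diagonal set to row ",
              "maximum (or 1 for empty rows)")
    for (i in which(noself)) {
      rmax <- max(m[i, ])
      diag(m)[i] <- if (rmax > 0) rmax else 1
    }
  }
  m
}

# Extend a substitution matrix with ORFAN singleton labels: diagonal = median
# diagonal of the real families (1 if there are none), off-diagonal = 0, so
# unassigned genes match only themselves without dominating the scores.
extend_matrix_orfans <- function(m, labels) {
  new <- setdiff(labels, rownames(m))
  if (length(new) == 0L) return(m)
  orfan <- startsWith(new, "ORFAN:")
  if (!all(orfan))
    stop("label(s) missing from substitution matrix: ",
         paste(new[!orfan], collapse = ", "))
  real <- !startsWith(rownames(m), "ORFAN:")
  selfscore <- if (any(real)) median(diag(m)[real]) else 1
  k <- length(new)
  out <- rbind(cbind(m, matrix(0, nrow(m), k)),
               cbind(matrix(0, k, ncol(m)), diag(selfscore, k)))
  dimnames(out) <- list(c(rownames(m), new), c(rownames(m), new))
  out
}

#' Write / read a labeled square similarity matrix as TSV
#'
#' @param m Symmetric numeric matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv` returns the matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("matrix in ", path, " is not symmetric")
  m
}
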