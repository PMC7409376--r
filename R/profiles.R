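# Gene-order profiles: from annotations + orthologous-group assignments to
# the ordered (circular) sequence of family labels per genome.

#' Construct a gene-order profile
#'
#' A gene-order profile is the ordered sequence of gene-family labels of one
#' genome, listed in ascending coordinate order. For circular genomes the
#' sequence is a linearization at an arbitrary origin; downstream alignment
#' searches all rotations, so the choice of origin carries no information.
#'
#' @param genome_id Genome identifier (single string).
#' @param families Character vector of family labels in chromosomal order
#'   (length >= 1).
#' @param strands Optional character vector of `"+"`/`"-"` of the same length.
#' @param circular Logical; is the genome circular? Default `TRUE` (phage
#'   genomes are circular or circularly permuted).
#' @return An object of class `genome_profile`.
#' @export
genome_profile <- function(genome_id, families, strands = NULL,
                           circular = TRUE) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  families <- as.character(families)
  if (length(families) < 1L) stop("profile must contain at least one gene")
  if (!is.null(strands)) {
    strands <- as.character(strands)
    if (length(strands) != length(families))
      stop("strands must have the same length as families")
    if (!all(strands %in% c("+", "-")))
      stop("strands must be '+' or '-'")
  }
  structure(list(genome_id = genome_id, families = families,
                 strands = strands, circular = isTRUE(circular)),
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("Gene-order profile '%s': %d genes (%s)\n", x$genome_id,
              length(x$families), if (x$circular) "circular" else "linear"))
  shown <- x$families
  if (length(shown) > 12L) shown <- c(shown[1:12], "...")
  cat(" ", paste(shown, collapse = " - "), "\n")
  invisible(x)
}

#' @export
length.genome_profile <- function(x) length(x$families)

#' Read gene annotations
#'
#' Reads coding-gene coordinates either from GFF3 (CDS features) or from a
#' plain TSV with header `genome_id,gene_id,start,end,strand`. Coordinates are
#' 1-based inclusive in both dialects. Records with `end < start` or
#' `start < 1` are dropped with a warning (genes spanning a circular origin
#' are expected to be supplied already placed by their start coordinate).
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return A data frame with columns `genome_id`, `gene_id`, `start`, `end`,
#'   `strand`, sorted by genome, then start, end, gene id.
#' @export
read_annotations <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0L) stop("annotation file is empty: ", path)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "gene_id", "start", "end", "strand")
    if (!all(need %in% names(df)))
      stop("TSV annotations need header columns: ", paste(need, collapse = ","))
    df <- df[, need]
  } else {
    g <- as.data.frame(rtracklayer::readGFF(path))
    g <- g[g$type == "CDS", , drop = FALSE]
    if (nrow(g) == 0L) stop("no CDS features in GFF3 file: ", path)
    ids <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
    miss <- is.na(ids) | ids == ""
    ids[miss] <- sprintf("cds%06d", which(miss))
    df <- data.frame(genome_id = as.character(g$seqid), gene_id = ids,
                     start = as.integer(g$start), end = as.integer(g$end),
                     strand = as.character(g$strand),
                     stringsAsFactors = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- is.na(df$start) | is.na(df$end) | df$start < 1L | df$end < df$start
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed coordinates dropped")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid gene records in ", path)
  dup <- duplicated(df[, c("genome_id", "gene_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (genome_id, gene_id) record(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$genome_id, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assign genes to gene families
#'
#' Resolves a table of HMM-search style hits to a single family per gene: the
#' hit with the smallest E-value strictly below `evalue_max` wins; ties are
#' broken by larger score, then lexicographic family id. Genes without a
#' passing hit receive a unique singleton label
#' `ORFAN:<genome_id>:<gene_id>`, so unassigned genes can only ever align to
#' themselves.
#'
#' @param genes Gene records as returned by [read_annotations()].
#' @param hits Data frame with columns `gene_id`, `family_id`, `score`,
#'   `evalue`.
#' @param evalue_max E-value cutoff; hits with `evalue < evalue_max` pass
#'   (default `1e-2`).
#' @return Named character vector mapping `gene_id` to family label, in the
#'   order of `genes`.
#' @export
assign_families <- function(genes, hits, evalue_max = 1e-2) {
  stopifnot(evalue_max > 0)
  need <- c("gene_id", "family_id", "score", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits need columns: ", paste(need, collapse = ","))
  unknown <- !(hits$gene_id %in% genes$gene_id)
  if (any(unknown)) {
    warning(sum(unknown), " hit(s) referencing unknown gene_id ignored")
    hits <- hits[!unknown, , drop = FALSE]
  }
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  out <- paste0("ORFAN:", genes$genome_id, ":", genes$gene_id)
  names(out) <- genes$gene_id
  if (nrow(hits) > 0L) {
    o <- order(hits$gene_id, hits$evalue, -hits$score, hits$family_id)
    hits <- hits[o, , drop = FALSE]
    first <- hits[!duplicated(hits$gene_id), , drop = FALSE]
    out[first$gene_id] <- first$family_id
  }
  out
}

#' Read gene-to-family hit tables
#'
#' Reads the 4-column TSV `gene_id, family_id, score, evalue` consumed by
#' [assign_families()]. HMM-search style tabular outputs with different
#' column layouts can be read by remapping `columns` to the right names or
#' positions.
#'
#' @param path Tabular file.
#' @param columns Length-4 vector (names `gene_id`, `family_id`, `score`,
#'   `evalue`) of column names or indices.
#' @param header Does the file have a header line? Default `TRUE`.
#' @return Data frame with the four canonical columns.
#' @export
read_family_hits <- function(path,
                             columns = c(gene_id = "gene_id",
                                         family_id = "family_id",
                                         score = "score", evalue = "evalue"),
                             header = TRUE) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  raw <- read.delim(path, header = header, stringsAsFactors = FALSE)
  pick <- function(key) {
    col <- columns[[key]]
    if (is.character(col)) raw[[col]] else raw[[as.integer(col)]]
  }
  data.frame(gene_id = as.character(pick("gene_id")),
             family_id = as.character(pick("family_id")),
             score = as.numeric(pick("score")),
             evalue = as.numeric(pick("evalue")),
             stringsAsFactors = FALSE)
}

#' Build a genome's gene-order profile
#'
#' Orders the genes of one genome by start coordinate (ties by end, then gene
#' id) and threads the assigned family labels into a [genome_profile()].
#'
#' @param genome_id Which genome to build.
#' @param genes Gene records (may contain several genomes).
#' @param assignment Named vector from [assign_families()].
#' @param circular Circular genome flag, default `TRUE`.
#' @param include_orfans Keep genes with singleton `ORFAN:` labels in the
#'   profile (default `TRUE`)? With `FALSE` only genes assigned to a shared
#'   family enter the gene order.
#' @return A `genome_profile`.
#' @export
build_profile <- function(genome_id, genes, assignment, circular = TRUE,
                          include_orfans = TRUE) {
  g <- genes[genes$genome_id == genome_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("no genes for genome ", genome_id)
  g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
  fam <- unname(assignment[g$gene_id])
  if (anyNA(fam)) stop("assignment is missing gene(s): ",
                       paste(g$gene_id[is.na(fam)], collapse = ", "))
  keep <- rep(TRUE, length(fam))
  if (!include_orfans) keep <- !startsWith(fam, "ORFAN:")
  if (!any(keep)) stop("no assigned genes left for genome ", genome_id)
  genome_profile(genome_id, fam[keep], strands = g$strand[keep],
                 circular = circular)
}

#' Core gene families shared by all genomes
#'
#' The exact intersection of the per-genome family sets; singleton `ORFAN:`
#' labels never count. Adding a genome can only shrink the result.
#'
#' @param profiles List of `genome_profile` objects (length >= 1).
#' @return Sorted character vector of family labels present in every genome.
#' @export
core_families <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  sets <- lapply(profiles, function(p) {
    f <- unique(p$families)
    f[!startsWith(f, "ORFAN:")]
  })
  sort(Reduce(intersect, sets))
}

#' Write / read gene-order profiles as TSV
#'
#' Serialization with columns `genome_id`, `position`, `family_id`, `strand`
#' (`strand` is `NA` when unknown). All profiles in one file.
#'
#' @param profiles List of `genome_profile` objects.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(genome_id = p$genome_id, position = seq_along(p$families),
               family_id = p$families,
               strand = if (is.null(p$strands)) NA_character_ else p$strands,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @param circular Circular flag applied to every profile read.
#' @return `read_profiles` returns a named list of `genome_profile` objects.
#' @export
read_profiles <- function(path, circular = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "position", "family_id")
  if (!all(need %in% names(df)))
    stop("profile TSV needs columns: ", paste(need, collapse = ","))
  out <- lapply(split(df, df$genome_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    strands <- if ("strand" %in% names(d) && !anyNA(d$strand)) d$strand else NULL
    genome_profile(d$genome_id[1L], d$family_id, strands = strands,
                   circular = circular)
  })
  out[order(names(out))]
}
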