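# Seedable simulator of gene-order evolution: profiles evolved along a known
# tree by inversion, transposition, gene loss/gain and rotation, plus
# synthetic family-similarity matrices and planted BLAST-style hit tables.
# Ground truth is known by construction, so every other module can be
# validated end to end without external data.

#' Configuration for the gene-order evolution simulator
#'
#' Rates are expected event counts per unit of branch length; the number of
#' events on a branch is Poisson(total rate x branch length). The defaults
#' model a large-phage scenario: circular genomes of 30 family-assigned genes
#' drawn from a pool of 500 families, with indels (gain/loss) somewhat more
#' frequent than rearrangements and occasional assembly-origin rotations
#' (which gene-order distances ignore by design).
#'
#' @param n_families Size of the family label pool.
#' @param genome_length Number of genes per genome (>= 2).
#' @param inversion,transposition,gene_loss,gene_gain,rotation Event rates
#'   per branch unit (>= 0).
#' @param inversion_span Integer range (length 2) of arc lengths for
#'   inversions and transpositions.
#' @param seed Optional integer seed applied by the top-level generators.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(n_families = 500, genome_length = 30,
                             inversion = 0.1, transposition = 0.1,
                             gene_loss = 0.15, gene_gain = 0.15,
                             rotation = 0.1, inversion_span = c(2L, 8L),
                             seed = NULL) {
  rates <- c(inversion = inversion, transposition = transposition,
             gene_loss = gene_loss, gene_gain = gene_gain,
             rotation = rotation)
  stopifnot(all(rates >= 0), genome_length >= 2, n_families >= 1,
            length(inversion_span) == 2L,
            inversion_span[1] >= 2, inversion_span[2] >= inversion_span[1])
  if (genome_length > n_families)
    stop("genome_length may not exceed n_families (profiles are drawn ",
         "without replacement)")
  structure(list(n_families = n_families, genome_length = genome_length,
                 rates = rates, inversion_span = as.integer(inversion_span),
                 seed = seed),
            class = "evolution_config")
}

.family_pool <- function(config) sprintf("F%04d", seq_len(config$n_families))

#' Random ancestral gene-order profile
#'
#' Draws `genome_length` distinct family labels from the pool, as a circular
#' profile.
#'
#' @param config An [evolution_config()]; its `seed` (if set) is applied
#'   before drawing.
#' @param genome_id Identifier for the profile.
#' @return A `genome_profile`.
#' @export
random_profile <- function(config, genome_id = "ancestor") {
  if (!is.null(config$seed)) set.seed(config$seed)
  fams <- sample(.family_pool(config), config$genome_length)
  genome_profile(genome_id, fams, circular = TRUE)
}

# Deterministically apply one fully parameterized event to a label vector.
.apply_one <- function(fams, ev) {
  n <- length(fams)
  switch(ev$type,
    inversion = {
      idx <- seq.int(ev$pos, ev$pos + ev$span - 1L)
      fams[idx] <- rev(fams[idx])
      fams
    },
    transposition = {
      idx <- seq.int(ev$pos, ev$pos + ev$span - 1L)
      arc <- fams[idx]
      rest <- fams[-idx]
      append(rest, arc, after = ev$insert_after)
    },
    gene_loss = fams[-ev$pos],
    gene_gain = append(fams, ev$label, after = ev$insert_after),
    rotation = {
      if (ev$offset == 0L) fams
      else fams[((seq_len(n) - 1L + ev$offset) %% n) + 1L]
    },
    stop("unknown event type: ", ev$type))
}

# Sample one event applicable to the current genome; events that would empty
# the genome are resampled.
.sample_event <- function(fams, config) {
  rates <- config$rates
  for (try in 1:100) {
    type <- sample(names(rates), 1L, prob = rates)
    n <- length(fams)
    if (type == "gene_loss" && n <= 1L) next
    if (type %in% c("inversion", "transposition")) {
      lo <- min(config$inversion_span[1L], n)
      hi <- min(config$inversion_span[2L], n)
      span <- if (hi > lo) sample(seq.int(lo, hi), 1L) else lo
      if (span >= n && type == "transposition") next
      pos <- sample(n - span + 1L, 1L)
      if (type == "inversion")
        return(list(type = type, pos = pos, span = span))
      insert_after <- sample(seq.int(0L, n - span), 1L)
      return(list(type = type, pos = pos, span = span,
                  insert_after = insert_after))
    }
    if (type == "gene_loss") return(list(type = type, pos = sample(n, 1L)))
    if (type == "gene_gain")
      return(list(type = type,
                  label = sprintf("NOVEL:%09d", sample.int(999999999L, 1L)),
                  insert_after = sample(seq.int(0L, n), 1L)))
    if (type == "rotation")
      return(list(type = type, offset = sample(seq.int(0L, n - 1L), 1L)))
  }
  stop("could not sample an applicable event (all rates degenerate?)")
}

#' Apply random evolutionary events to a profile
#'
#' Samples `n_events` events according to the relative rates in `config` and
#' applies them sequentially. Each event is recorded with all of its sampled
#' parameters, so [replay_events()] reproduces the mutated profile exactly.
#' Gained genes receive fresh `NOVEL:` labels never drawn from the standing
#' pool, keeping homoplasy out of the simulation.
#'
#' @param profile A `genome_profile`.
#' @param config An [evolution_config()].
#' @param n_events Number of events (>= 0).
#' @return List with elements `profile` (mutated) and `log` (list of events).
#' @export
apply_events <- function(profile, config, n_events) {
  stopifnot(n_events >= 0)
  fams <- profile$families
  log <- vector("list", n_events)
  for (k in seq_len(n_events)) {
    ev <- .sample_event(fams, config)
    fams <- .apply_one(fams, ev)
    log[[k]] <- ev
  }
  list(profile = genome_profile(profile$genome_id, fams,
                                circular = profile$circular),
       log = log)
}

#' Replay a recorded event log
#'
#' @param profile The starting `genome_profile`.
#' @param log Event log from [apply_events()].
#' @return The mutated `genome_profile`.
#' @export
replay_events <- function(profile, log) {
  fams <- profile$families
  for (ev in log) fams <- .apply_one(fams, ev)
  genome_profile(profile$genome_id, fams, circular = profile$circular)
}

#' Evolve gene-order profiles along a tree
#'
#' Draws a random ancestral profile at the root and evolves it along every
#' branch, with the number of events on a branch Poisson-distributed with
#' mean (total event rate) x (branch length). Returns the leaf profiles
#' together with the generating tree, so recovered topologies can be scored
#' against the truth.
#'
#' @param tree A `phylo` tree with nonnegative branch lengths.
#' @param config An [evolution_config()]; its `seed` (if set) is applied once
#'   at entry (a single RNG stream drives the whole simulation).
#' @return List with `profiles` (named list of `genome_profile` at the
#'   leaves), `tree` (the input tree), and `logs` (per-edge event logs).
#' @export
evolve_along_tree <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0))
  if (!is.null(config$seed)) set.seed(config$seed)
  total_rate <- sum(config$rates)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  fams0 <- sample(.family_pool(config), config$genome_length)
  node_profiles <- vector("list", ntip + tree$Nnode)
  node_profiles[[root]] <- fams0
  logs <- vector("list", nrow(tree$edge))
  # edges in preorder so the parent profile always exists
  ord <- order(tree$edge[, 1L])
  for (e in ord) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    p <- genome_profile("tmp", node_profiles[[parent]], circular = TRUE)
    nev <- rpois(1L, total_rate * tree$edge.length[e])
    res <- apply_events(p, config, nev)
    node_profiles[[child]] <- res$profile$families
    logs[[e]] <- res$log
  }
  profiles <- lapply(seq_len(ntip), function(i)
    genome_profile(tree$tip.label[i], node_profiles[[i]], circular = TRUE))
  names(profiles) <- tree$tip.label
  list(profiles = profiles, tree = tree, logs = logs)
}

#' Synthetic family-similarity matrix
#'
#' Identity-like substitution matrix over the given labels: diagonal 1,
#' off-diagonal values drawn uniformly from `[0, noise]` (symmetric). With
#' `noise = 0` the matrix is exactly the identity.
#'
#' @param labels Family labels.
#' @param noise Upper bound of off-diagonal similarity, in `[0, 1)`.
#' @param seed Optional seed.
#' @return Symmetric numeric matrix.
#' @export
synth_similarity_matrix <- function(labels, noise = 0, seed = NULL) {
  stopifnot(noise >= 0, noise < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  if (noise > 0 && n > 1L) {
    up <- upper.tri(m)
    m[up] <- runif(sum(up), 0, noise)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  m
}

#' Plant reciprocal alignment hits with known coverage
#'
#' Builds a 12-column BLAST-style hit table for a genome pair in which each
#' direction covers a chosen fraction of the query genome at a chosen percent
#' identity, so the resulting Dice / symmetrical-identity scores are known by
#' construction (e.g. coverage 0.2 at 100% identity in both directions gives
#' a Dice score of exactly 20 for equal genome lengths).
#'
#' @param genome_a,genome_b Genome identifiers.
#' @param len_a,len_b Genome lengths in bp.
#' @param coverage Fraction of each query genome covered, in `[0, 1]`.
#' @param identity Percent identity of the planted hits.
#' @param evalue E-value assigned to every hit.
#' @param aln_length Alignment length recorded per hit; defaults to the
#'   covered span.
#' @return Data frame in [read_blast_tab()] layout (both directions).
#' @export
plant_reciprocal_hits <- function(genome_a, genome_b, len_a, len_b,
                                  coverage, identity = 100, evalue = 1e-10,
                                  aln_length = NULL) {
  stopifnot(coverage >= 0, coverage <= 1)
  one <- function(q, s, lq) {
    span <- round(coverage * lq)
    if (span == 0) return(NULL)
    data.frame(qseqid = q, sseqid = s, pident = identity, length =
                 if (is.null(aln_length)) span else aln_length,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = span,
               sstart = 1L, send = span, evalue = evalue, bitscore = 2 * span,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(genome_a, genome_b, len_a), one(genome_b, genome_a, len_b))
  if (is.null(out))
    out <- data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  out
}
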