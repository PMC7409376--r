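# Shared fixture builders (everything is generated in code).

identity_matrix <- function(labels) {
  m <- diag(1, length(labels))
  dimnames(m) <- list(labels, labels)
  m
}

prof <- function(id, fams, circular = TRUE)
  genome_profile(id, fams, circular = circular)

# a random profile pair: an ancestor and a mutated copy
mutated_pair <- function(config, n_events, seed) {
  set.seed(seed)
  a <- genome_profile("a", sample(sprintf("F%04d", 1:config$n_families),
                                  config$genome_length))
  b <- apply_events(genome_profile("b", a$families), config, n_events)$profile
  list(a = a, b = b)
}

# annotation TSV written on the fly
write_annotation_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# minimal single-genome GFF3 with one CDS per row
write_gff3 <- function(starts, ends, seqid = "g1") {
  f <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tCDS\t%d\t%d\t.\t+\t0\tID=cds%02d",
                     seqid, starts, ends, seq_along(starts)))
  writeLines(lines, f)
  f
}

balanced8 <- function()
  ape::read.tree(text = paste0("(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
                               "((t5:1,t6:1):1,(t7:1,t8:1):1):1);"))
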