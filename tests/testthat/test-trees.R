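test_that("BioNJ recovers additive matrices exactly", {
  # hand-built 4-taxon additive case
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  d <- ape::cophenetic.phylo(tr)
  est <- bionj_tree(d)
  expect_equal(robinson_foulds(est, tr), 0)
  expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(d), colnames(d)] - d)),
            1e-6)
  # random additive matrices up to 12 leaves
  set.seed(5)
  for (k in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    d <- ape::cophenetic.phylo(tr)
    est <- bionj_tree(d)
    expect_equal(robinson_foulds(est, tr), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(d), colnames(d)] -
                        d)), 1e-5)
  }
})

test_that("BioNJ input validation and degenerate cases", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(bionj_tree(d), "at least 3")
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- bionj_tree(d3)
  expect_equal(length(t3$tip.label), 3L)
  # three-point formulas: pendant edges (1, 1, 2)
  expect_equal(sort(t3$edge.length), c(1, 1, 2))
  dn <- d3
  dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(bionj_tree(dn), "NA/NaN")
  # non-symmetric input refused
  ds <- d3
  ds[1, 2] <- 5
  expect_error(bionj_tree(ds), "symmetric")
  # no negative branch lengths survive postprocessing
  set.seed(8)
  for (k in 1:10) {
    n <- sample(4:10, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 1)
    m <- m + t(m)
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_true(all(bionj_tree(m)$edge.length >= 0))
  }
})

test_that("BioNJ and classical NJ agree on ultrametric matrices", {
  set.seed(12)
  for (k in 1:5) {
    tr <- ape::rcoal(8)
    d <- ape::cophenetic.phylo(tr)
    expect_equal(robinson_foulds(bionj_tree(d), ape::nj(d)), 0)
  }
})

test_that("outgroup rooting splits the pendant edge and keeps the topology", {
  set.seed(2)
  tr <- ape::rtree(8)
  rooted <- root_at_outgroup(tr, "t5")
  expect_true(ape::is.rooted(rooted))
  root <- length(rooted$tip.label) + 1L
  root_children <- rooted$edge[rooted$edge[, 1] == root, 2]
  expect_true(match("t5", rooted$tip.label) %in% root_children)
  # unrooting recovers the original topology
  expect_equal(robinson_foulds(rooted, tr), 0)
  # outgroup pendant edge is halved
  old_len <- tr$edge.length[tr$edge[, 2] == match("t5", tr$tip.label)]
  new_len <- rooted$edge.length[rooted$edge[, 2] ==
                                  match("t5", rooted$tip.label)]
  expect_equal(new_len, old_len / 2)
  expect_error(root_at_outgroup(tr, "nope"), "nope")
})

test_that("Robinson-Foulds handles the analytic cases", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(robinson_foulds(t1, t1), 0)
  # conflicting binary quartets: each has one internal bipartition, unshared
  q1 <- ape::read.tree(text = "((A,B),(C,D));")
  q2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(q1, q2), 1.0)
  # five taxa sharing one of two internal bipartitions each: 2/4
  t2 <- ape::read.tree(text = "((A,B),(C,E),D);")
  expect_equal(robinson_foulds(t1, t2), 0.5)
  expect_equal(robinson_foulds(t1, t2, normalized = FALSE), 2)
  expect_error(robinson_foulds(t1, q1), "leaf sets")
})

test_that("Robinson-Foulds is a pseudometric matching phangorn on counts", {
  set.seed(33)
  trees <- lapply(1:6, function(i) ape::rtree(10))
  for (i in 1:5) {
    a <- trees[[i]]
    b <- trees[[i + 1]]
    raw <- robinson_foulds(a, b, normalized = FALSE)
    expect_identical(robinson_foulds(b, a, normalized = FALSE), raw)
    expect_equal(raw, as.numeric(phangorn::RF.dist(a, b)))
    nrm <- robinson_foulds(a, b)
    expect_gte(nrm, 0)
    expect_lte(nrm, 1)
  }
  # triangle inequality on the raw count
  for (k in 1:4) {
    r_ab <- robinson_foulds(trees[[k]], trees[[k + 1]], normalized = FALSE)
    r_bc <- robinson_foulds(trees[[k + 1]], trees[[k + 2]], normalized = FALSE)
    r_ac <- robinson_foulds(trees[[k]], trees[[k + 2]], normalized = FALSE)
    expect_lte(r_ac, r_ab + r_bc)
  }
})

test_that("Newick I/O round-trips topology, lengths and quoted labels", {
  f <- tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:2,C:3):4);", f)
  t <- read_newick(f)
  f2 <- tempfile(fileext = ".nwk")
  write_newick(t, f2)
  t2 <- read_newick(f2)
  expect_equal(robinson_foulds(t, t2), 0)
  expect_equal(sort(t2$tip.label), sort(t$tip.label))
  expect_equal(sum(t2$edge.length), sum(t$edge.length), tolerance = 1e-9)

  writeLines("('sp one':1,(B:2,C:3):4);", f)
  t <- read_newick(f)
  expect_true("sp one" %in% t$tip.label)
  write_newick(t, f2)
  expect_true("sp one" %in% read_newick(f2)$tip.label)

  writeLines("(A:1,(B:2,C:3):4;", f)  # unbalanced parentheses
  expect_error(suppressWarnings(read_newick(f)))
  writeLines("(A:1,(A:2,C:3):4);", f)
  expect_error(read_newick(f), "duplicate")
})

test_that("PHYLIP lower-triangle distance files round-trip", {
  set.seed(4)
  tr <- ape::rtree(7)
  d <- ape::cophenetic.phylo(tr)
  f <- tempfile(fileext = ".phy")
  write_phylip_dist(d, f)
  back <- read_phylip_dist(f)
  expect_equal(rownames(back), rownames(d))
  expect_lt(max(abs(back - d)), 1e-8)
  expect_equal(as.integer(trimws(readLines(f, 1))), 7L)
})
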