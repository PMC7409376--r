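par05 <- alignment_params(gap_penalty = 0.5)

test_that("semiglobal alignment matches hand-computable cases", {
  m <- identity_matrix(c("A", "B", "C", "D"))
  a <- prof("a", c("A", "B", "C"))
  r <- semiglobal_align(a, prof("b", c("A", "B", "C")), m, par05)
  expect_equal(r$score, 3)
  expect_equal(unname(r$aligned_pairs), cbind(1:3, 1:3), ignore_attr = TRUE)

  # one internal gap
  r <- semiglobal_align(a, prof("b", c("A", "C")), m, par05)
  expect_equal(r$score, 1.5)

  # nothing alignable: free end gaps give zero
  r <- semiglobal_align(prof("a", c("A", "B")), prof("b", c("C", "D")),
                        m, par05)
  expect_equal(r$score, 0)

  # end gaps really are free: shared block at opposite ends
  r <- semiglobal_align(prof("a", c("C", "D", "A", "B"), circular = FALSE),
                        prof("b", c("A", "B"), circular = FALSE), m, par05)
  expect_equal(r$score, 2)
})

test_that("alignment score equals re-scored pairs minus internal gap costs", {
  set.seed(21)
  pool <- LETTERS[1:8]
  m <- synth_similarity_matrix(pool, noise = 0.6, seed = 5)
  for (k in 1:25) {
    a <- prof("a", sample(pool, sample(3:9, 1), replace = TRUE))
    b <- prof("b", sample(pool, sample(3:9, 1), replace = TRUE))
    r <- best_alignment(a, b, m, par05)
    ta <- a$families[((seq_along(a$families) - 1 + r$rotation_offset_a) %%
                        length(a$families)) + 1]
    tb <- b$families[((seq_along(b$families) - 1 + r$rotation_offset_b) %%
                        length(b$families)) + 1]
    if (r$orientation == "antisense") tb <- rev(tb)
    p <- r$aligned_pairs
    match_sum <- sum(m[cbind(ta[p[, 1]], tb[p[, 2]])])
    gaps <- 0
    if (nrow(p) > 0) {
      gaps <- (max(p[, 1]) - min(p[, 1]) + 1 - nrow(p)) +
        (max(p[, 2]) - min(p[, 2]) + 1 - nrow(p))
    }
    expect_equal(r$score, match_sum - r$gap_penalty * gaps, tolerance = 1e-9)
  }
})

test_that("rotation and antisense searches find the planted arrangement", {
  m <- identity_matrix(LETTERS[1:4])
  r <- best_alignment(prof("a", c("A", "B", "C", "D")),
                      prof("b", c("C", "D", "A", "B")), m, par05)
  expect_equal(r$score, 4)
  expect_equal(r$rotation_offset_a, 0L)
  expect_equal(r$rotation_offset_b, 2L)
  expect_equal(r$orientation, "sense")

  r <- best_alignment(prof("a", c("A", "B", "C"), circular = FALSE),
                      prof("b", c("C", "B", "A"), circular = FALSE),
                      m, alignment_params(gap_penalty = 0.5,
                                          search_rotations = FALSE))
  expect_equal(r$score, 3)
  expect_equal(r$orientation, "antisense")

  # linear second genome: only offset 0 explored
  r <- best_alignment(prof("a", c("A", "B", "C", "D")),
                      prof("b", c("C", "D", "A", "B"), circular = FALSE),
                      m, par05)
  expect_equal(r$rotation_offset_b, 0L)
})

test_that("dynamic programming equals the exhaustive oracle on short pairs", {
  set.seed(42)
  pool <- LETTERS[1:6]
  m <- synth_similarity_matrix(pool, noise = 0.5, seed = 7)
  for (k in 1:40) {
    a <- prof("a", sample(pool, sample(2:7, 1), replace = TRUE))
    b <- prof("b", sample(pool, sample(2:7, 1), replace = TRUE))
    expect_equal(best_alignment(a, b, m)$score,
                 best_alignment_exhaustive(a, b, m), tolerance = 1e-9)
  }
})

test_that("labels absent from the matrix are auto-extended only for ORFANs", {
  m <- identity_matrix(c("A", "B"))
  a <- prof("a", c("A", "ORFAN:g:x"))
  b <- prof("b", c("A", "B"))
  r <- best_alignment(a, b, m)
  expect_equal(r$score, 1)  # ORFAN matches nothing but itself
  expect_error(
    best_alignment(prof("a", c("A", "Z")), b, m),
    "missing from substitution matrix.*Z")
  expect_error(
    best_alignment(a, b, m, alignment_params(extend_orfans = FALSE)),
    "ORFAN")
})

test_that("distances satisfy the metric-style axioms and invariances", {
  cfg <- evolution_config()
  for (s in 1:20) {
    pr <- mutated_pair(cfg, n_events = sample(0:6, 1), seed = 100 + s)
    labs <- unique(c(pr$a$families, pr$b$families))
    m <- synth_similarity_matrix(labs)
    dab <- goat_distance(pr$a, pr$b, m)
    expect_equal(goat_distance(pr$a, pr$a, m), 0)
    expect_identical(dab, goat_distance(pr$b, pr$a, m))
    expect_gte(dab, 0)
    expect_lte(dab, 1)
    # rotating or reversing either input is invisible to the distance
    off <- sample(length(pr$a$families) - 1, 1)
    rot <- prof("a", pr$a$families[((seq_along(pr$a$families) - 1 + off) %%
                                      length(pr$a$families)) + 1])
    expect_equal(goat_distance(rot, pr$b, m), dab, tolerance = 1e-9)
    rev_b <- prof("b", rev(pr$b$families))
    expect_equal(goat_distance(pr$a, rev_b, m), dab, tolerance = 1e-9)
  }
})

test_that("distances are invariant to rescaling the substitution matrix", {
  cfg <- evolution_config()
  pr <- mutated_pair(cfg, n_events = 4, seed = 7)
  labs <- unique(c(pr$a$families, pr$b$families))
  m <- synth_similarity_matrix(labs, noise = 0.3, seed = 8)
  d1 <- goat_distance(pr$a, pr$b, m)          # default matrix-relative gap
  d2 <- goat_distance(pr$a, pr$b, m * 7.5)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("mean distance grows with the number of evolutionary events", {
  cfg <- evolution_config(rotation = 0)  # rotations are invisible by design
  levels <- c(1L, 4L, 12L)
  means <- sapply(levels, function(nev) {
    mean(sapply(1:35, function(s) {
      pr <- mutated_pair(cfg, n_events = nev, seed = 1000 * nev + s)
      labs <- unique(c(pr$a$families, pr$b$families))
      goat_distance(pr$a, pr$b, synth_similarity_matrix(labs))
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("distance matrices are symmetric with zero diagonal", {
  cfg <- evolution_config(seed = 31)
  sim <- evolve_along_tree(balanced8(), cfg)
  profs <- sim$profiles[1:4]
  labs <- unique(unlist(lapply(profs, `[[`, "families")))
  d <- goat_distance_matrix(profs, synth_similarity_matrix(labs))
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 1))
  # identical genomes at distance zero
  two <- list(prof("x", c("A", "B", "C")), prof("y", c("A", "B", "C")))
  d2 <- goat_distance_matrix(two, identity_matrix(c("A", "B", "C")))
  expect_equal(unname(d2), matrix(0, 2, 2))
})
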