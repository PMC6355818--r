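simple_dna <- function(mode, open, ext, match = 1, mismatch = -1) {
  align_params(mode = mode, alphabet = "dna", gap_open = open,
               gap_extend = ext, match = match, mismatch = mismatch)
}

test_that("local and global alignment reproduce hand-checked scores", {
  p <- simple_dna("local", -2, -2)
  r <- pairwise_align("ACGT", "ACGT", p)
  expect_equal(r$score, 4)
  expect_equal(r$identity_pct, 100)

  r2 <- pairwise_align("AAAA", "CCCC", p)
  expect_equal(r2$score, 0)
  expect_equal(r2$aligned_cols, 0)

  pg <- simple_dna("global", -1, -1)
  r3 <- pairwise_align("ACGT", "AGT", pg)
  expect_equal(r3$score, 2)
  expect_equal(r3$gap_cols, 1)
  expect_equal(r3$matches, 3)
})

test_that("alignment accounting is internally consistent", {
  set.seed(31)
  p <- align_params(mode = "global", alphabet = "protein")
  for (i in 1:10) {
    a <- rand_protein(sample(5:30, 1))
    b <- rand_protein(sample(5:30, 1))
    r <- pairwise_align(a, b, p)
    expect_equal(r$matches + r$mismatches + r$gap_cols, r$aligned_cols)
    expect_true(r$identity_pct >= 0 && r$identity_pct <= 100)
  }
})

test_that("sequences from different alphabets are rejected", {
  expect_error(pairwise_align("ACGT", "MDEK"), "different alphabets")
  expect_error(pairwise_align("", "ACGT"), "empty")
})

test_that("dynamic programming matches the exhaustive enumerator (mini battery)", {
  set.seed(32)
  pg_dna <- simple_dna("global", -3, -1, match = 2, mismatch = -2)
  pg_aa <- align_params(mode = "global", alphabet = "protein")
  for (i in 1:20) {
    a <- rand_dna_str(sample(1:6, 1)); b <- rand_dna_str(sample(1:6, 1))
    expect_equal(pairwise_align(a, b, pg_dna)$score,
                 enumerate_alignment_score(a, b, pg_dna))
    a2 <- rand_protein(sample(1:6, 1)); b2 <- rand_protein(sample(1:6, 1))
    expect_equal(pairwise_align(a2, b2, pg_aa)$score,
                 enumerate_alignment_score(a2, b2, pg_aa))
  }
  pl <- simple_dna("local", -2, -1)
  for (i in 1:8) {
    a <- rand_dna_str(sample(2:4, 1)); b <- rand_dna_str(sample(2:4, 1))
    expect_equal(pairwise_align(a, b, pl)$score,
                 enumerate_alignment_score(a, b, pl))
  }
})

test_that("percent identity matches the published worked example", {
  # gapless 480-column alignment differing at 24 sites -> 95.0%
  set.seed(33)
  a <- rand_protein(480)
  idx <- sample(480, 24)
  bch <- strsplit(a, "")[[1]]
  for (i in idx) bch[i] <- setdiff(c("A", "L", "K", "D"), bch[i])[1]
  b <- paste(bch, collapse = "")
  r <- pairwise_align(a, b, align_params(mode = "global",
                                         alphabet = "protein"))
  expect_equal(r$aligned_cols, 480)
  expect_equal(r$mismatches, 24)
  expect_equal(percent_identity(r), 95.0)
})

test_that("percent identity handles denominators and empty alignments", {
  r <- list(matches = 5, mismatches = 5, gap_cols = 0, aligned_cols = 10)
  expect_equal(percent_identity(r), 50)
  r2 <- list(matches = 6, mismatches = 2, gap_cols = 2, aligned_cols = 10)
  expect_equal(percent_identity(r2), 60)
  expect_equal(percent_identity(r2, include_gaps = FALSE), 75)
  r3 <- list(matches = 0, mismatches = 0, gap_cols = 0, aligned_cols = 0)
  expect_error(percent_identity(r3), "empty")
})

test_that("Karlin-Altschul expectation behaves as the closed form", {
  lambda <- 1.33; K <- 0.621
  S1 <- log(K * 1000 * 1000) / lambda
  expect_equal(karlin_evalue(S1, 1000, 1000, lambda, K), 1.0,
               tolerance = 1e-12)
  expect_equal(karlin_evalue(20, 1000, 1000, lambda, K),
               0.621e6 * exp(-26.6), tolerance = 1e-12)
  # linear in database size, strictly decreasing in score
  expect_equal(karlin_evalue(20, 1000, 2000, lambda, K),
               2 * karlin_evalue(20, 1000, 1000, lambda, K))
  expect_lt(karlin_evalue(21, 1000, 1000, lambda, K),
            karlin_evalue(20, 1000, 1000, lambda, K))
  expect_error(karlin_evalue(10, 100, 100, -1, 0.1), "positive")
  expect_error(karlin_evalue(10, 100, 100, 0.5, 0), "positive")
})

test_that("family harvesting separates homologs from random proteins", {
  set.seed(34)
  base_cds <- famdup:::random_cds(750)
  query <- c(query = as.character(translate_cds(base_cds)))
  homologs <- vapply(1:20, function(i) {
    as.character(translate_cds(mutate_seq(base_cds, 0.10)))
  }, character(1))
  names(homologs) <- sprintf("hom_%02d", 1:20)
  decoys <- random_proteins(20, len = 249)
  proteome <- c(homologs, decoys)[sample(40)]
  hits <- find_family(query, proteome)
  expect_setequal(hits$sseqid, names(homologs))  # recall and precision 1
  expect_true(all(diff(hits$score) <= 0))        # sorted by score

  # query present in the proteome: it is the top hit at 100% identity
  hits2 <- find_family(query, c(proteome, self = query[[1]]))
  expect_identical(hits2$sseqid[1], "self")
  expect_equal(hits2$pident[1], 100)

  # nothing passes an impossible threshold
  expect_equal(nrow(find_family(query, decoys)), 0)
})

test_that("p-distance and Poisson correction follow their definitions", {
  expect_equal(p_distance("MDEK", "MDEK"), 0)
  expect_equal(p_distance("MDEK", "MDQK"), 0.25)
  set.seed(35)
  for (i in 1:5) {
    a <- rand_protein(40); b <- rand_protein(40)
    expect_equal(p_distance(a, b), p_distance(b, a))
  }
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2), tolerance = 1e-12)
  expect_equal(poisson_correct(0.95), -log(0.05), tolerance = 1e-12)
  expect_error(poisson_correct(1), "p >= 1")
  p <- seq(0, 0.9, by = 0.1)
  expect_true(all(poisson_correct(p) >= p))
  expect_true(all(diff(poisson_correct(p)) > 0))
})

test_that("Poisson-corrected distances form a metric on diverged proteins", {
  set.seed(36)
  base <- famdup:::random_cds(600)
  prots <- vapply(1:6, function(i) {
    as.character(translate_cds(mutate_seq(base, 0.05)))
  }, character(1))
  names(prots) <- sprintf("p%d", 1:6)
  D <- family_distances(prots)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_gte(D[i, j] + D[j, k] - D[i, k], -1e-9)
  }
})
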