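mk_models <- function(ids, chrom, start, width = 2000L) {
  gene_models(ids, chrom, rep("+", length(ids)), start, start + width,
              lapply(start, function(s) cbind(s, s + width)))
}

test_that("tandem chaining groups nearby sister genes", {
  models <- mk_models(c("g1", "g2", "g3"), rep("c1", 3),
                      c(10000L, 40000L, 70000L))
  tree <- ape::read.tree(text = "(((g1:1,g2:1):1,g3:1):1,out:1);")
  cl <- detect_tandem_clusters(models, tree)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members, c("g1", "g2", "g3"))
  expect_equal(cl[[1]]$sisterhood_fraction, 1.0)
  expect_true(cl[[1]]$tandem_origin)

  # different chromosomes never cluster
  m2 <- mk_models(c("a", "b"), c("c1", "c2"), c(1000L, 1000L))
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_length(detect_tandem_clusters(m2, t2), 0)

  # genes beyond the gap limit split into separate chains
  m3 <- mk_models(c("x", "y"), c("c1", "c1"), c(1000L, 400000L))
  t3 <- ape::read.tree(text = "(x:1,y:1);")
  expect_length(detect_tandem_clusters(m3, t3), 0)

  expect_error(detect_tandem_clusters(models,
                                      ape::read.tree(text = "(g1:1,g2:1);")),
               "g3")
})

test_that("intervening non-family genes break chains", {
  fam <- mk_models(c("f1", "f2"), c("c1", "c1"), c(10000L, 60000L))
  tree <- ape::read.tree(text = "(f1:1,f2:1);")
  decoys <- mk_models(sprintf("d%d", 1:6), rep("c1", 6),
                      seq(15000L, 40000L, by = 5000L), width = 500L)
  all1 <- rbind(fam, decoys)
  expect_length(detect_tandem_clusters(fam, tree, all_models = all1), 0)
  few <- rbind(fam, decoys[1:3, ])
  expect_length(detect_tandem_clusters(fam, tree, all_models = few), 1)
})

test_that("cluster chaining is order-independent", {
  set.seed(81)
  ids <- sprintf("g%d", 1:6)
  models <- mk_models(ids, rep("c1", 6),
                      c(1e4, 3e4, 5e4, 5e5, 5.2e5, 9e5))
  tree <- ape::read.tree(
    text = "(((g1:1,g2:1):1,g3:1):1,((g4:1,g5:1):1,g6:1):1);")
  ref <- detect_tandem_clusters(models, tree)
  for (i in 1:3) {
    shuf <- models[sample(nrow(models)), ]
    expect_equal(detect_tandem_clusters(shuf, tree), ref)
  }
})

test_that("retro interlopers do not spoil sisterhood when ignored", {
  models <- mk_models(c("g1", "g2"), c("c1", "c1"), c(10000L, 30000L))
  # each array member's nearest tree relative is its own retrocopy
  tree <- ape::read.tree(text = "((g1:1,r1:1):1,(g2:1,r2:1):1);")
  naive <- detect_tandem_clusters(models, tree)
  expect_equal(naive[[1]]$sisterhood_fraction, 0)
  informed <- detect_tandem_clusters(models, tree,
                                     ignore_leaves = c("r1", "r2"))
  expect_equal(informed[[1]]$sisterhood_fraction, 1.0)
  expect_true(informed[[1]]$tandem_origin)
})

test_that("segmental pairs respect the identity and E-value thresholds", {
  set.seed(82)
  base <- famdup:::random_cds(600)
  near <- mutate_seq(base, 0.05)   # ~90% identity
  far <- mutate_seq(base, 0.30)    # well below 80%
  gs <- function(cds) structure(list(cds = cds), class = "gene_sequences")
  seqs <- list(a = gs(base), b = gs(near), c = gs(far))
  models <- mk_models(c("a", "b", "c"), c("c1", "c2", "c3"),
                      rep(1000L, 3), width = 600L)
  pairs <- detect_segmental_pairs(seqs, models)
  expect_true(any(pairs$gene_a == "a" & pairs$gene_b == "b"))
  expect_false(any(pairs$gene_a == "a" & pairs$gene_b == "c"))
  ab <- pairs[pairs$gene_a == "a" & pairs$gene_b == "b", ]
  expect_gt(ab$identity_pct, 80)
  expect_lt(ab$evalue, 1e-10)

  # identical but short sequences fail the E-value screen
  short <- famdup:::random_cds(30)
  seqs2 <- list(s1 = gs(short), s2 = gs(short))
  models2 <- mk_models(c("s1", "s2"), c("c1", "c2"), c(100L, 100L),
                       width = 30L)
  expect_equal(nrow(detect_segmental_pairs(seqs2, models2)), 0)

  # pairs within a tandem-origin cluster are excluded
  seqs3 <- list(a = gs(base), b = gs(near))
  models3 <- mk_models(c("a", "b"), c("c1", "c1"), c(1000L, 9000L),
                       width = 600L)
  cl <- list(list(cluster_id = "TC01", chrom = "c1",
                  members = c("a", "b"), sisterhood_fraction = 1,
                  tandem_origin = TRUE))
  expect_equal(nrow(detect_segmental_pairs(seqs3, models3, clusters = cl)),
               0)
})

test_that("tightening thresholds never adds segmental pairs", {
  set.seed(83)
  base <- famdup:::random_cds(450)
  gs <- function(cds) structure(list(cds = cds), class = "gene_sequences")
  seqs <- list(a = gs(base), b = gs(mutate_seq(base, 0.05)),
               c = gs(mutate_seq(base, 0.12)),
               d = gs(mutate_seq(base, 0.2)))
  models <- mk_models(letters[1:4], paste0("c", 1:4), rep(1000L, 4),
                      width = 450L)
  loose <- detect_segmental_pairs(seqs, models, min_identity = 75)
  tight <- detect_segmental_pairs(seqs, models, min_identity = 85)
  key <- function(p) paste(p$gene_a, p$gene_b)
  expect_true(all(key(tight) %in% key(loose)))
  tighter_e <- detect_segmental_pairs(seqs, models, min_identity = 75,
                                      max_evalue = 1e-100)
  expect_true(all(key(tighter_e) %in% key(loose)))
})

test_that("mode assignment follows the documented precedence", {
  clusters <- list(list(cluster_id = "TC01", chrom = "c1",
                        members = c("t1", "t2"),
                        sisterhood_fraction = 1, tandem_origin = TRUE))
  pairs <- data.frame(gene_a = "s1", gene_b = "t1",
                      identity_pct = 90, evalue = 1e-30, score = 500,
                      same_chrom = FALSE, reciprocal_best = TRUE,
                      stringsAsFactors = FALSE)
  calls <- assign_modes(c("t1", "t2", "s1", "r1", "u1"), clusters, pairs,
                        retro_genes = c("r1", "t2"))
  modes <- setNames(calls$primary_mode, calls$gene_id)
  expect_identical(unname(modes[c("t2", "r1")]), c("retro", "retro"))
  expect_identical(unname(modes["t1"]), "tandem")  # despite segmental pair
  expect_identical(unname(modes["s1"]), "segmental")
  expect_identical(unname(modes["u1"]), "unclassified")
  expect_true(calls$in_tandem_cluster[calls$gene_id == "t2"])  # flags kept
  expect_error(assign_modes(c("a", "a"), list(), pairs[0, ], character(0)),
               "duplicate")
})
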