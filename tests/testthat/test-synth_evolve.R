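test_that("mutation respects rate extremes and expectation", {
  s <- rand_dna_str(200)
  expect_identical(mutate_seq(s, 0), s)
  m1 <- mutate_seq(s, 1)
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  expect_error(mutate_seq(s, 1.5), "rate")

  set.seed(71)
  long <- rand_dna_str(10000)
  frac <- mean(strsplit(mutate_seq(long, 0.1), "")[[1]] !=
                 strsplit(long, "")[[1]])
  sigma <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * sigma)

  # length preserved, N untouched
  expect_identical(nchar(mutate_seq(rand_dna_str(57), 0.3)), 57L)
  expect_identical(mutate_seq("NNNN", 1), "NNNN")
})

test_that("a zero-divergence retro event leaves a verbatim signature", {
  cfg <- sim_config(seed = 101, n_events = 1L,
                    event_counts = c(tandem = 0L, segmental = 0L,
                                     retro = 1L),
                    subs_rate = 0)
  ds <- simulate_family(cfg)
  expect_equal(nrow(ds$truth), 1L)
  retro_id <- ds$truth$new_gene_id[1]
  donor_id <- ds$truth$donor_gene_id[1]
  seqs <- extract_all_genes(ds$genome, ds$models)
  # spliced CDS identical to the donor's, single exon
  expect_identical(seqs[[retro_id]]$cds, seqs[[donor_id]]$cds)
  expect_equal(seqs[[retro_id]]$intron_count, 0L)
  expect_identical(as.character(seqs[[retro_id]]$protein),
                   as.character(seqs[[donor_id]]$protein))
  # poly(A) tail verbatim at the start of the 3' flank
  expect_identical(substr(seqs[[retro_id]]$flank3, 1, 15), strrep("A", 15))
  # TSD duplicated on both sides
  f5 <- seqs[[retro_id]]$flank5
  tsd5 <- substr(f5, nchar(f5) - 11, nchar(f5))
  tsd3 <- substr(seqs[[retro_id]]$flank3, 16, 27)
  expect_identical(tsd5, tsd3)
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 7, n_events = 6L,
                    event_counts = c(tandem = 2L, segmental = 2L,
                                     retro = 2L))
  d1 <- simulate_family(cfg)
  d2 <- simulate_family(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$models, d2$models)
  d3 <- simulate_family(sim_config(seed = 8, n_events = 6L,
                                   event_counts = c(tandem = 2L,
                                                    segmental = 2L,
                                                    retro = 2L)))
  expect_false(identical(d1$genome, d3$genome))
})

test_that("event accounting matches the configuration", {
  ds <- simulate_family(sim_config(seed = 9))
  expect_equal(nrow(ds$truth), 12L)
  expect_equal(unname(table(ds$truth$type)[c("retro", "segmental",
                                             "tandem")]),
               c(4L, 4L, 4L), ignore_attr = TRUE)
  # every truth gene exists in the models; retro copies are intronless;
  # tandem copies share the donor chromosome; segmental copies do not
  expect_true(all(ds$truth$new_gene_id %in% ds$models$gene_id))
  ic <- intron_count(ds$models)
  expect_true(all(ic[ds$truth$new_gene_id[ds$truth$type == "retro"]] == 0))
  donor_chrom <- ds$genes$chrom[match(ds$truth$donor_gene_id,
                                      ds$genes$gene_id)]
  new_chrom <- ds$genes$chrom[match(ds$truth$new_gene_id,
                                    ds$genes$gene_id)]
  tnd <- ds$truth$type == "tandem"
  expect_true(all(donor_chrom[tnd] == new_chrom[tnd]))
  seg <- ds$truth$type == "segmental"
  expect_true(all(donor_chrom[seg] != new_chrom[seg]))
  # tandem copies land close to their donors
  dpos <- ds$genes$start[match(ds$truth$donor_gene_id, ds$genes$gene_id)]
  npos <- ds$genes$start[match(ds$truth$new_gene_id, ds$genes$gene_id)]
  expect_true(all(abs(dpos - npos)[tnd] < 100000))

  # probability-driven scheduling also honours n_events
  ds2 <- simulate_family(sim_config(seed = 10, n_events = 5L,
                                    event_counts = NULL,
                                    event_type_probs = c(1/3, 1/3, 1/3)))
  expect_equal(nrow(ds2$truth), 5L)
})

test_that("stored proteins equal translated extractions (conservation)", {
  ds <- simulate_family(sim_config(seed = 11, n_events = 6L,
                                   event_counts = c(tandem = 2L,
                                                    segmental = 2L,
                                                    retro = 2L)))
  seqs <- extract_all_genes(ds$genome, ds$models)
  for (g in names(ds$proteins)) {
    expect_identical(as.character(seqs[[g]]$protein),
                     as.character(ds$proteins[[g]]))
  }
})

test_that("truth tables round-trip through TSV", {
  ds <- simulate_family(sim_config(seed = 12, n_events = 3L,
                                   event_counts = c(tandem = 1L,
                                                    segmental = 1L,
                                                    retro = 1L)))
  path <- tempfile(fileext = ".tsv")
  write_truth(ds, path)
  back <- read_truth(path)
  expect_equal(back, ds$truth, ignore_attr = TRUE)

  # an empty run writes a header-only file
  ds0 <- simulate_family(sim_config(seed = 13, n_events = 0L,
                                    event_counts = c(tandem = 0L,
                                                     segmental = 0L,
                                                     retro = 0L)))
  p0 <- tempfile(fileext = ".tsv")
  write_truth(ds0, p0)
  expect_length(readLines(p0), 1L)
  expect_equal(nrow(read_truth(p0)), 0L)
})
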