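test_that("FASTA parsing normalises case, keeps order, rejects bad input", {
  p <- tmp_write(c(">a", "acgt"), ".fa")
  expect_identical(parse_fasta(p), c(a = "ACGT"))

  p2 <- tmp_write(c(">x", "AAAA", ">y desc text", "CCGG"), ".fa")
  recs <- parse_fasta(p2)
  expect_identical(names(recs), c("x", "y"))
  expect_identical(unname(recs), c("AAAA", "CCGG"))

  dup <- tmp_write(c(">a", "AC", ">a", "GT"), ".fa")
  expect_error(parse_fasta(dup), "duplicate.*a")
})

test_that("FASTA round-trips through the 60-column writer", {
  set.seed(11)
  seqs <- c(g1 = rand_dna_str(150), g2 = rand_dna_str(61),
            g3 = rand_dna_str(60), g4 = rand_dna_str(7))
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_identical(parse_fasta(path), seqs)
  # wrapped at 60 columns
  expect_true(all(nchar(readLines(path)) <= 61))
})

test_that("GFF3 parsing collates exons, applies fallbacks, validates", {
  g <- c("##gff-version 3",
         "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gA",
         "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
         "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
         "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
         "chr1\tsrc\tgene\t600\t800\t.\t-\t.\tID=gB",
         "chr1\tsrc\tmRNA\t600\t800\t.\t-\t.\tID=gB.t1;Parent=gB",
         "chr1\tsrc\tCDS\t600\t800\t.\t-\t.\tID=gB.c1;Parent=gB.t1",
         "chr2\tsrc\tgene\t50\t90\t.\t+\t.\tID=gC")
  models <- parse_gff3(tmp_write(g, ".gff3"))
  expect_equal(nrow(models), 3L)
  ic <- intron_count(models)
  expect_equal(unname(ic[c("gA", "gB", "gC")]), c(1L, 0L, 0L))
  # CDS fallback and gene-span fallback produce single exons
  expect_equal(models$exons[[match("gB", models$gene_id)]][1, ],
               c(start = 600L, end = 800L))
  expect_equal(models$exons[[match("gC", models$gene_id)]][1, ],
               c(start = 50L, end = 90L))
  # sorted by (chrom, start)
  expect_identical(models$gene_id, c("gA", "gB", "gC"))
})

test_that("GFF3 round-trips through the writer", {
  models <- gene_models(c("x1", "x2"), c("c1", "c1"), c("+", "-"),
                        c(10L, 500L), c(90L, 700L),
                        list(cbind(c(10L, 60L), c(40L, 90L)),
                             cbind(500L, 700L)))
  path <- tempfile(fileext = ".gff3")
  write_gff3(models, path)
  again <- parse_gff3(path)
  expect_equal(again$gene_id, models$gene_id)
  expect_equal(again$exons, models$exons)
  expect_identical(readLines(path)[1], "##gff-version 3")
})

test_that("invalid gene models are rejected with informative errors", {
  expect_error(gene_models("g", "c1", "+", 10L, 5L, list(cbind(10L, 5L))),
               "start > end")
  expect_error(gene_models("g", "c1", "*", 1L, 10L, list(cbind(1L, 10L))),
               "unknown strand")
  expect_error(gene_models("g", "c1", "+", 10L, 100L,
                           list(cbind(c(10L, 30L), c(50L, 70L)))),
               "overlapping")
  expect_error(gene_models("g", "c1", "+", 10L, 20L, list(cbind(5L, 20L))),
               "outside gene span")
})

test_that("gene sequence extraction honours strand and clips flanks", {
  chr <- paste0(strrep("G", 10), "ATGAAATAA", strrep("C", 10))
  genome <- c(c1 = chr)
  plus <- gene_models("gp", "c1", "+", 11L, 19L, list(cbind(11L, 19L)))
  sp <- extract_gene_sequences(genome, plus, flank_bp = 5L)
  expect_identical(sp$cds, "ATGAAATAA")
  expect_identical(as.character(sp$protein), "MK")
  expect_identical(sp$flank5, "GGGGG")
  expect_identical(sp$flank3, "CCCCC")
  expect_false(sp$clipped5 || sp$clipped3)

  minus <- gene_models("gm", "c1", "-", 11L, 19L, list(cbind(11L, 19L)))
  sm <- extract_gene_sequences(genome, minus, flank_bp = 5L)
  expect_identical(sm$cds, revcomp("ATGAAATAA"))
  expect_identical(sm$flank5, revcomp("CCCCC"))
  expect_identical(sm$flank3, revcomp("GGGGG"))

  edge <- gene_models("ge", "c1", "+", 1L, 9L, list(cbind(1L, 9L)))
  se <- extract_gene_sequences(genome, edge, flank_bp = 5L)
  expect_identical(se$flank5, "")
  expect_true(se$clipped5)

  beyond <- gene_models("gz", "c1", "+", 1L, 999L, list(cbind(1L, 999L)))
  expect_error(extract_gene_sequences(genome, beyond), "beyond contig")
  wrong <- gene_models("gw", "cX", "+", 1L, 9L, list(cbind(1L, 9L)))
  expect_error(extract_gene_sequences(genome, wrong), "not present")
})

test_that("minus-strand extraction equals revcomp of the mirrored gene", {
  set.seed(21)
  for (rep in 1:5) {
    chr <- rand_dna_str(300)
    genome <- c(c1 = chr)
    s <- sample(50:120, 1)
    e <- s + 3 * sample(10:30, 1) - 1
    mp <- gene_models("g", "c1", "+", s, e, list(cbind(s, e)))
    mm <- gene_models("g", "c1", "-", s, e, list(cbind(s, e)))
    xp <- extract_gene_sequences(genome, mp, flank_bp = 20L,
                                 translate = FALSE)
    xm <- extract_gene_sequences(genome, mm, flank_bp = 20L,
                                 translate = FALSE)
    expect_identical(xm$cds, revcomp(xp$cds))
    expect_identical(xm$flank5, revcomp(xp$flank3))
    expect_identical(xm$flank3, revcomp(xp$flank5))
  }
})

test_that("translation follows the standard code with stop/N policies", {
  expect_identical(as.character(translate_cds("ATGGATTAA")), "MD")
  expect_identical(as.character(translate_cds("ATGNNNTAA")), "MX")
  t3 <- translate_cds("ATGTAAGAT")
  expect_identical(as.character(t3), "M*D")
  expect_true(attr(t3, "internal_stop"))
  expect_false(attr(translate_cds("ATGGATTAA"), "internal_stop"))
  expect_error(translate_cds("ATGA"), "divisible by 3")
})
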