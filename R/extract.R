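#' Extract per-gene sequences from a genome
#'
#' Derives the spliced CDS, its translation and the flanking noncoding
#' sequence of one gene, all in gene-strand (transcription) orientation: the
#' 3' flank starts immediately after the last exon in transcription
#' direction, so a retrogene's poly(A) tail appears as a run of `A`s at the
#' start of `flank3` regardless of genomic strand.
#'
#' @param genome Named character vector of chromosome sequences
#'   (see [parse_fasta()]).
#' @param model One row of a gene model table.
#' @param flank_bp Flank length to extract on each side (default 1000 bp);
#'   clipped at contig boundaries and flagged when clipped.
#' @param translate Whether to translate the CDS (requires length divisible
#'   by 3).
#' @return A list of class `gene_sequences` with elements `gene_id`, `cds`,
#'   `protein` (or `NA`), `flank5`, `flank3`, `clipped5`, `clipped3`,
#'   `intron_count`.
#' @export
extract_gene_sequences <- function(genome, model, flank_bp = 1000L,
                                   translate = TRUE) {
  stopifnot(flank_bp >= 0L, nrow(model) == 1L)
  chrom <- model$chrom
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " not present in genome", call. = FALSE)
  }
  chr <- genome[[chrom]]
  len <- nchar(chr)
  if (model$end > len) {
    stop("gene ", model$gene_id, " extends beyond contig ", chrom,
         " (length ", len, ")", call. = FALSE)
  }
  e <- model$exons[[1L]]
  cds <- paste(substring(chr, e[, 1L], e[, 2L]), collapse = "")
  up_start <- max(1L, model$start - flank_bp)
  up <- if (model$start > 1L) substr(chr, up_start, model$start - 1L) else ""
  dn_end <- min(len, model$end + flank_bp)
  dn <- if (model$end < len) substr(chr, model$end + 1L, dn_end) else ""
  clipped_up <- nchar(up) < flank_bp
  clipped_dn <- nchar(dn) < flank_bp
  if (model$strand == "-") {
    cds <- revcomp(cds)
    flank5 <- revcomp(dn); flank3 <- revcomp(up)
    clipped5 <- clipped_dn; clipped3 <- clipped_up
  } else {
    flank5 <- up; flank3 <- dn
    clipped5 <- clipped_up; clipped3 <- clipped_dn
  }
  prot <- if (translate && nchar(cds) %% 3L == 0L) translate_cds(cds) else NA
  structure(list(gene_id = model$gene_id, cds = cds, protein = prot,
                 flank5 = flank5, flank3 = flank3,
                 clipped5 = clipped5, clipped3 = clipped3,
                 intron_count = nrow(e) - 1L),
            class = "gene_sequences")
}

#' Extract sequences for every gene in a model table
#'
#' @inheritParams extract_gene_sequences
#' @param models A gene model table.
#' @return A named list of `gene_sequences`, one per gene.
#' @export
extract_all_genes <- function(genome, models, flank_bp = 1000L,
                              translate = TRUE) {
  out <- lapply(seq_len(nrow(models)), function(i) {
    extract_gene_sequences(genome, models[i, ], flank_bp, translate)
  })
  names(out) <- models$gene_id
  out
}
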