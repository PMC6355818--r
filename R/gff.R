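#' Gene model tables
#'
#' A gene model table is a `data.frame` with one row per gene and columns
#' `gene_id`, `chrom`, `strand` (`"+"`/`"-"`), `start`, `end` (1-based
#' inclusive), `source`, and a list column `exons` holding an n x 2 integer
#' matrix of exon `(start, end)` pairs sorted by coordinate. Coordinates are
#' GFF3 1-based inclusive throughout the package.
#'
#' @param gene_id,chrom,strand,start,end,source Vectors of per-gene fields.
#' @param exons List of n x 2 matrices of exon coordinates, one per gene.
#' @return A validated gene model `data.frame` sorted by `(chrom, start)`.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end, exons,
                        source = "famdup") {
  stopifnot(length(gene_id) == length(chrom),
            length(gene_id) == length(exons))
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   source = rep_len(as.character(source), length(gene_id)),
                   stringsAsFactors = FALSE)
  df$exons <- lapply(exons, function(e) {
    e <- matrix(as.integer(e), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    e[order(e[, 1L]), , drop = FALSE]
  })
  validate_gene_models(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_gene_models <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    g <- df[i, ]
    e <- df$exons[[i]]
    if (!g$strand %in% c("+", "-")) {
      stop("gene ", g$gene_id, ": unknown strand '", g$strand, "'",
           call. = FALSE)
    }
    if (g$start > g$end) {
      stop("gene ", g$gene_id, ": start > end", call. = FALSE)
    }
    if (nrow(e) < 1L) stop("gene ", g$gene_id, ": no exons", call. = FALSE)
    if (any(e[, 1L] > e[, 2L])) {
      stop("gene ", g$gene_id, ": exon with start > end", call. = FALSE)
    }
    if (any(e[, 1L] < g$start) || any(e[, 2L] > g$end)) {
      stop("gene ", g$gene_id, ": exon outside gene span", call. = FALSE)
    }
    if (nrow(e) > 1L && any(e[-1L, 1L] <= e[-nrow(e), 2L])) {
      stop("gene ", g$gene_id, ": overlapping exons", call. = FALSE)
    }
  }
  invisible(df)
}

#' Number of introns per gene model
#' @param models A gene model table (see [gene_models()]).
#' @return Named integer vector: exon count minus one, per gene.
#' @export
intron_count <- function(models) {
  n <- vapply(models$exons, nrow, integer(1L)) - 1L
  names(n) <- models$gene_id
  n
}

#' Parse gene models from a GFF3 file
#'
#' Collates `exon` features under their parent genes (via `mRNA` or direct
#' gene parentage). Genes lacking `exon` features fall back to `CDS`
#' features, then to the gene span as a single exon, so database dumps with
#' either dialect load identically.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @return A gene model table (see [gene_models()]), sorted by
#'   `(chrom, start)`.
#' @export
parse_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no features in ", path, call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) {
    stop("malformed GFF3 line(s) in ", path, call. = FALSE)
  }
  f <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(f) <- c("seqid", "source", "type", "start", "end", "score",
                "strand", "phase", "attributes")
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
           character(1L))
  }
  f$ID <- attr_field(f$attributes, "ID")
  f$Parent <- attr_field(f$attributes, "Parent")

  genes <- f[f$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path, call. = FALSE)
  if (any(is.na(genes$ID))) stop("gene feature without ID", call. = FALSE)
  # map every feature to its owning gene (child or grandchild)
  parent_of <- function(ids) {
    own <- ids %in% genes$ID
    out <- ifelse(own, ids, NA_character_)
    idx <- match(ids, f$ID)
    up <- f$Parent[idx]
    out[is.na(out)] <- ifelse(up[is.na(out)] %in% genes$ID, up[is.na(out)],
                              NA_character_)
    out
  }
  f$gene <- parent_of(f$Parent)

  exon_like <- function(gene_id, type) {
    e <- f[f$type == type & !is.na(f$gene) & f$gene == gene_id, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    cbind(e$start, e$end)
  }
  ex <- lapply(genes$ID, function(gid) {
    e <- exon_like(gid, "exon")
    if (is.null(e)) e <- exon_like(gid, "CDS")
    if (is.null(e)) {
      g <- genes[genes$ID == gid, ]
      e <- cbind(g$start, g$end)  # gene-span fallback
    }
    e
  })
  gene_models(genes$ID, genes$seqid, genes$strand, genes$start, genes$end,
              ex, source = genes$source)
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features with a `##gff-version 3` header,
#' UTF-8, LF line endings.
#'
#' @param models A gene model table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    e <- models$exons[[i]]
    rows <- c(
      paste(g$chrom, g$source, "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, g$source, "mRNA", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id), sep = "\t"),
      vapply(seq_len(nrow(e)), function(j) {
        paste(g$chrom, g$source, "exon", e[j, 1L], e[j, 2L], ".", g$strand,
              ".", paste0("ID=", g$gene_id, ".e", j, ";Parent=", g$gene_id,
                          ".t1"), sep = "\t")
      }, character(1L))
    )
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
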