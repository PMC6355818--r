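#' Configuration for the gene-family evolution simulator
#'
#' Defines the study conditions for a forward simulation that starts from a
#' single multi-exon ancestor gene and expands it by tandem, segmental and
#' retroduplication events with per-site substitution divergence, producing
#' a multi-chromosome genome, gene models and an event ground truth.
#'
#' Defaults plant 12 events, four per mechanism, on an 8-chromosome genome,
#' with a 3-exon ancestor (300/150/300 bp exons, 200 bp introns) so intron
#' presence is a clean binary character. Retro donors are drawn from
#' intron-bearing genes only, since a retrocopy of an already intronless
#' gene leaves no intron-loss signal to reconstruct. Dispersed insertions
#' (segmental, retro, the ancestor, decoys) land at well-separated sites so
#' that planted tandem arrays are the only physically clustered structures,
#' as in real genomes where dispersed duplicates land megabases away.
#'
#' @param seed Mandatory RNG seed; the whole run is deterministic given it.
#' @param n_chromosomes,chrom_len_bp Genome shape.
#' @param ancestor_exon_lengths,intron_lengths Ancestor gene structure
#'   (`length(intron_lengths) == length(ancestor_exon_lengths) - 1`).
#' @param n_events Number of duplication events.
#' @param event_counts Named counts (`tandem`, `segmental`, `retro`) summing
#'   to `n_events`; the event order is shuffled. Set to `NULL` to sample
#'   types i.i.d. from `event_type_probs` instead.
#' @param event_type_probs Probabilities (tandem, segmental, retro) summing
#'   to 1; only used when `event_counts` is `NULL`.
#' @param subs_rate Per-site substitution probability applied to every
#'   gene's exons and introns after each event step.
#' @param polyA_len,tsd_len Poly(A)-tail and target-site-duplication lengths
#'   attached to retro insertions.
#' @param flank_erosion_rate Per-site substitution probability applied to
#'   promoters, poly(A) tails and TSDs each step (0 = pristine flanks).
#' @param independent_intron_loss_prob Per-gene, per-step probability that a
#'   multi-exon gene loses its introns without retroduplication (a
#'   homoplasy stressor; 0 by default).
#' @param promoter_len Promoter length carved immediately upstream of each
#'   gene.
#' @param promoter_elements Named counts of dictionary elements
#'   ([cis_element_table()]) planted in the ancestor promoter (copied by
#'   tandem/segmental duplication; retro insertions get a fresh unplanted
#'   promoter region, mirroring the loss of regulatory sequence).
#' @param n_decoy_genes Unrelated single-exon genes added to the annotation
#'   so family harvesting has true negatives.
#' @param tandem_gap_bp Range (min, max) of intergenic gap between tandem
#'   neighbours.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 8L,
                       chrom_len_bp = 1500000L,
                       ancestor_exon_lengths = c(300L, 150L, 300L),
                       intron_lengths = c(200L, 200L),
                       n_events = 12L,
                       event_counts = c(tandem = 4L, segmental = 4L, retro = 4L),
                       event_type_probs = NULL,
                       subs_rate = 0.01,
                       polyA_len = 15L,
                       tsd_len = 12L,
                       flank_erosion_rate = 0,
                       independent_intron_loss_prob = 0,
                       promoter_len = 2000L,
                       promoter_elements = c("G-box" = 1L, "TCT-motif" = 2L,
                                             "LTR" = 1L, "Sp1" = 1L),
                       n_decoy_genes = 6L,
                       tandem_gap_bp = c(3000L, 15000L)) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  stopifnot(length(ancestor_exon_lengths) >= 1L,
            length(intron_lengths) == length(ancestor_exon_lengths) - 1L,
            sum(ancestor_exon_lengths) %% 3L == 0L,
            subs_rate >= 0, subs_rate <= 1,
            flank_erosion_rate >= 0, flank_erosion_rate <= 1,
            independent_intron_loss_prob >= 0,
            independent_intron_loss_prob <= 1,
            polyA_len >= 0L, tsd_len >= 0L, n_events >= 0L)
  if (!is.null(event_counts)) {
    stopifnot(setequal(names(event_counts),
                       c("tandem", "segmental", "retro")),
              sum(event_counts) == n_events)
  } else {
    stopifnot(!is.null(event_type_probs), length(event_type_probs) == 3L,
              all(event_type_probs >= 0),
              abs(sum(event_type_probs) - 1) < 1e-9)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Random coding sequence: ATG + random sense codons + TAA.
random_cds <- function(len_bp) {
  stopifnot(len_bp %% 3L == 0L, len_bp >= 6L)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  body <- sample(sense, len_bp / 3L - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Random unrelated protein sequences
#'
#' Uniform i.i.d. amino-acid strings, used as true negatives when
#' benchmarking family harvesting.
#'
#' @param n Number of proteins.
#' @param len Length of each (residues).
#' @param prefix Id prefix.
#' @return Named character vector.
#' @export
random_proteins <- function(n, len = 250L, prefix = "rnd") {
  aa <- setdiff(AA_ALPHABET, c("X", "*"))
  out <- vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1L))
  names(out) <- sprintf("%s_%03d", prefix, seq_len(n))
  out
}

#' Substitute bases at a fixed per-site rate
#'
#' Each site is substituted independently with probability `rate`; the
#' replacement is uniform over the three alternative bases, so a hit always
#' changes the base. Non-ACGT characters are left untouched. Length is
#' preserved.
#'
#' @param seq DNA string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @return Mutated DNA string.
#' @export
mutate_seq <- function(seq, rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  n <- nchar(seq)
  if (n == 0L || rate == 0) return(seq)
  ch <- str_chars(seq)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    cur <- match(ch[hit], bases)
    real <- !is.na(cur)
    if (any(real)) {
      shift <- sample.int(3L, sum(real), replace = TRUE)
      ch[hit[real]] <- bases[(cur[real] - 1L + shift) %% 4L + 1L]
    }
  }
  paste(ch, collapse = "")
}

# Promoter background with dictionary elements planted at random
# non-overlapping positions.
make_promoter <- function(len, elements_to_plant, dictionary) {
  seq <- random_dna(len)
  if (length(elements_to_plant) == 0) return(seq)
  occupied <- matrix(numeric(0), ncol = 2L)
  for (nm in names(elements_to_plant)) {
    el <- dictionary[[nm]]
    if (is.null(el)) stop("unknown promoter element: ", nm, call. = FALSE)
    for (k in seq_len(elements_to_plant[[nm]])) {
      pat <- el$patterns[sample.int(length(el$patterns), 1L)]
      w <- nchar(pat)
      for (try in 1:100) {
        pos <- sample.int(len - w + 1L, 1L)
        clash <- nrow(occupied) > 0 &&
          any(pos <= occupied[, 2L] & pos + w - 1L >= occupied[, 1L])
        if (!clash) break
      }
      substr(seq, pos, pos + w - 1L) <- pat
      occupied <- rbind(occupied, c(pos, pos + w - 1L))
    }
  }
  seq
}

#' Simulate the evolution of a gene family
#'
#' Starts from one multi-exon ancestor and applies `n_events` duplication
#' events. Tandem events insert a full genomic copy (introns and promoter
#' retained) a few kb from the donor; segmental events insert a full copy at
#' a distant site on a different chromosome; retro events insert the
#' donor's spliced CDS (intronless) with a poly(A) tail appended and a
#' target-site duplication bracketing the insertion, at a random distant
#' site on a random chromosome, on a random strand. After each event every
#' gene's exons and introns are mutated at `subs_rate` per site.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `genome` (named chromosome
#'   sequences), `models` (gene model table, family plus decoys), `truth`
#'   (event table: `event_id`, `step`, `type`, `donor_gene_id`,
#'   `new_gene_id`, `chrom`, `insertion_pos`), `genes` (per-gene table with
#'   `origin` and `parent`), `proteins` (current family protein sequences),
#'   `query_id` (the ancestor gene), and `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dict <- load_element_table()

  # dispersed-insertion sites: well separated within and between sites
  site_centers <- seq(250000L, config$chrom_len_bp - 250000L, by = 450000L)
  sites <- expand.grid(chrom = seq_len(config$n_chromosomes),
                       center = site_centers)
  sites <- sites[order(sites$chrom, sites$center), ]
  sites$used <- FALSE
  take_site <- function(exclude_chrom = NULL) {
    free <- which(!sites$used)
    if (!is.null(exclude_chrom)) {
      free <- free[sites$chrom[free] != exclude_chrom]
    }
    if (length(free) == 0) {
      stop("no free insertion site left; enlarge the genome", call. = FALSE)
    }
    s <- free[sample.int(length(free), 1L)]
    sites$used[s] <<- TRUE
    s
  }

  genes <- list()
  new_gene <- function(id, site, pos_key, strand, exons, introns, promoter,
                       up_extra, down_extra, origin, parent, step) {
    list(id = id, site = site, chrom = sites$chrom[site], pos_key = pos_key,
         strand = strand, exons = exons, introns = introns,
         promoter = promoter, up_extra = up_extra, down_extra = down_extra,
         origin = origin, parent = parent, step = step)
  }

  # ancestor
  anc_cds <- random_cds(sum(config$ancestor_exon_lengths))
  splits <- cumsum(config$ancestor_exon_lengths)
  exons <- mapply(function(a, b) substr(anc_cds, a, b),
                  c(1L, utils::head(splits, -1L) + 1L), splits,
                  SIMPLIFY = FALSE)
  introns <- lapply(config$intron_lengths, random_dna)
  anc_prom <- make_promoter(config$promoter_len, config$promoter_elements,
                            dict)
  genes[["fam001"]] <- new_gene("fam001", take_site(), 0, "+", exons,
                               introns, anc_prom, "", "", "ancestor", NA,
                               0L)

  # decoys: unrelated intronless genes
  for (k in seq_len(config$n_decoy_genes)) {
    len <- sample(seq.int(150L, 300L), 1L) * 3L
    id <- sprintf("dec%03d", k)
    genes[[id]] <- new_gene(id, take_site(), 0, sample(c("+", "-"), 1L),
                            list(random_cds(len)), list(),
                            random_dna(config$promoter_len), "", "",
                            "decoy", NA, 0L)
  }

  # event schedule
  types <- if (!is.null(config$event_counts)) {
    sample(rep(names(config$event_counts), config$event_counts))
  } else if (config$n_events > 0) {
    sample(c("tandem", "segmental", "retro"), config$n_events,
           replace = TRUE, prob = config$event_type_probs)
  } else character(0)

  family_ids <- function() {
    names(genes)[vapply(genes, function(g) g$origin != "decoy", logical(1L))]
  }
  truth <- list()
  n_fam <- 1L
  for (step in seq_along(types)) {
    type <- types[step]
    fam <- family_ids()
    pool <- if (type == "retro") {
      fam[vapply(genes[fam], function(g) length(g$exons) > 1L, logical(1L))]
    } else fam
    if (length(pool) == 0) {
      stop("no eligible donor for a ", type, " event at step ", step,
           call. = FALSE)
    }
    donor_id <- pool[sample.int(length(pool), 1L)]
    donor <- genes[[donor_id]]
    n_fam <- n_fam + 1L
    id <- sprintf("fam%03d", n_fam)
    if (type == "tandem") {
      g <- new_gene(id, donor$site, donor$pos_key + stats::runif(1L),
                    donor$strand, donor$exons, donor$introns,
                    donor$promoter, donor$up_extra, donor$down_extra,
                    "tandem", donor_id, step)
    } else if (type == "segmental") {
      g <- new_gene(id, take_site(exclude_chrom = donor$chrom), 0,
                    donor$strand, donor$exons, donor$introns,
                    donor$promoter, donor$up_extra, donor$down_extra,
                    "segmental", donor_id, step)
    } else {
      cds <- paste(unlist(donor$exons), collapse = "")
      tsd <- random_dna(config$tsd_len)
      g <- new_gene(id, take_site(), 0, sample(c("+", "-"), 1L),
                    list(cds), list(),
                    random_dna(config$promoter_len),
                    tsd,
                    paste0(strrep("A", config$polyA_len), tsd),
                    "retro", donor_id, step)
    }
    genes[[id]] <- g
    truth[[step]] <- data.frame(event_id = sprintf("ev%02d", step),
                                step = step, type = type,
                                donor_gene_id = donor_id, new_gene_id = id,
                                stringsAsFactors = FALSE)
    # divergence: every family gene evolves after the event
    for (gid in family_ids()) {
      genes[[gid]]$exons <- lapply(genes[[gid]]$exons, mutate_seq,
                                   rate = config$subs_rate)
      genes[[gid]]$introns <- lapply(genes[[gid]]$introns, mutate_seq,
                                     rate = config$subs_rate)
      if (config$flank_erosion_rate > 0) {
        genes[[gid]]$promoter <- mutate_seq(genes[[gid]]$promoter,
                                            config$flank_erosion_rate)
        genes[[gid]]$up_extra <- mutate_seq(genes[[gid]]$up_extra,
                                            config$flank_erosion_rate)
        genes[[gid]]$down_extra <- mutate_seq(genes[[gid]]$down_extra,
                                              config$flank_erosion_rate)
      }
      if (config$independent_intron_loss_prob > 0 &&
          length(genes[[gid]]$exons) > 1L &&
          stats::runif(1L) < config$independent_intron_loss_prob) {
        genes[[gid]]$exons <- list(paste(unlist(genes[[gid]]$exons),
                                         collapse = ""))
        genes[[gid]]$introns <- list()
      }
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(event_id = character(0), step = integer(0),
               type = character(0), donor_gene_id = character(0),
               new_gene_id = character(0), stringsAsFactors = FALSE)

  assemble_genome(genes, sites, truth, config)
}

# Lay the gene cassettes onto chromosomes and build the final dataset.
assemble_genome <- function(genes, sites, truth, config) {
  ord <- order(vapply(genes, `[[`, integer(1L), "site") * 1e6 +
               vapply(genes, `[[`, numeric(1L), "pos_key"))
  genes <- genes[ord]
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  pieces <- rep(list(list()), config$n_chromosomes)
  cursor <- rep(1L, config$n_chromosomes)
  rows <- list()
  for (g in genes) {
    body <- character(0)
    bounds <- matrix(0L, nrow = length(g$exons), ncol = 2L)
    off <- 0L
    for (k in seq_along(g$exons)) {
      bounds[k, ] <- c(off + 1L, off + nchar(g$exons[[k]]))
      body <- c(body, g$exons[[k]])
      off <- off + nchar(g$exons[[k]])
      if (k <= length(g$introns)) {
        body <- c(body, g$introns[[k]])
        off <- off + nchar(g$introns[[k]])
      }
    }
    body <- paste(body, collapse = "")
    cassette <- paste0(g$promoter, g$up_extra, body, g$down_extra)
    lead <- nchar(g$promoter) + nchar(g$up_extra)
    if (g$strand == "-") {
      cassette <- revcomp(cassette)
      lc <- nchar(cassette)
      b2 <- cbind(lc - (lead + bounds[, 2L]) + 1L,
                  lc - (lead + bounds[, 1L]) + 1L)
      bounds <- b2[rev(seq_len(nrow(b2))), , drop = FALSE]
    } else {
      bounds <- bounds + lead
    }
    ci <- g$chrom
    site_start <- sites$center[g$site]
    start_at <- if (cursor[ci] <= site_start) {
      site_start
    } else {
      # subsequent gene at the same site: tandem gap after the previous one
      cursor[ci] + sample(seq(config$tandem_gap_bp[1L],
                              config$tandem_gap_bp[2L]), 1L)
    }
    if (start_at + nchar(cassette) > config$chrom_len_bp) {
      stop("chromosome ", ci, " is full; enlarge chrom_len_bp",
           call. = FALSE)
    }
    gap <- start_at - cursor[ci]
    pieces[[ci]][[length(pieces[[ci]]) + 1L]] <- random_dna(gap)
    pieces[[ci]][[length(pieces[[ci]]) + 1L]] <- cassette
    rows[[g$id]] <- data.frame(  # cassette base 1 sits at genome position start_at
      gene_id = g$id, chrom = chrom_names[ci], strand = g$strand,
      start = start_at - 1L + min(bounds), end = start_at - 1L + max(bounds),
      exon_start = I(list(start_at - 1L + bounds[, 1L])),
      exon_end = I(list(start_at - 1L + bounds[, 2L])),
      origin = g$origin, parent = ifelse(is.na(g$parent), "", g$parent),
      step = g$step, n_exons = length(g$exons), stringsAsFactors = FALSE)
    cursor[ci] <- start_at + nchar(cassette)
  }
  genome <- vapply(seq_len(config$n_chromosomes), function(ci) {
    tail_len <- config$chrom_len_bp - cursor[ci] + 1L
    paste(c(unlist(pieces[[ci]]), random_dna(tail_len)), collapse = "")
  }, character(1L))
  names(genome) <- chrom_names

  info <- do.call(rbind, rows)
  rownames(info) <- NULL
  models <- gene_models(info$gene_id, info$chrom, info$strand, info$start,
                        info$end,
                        mapply(function(s, e) cbind(s, e), info$exon_start,
                               info$exon_end, SIMPLIFY = FALSE),
                        source = "famdup-sim")
  fam <- info$gene_id[info$origin != "decoy"]
  proteins <- vapply(genes[fam], function(g) {
    translate_cds(paste(unlist(g$exons), collapse = ""))
  }, character(1L))
  names(proteins) <- fam
  if (nrow(truth) > 0) {
    truth$chrom <- info$chrom[match(truth$new_gene_id, info$gene_id)]
    truth$insertion_pos <- info$start[match(truth$new_gene_id,
                                            info$gene_id)]
  }
  structure(list(genome = genome, models = models, truth = truth,
                 genes = info[, c("gene_id", "chrom", "strand", "start",
                                  "end", "origin", "parent", "step",
                                  "n_exons")],
                 proteins = proteins, query_id = "fam001", config = config),
            class = "sim_dataset")
}

#' Write and read the simulator's event ground truth
#'
#' @param dataset A `sim_dataset` (or its `truth` data.frame).
#' @param path TSV path.
#' @return `path` invisibly; [read_truth()] returns the truth data.frame.
#' @export
write_truth <- function(dataset, path) {
  truth <- if (inherits(dataset, "sim_dataset")) dataset$truth else dataset
  cols <- c("event_id", "step", "type", "donor_gene_id", "new_gene_id",
            "chrom", "insertion_pos")
  cols <- intersect(cols, names(truth))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  if (nrow(truth) > 0) {
    lines <- do.call(paste, c(unname(truth[cols]), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build the flanks of one synthetic retro insertion
#'
#' A unit-level generator for benchmarking the poly(A) and direct-repeat
#' scanners in isolation: the 3' flank starts with a poly(A) tail followed
#' by the target-site duplication, and the 5' flank ends with the same
#' duplication, exactly as a fresh retro insertion leaves them.
#'
#' @param polyA_len,tsd_len Tail and TSD lengths.
#' @param flank_len Total flank length on each side.
#' @param erosion Per-site substitution rate applied to both flanks after
#'   construction (0 = pristine).
#' @return A list with `flank5`, `flank3`, `tsd`, `polyA_offset` (0-based
#'   offset of the tail in `flank3`), `tsd_offset3` (0-based offset of the
#'   TSD in `flank3`).
#' @export
sim_retro_flanks <- function(polyA_len = 15L, tsd_len = 12L,
                             flank_len = 1000L, erosion = 0) {
  tsd <- random_dna(tsd_len)
  flank5 <- paste0(random_dna(flank_len - tsd_len), tsd)
  flank3 <- paste0(strrep("A", polyA_len), tsd,
                   random_dna(flank_len - polyA_len - tsd_len))
  if (erosion > 0) {
    flank5 <- mutate_seq(flank5, erosion)
    flank3 <- mutate_seq(flank3, erosion)
  }
  list(flank5 = flank5, flank3 = flank3, tsd = tsd,
       polyA_offset = 0L, tsd_offset3 = polyA_len)
}
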