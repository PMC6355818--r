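#' Pipeline configuration
#'
#' Exactly one input source must be given: a simulation block
#' ([sim_config()]) or real inputs (genome FASTA + GFF3 + query protein
#' FASTA). Stage thresholds default to the values used throughout the
#' package: harvest at E < 1e-10; tandem chaining at 250 kb / 5 intervening
#' genes with sisterhood 0.5; segmental calls at identity > 80% and
#' E < 1e-10; poly(A) and TSD scans at their documented defaults.
#'
#' @param simulate A [sim_config()] or `NULL`.
#' @param genome_fasta,gff3,query_fasta Paths to real inputs (or `NULL`).
#' @param out_dir Output directory (created); `NULL` keeps everything in
#'   memory.
#' @param anchors Optional leaf ids delimiting the analysed clade (the
#'   smallest clade containing all anchors); default: every harvested gene.
#' @param max_evalue Family-harvest E-value cutoff.
#' @param flank_bp Flank length for retro scans.
#' @param promoter_len Promoter length for element scanning.
#' @param max_gap_bp,max_intervening_genes,sisterhood_min Tandem-cluster
#'   parameters.
#' @param min_identity,seg_max_evalue Segmental-pair thresholds.
#' @param polyA,tsd Parameter lists forwarded to [detect_polyA()] /
#'   [detect_direct_repeats()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, genome_fasta = NULL,
                            gff3 = NULL, query_fasta = NULL,
                            out_dir = NULL, anchors = NULL,
                            max_evalue = 1e-10, flank_bp = 1000L,
                            promoter_len = 2000L,
                            max_gap_bp = 250000L,
                            max_intervening_genes = 5L,
                            sisterhood_min = 0.5,
                            min_identity = 80, seg_max_evalue = 1e-10,
                            polyA = list(), tsd = list()) {
  have_sim <- !is.null(simulate)
  have_real <- !is.null(genome_fasta) || !is.null(gff3) ||
    !is.null(query_fasta)
  if (have_sim == have_real) {
    stop("give exactly one of: a simulate block, or real input paths",
         call. = FALSE)
  }
  if (have_real &&
      (is.null(genome_fasta) || is.null(gff3) || is.null(query_fasta))) {
    stop("real inputs need genome_fasta, gff3 and query_fasta",
         call. = FALSE)
  }
  if (have_sim) stopifnot(inherits(simulate, "sim_config"))
  structure(as.list(environment())[c("simulate", "genome_fasta", "gff3",
                                     "query_fasta", "out_dir", "anchors",
                                     "max_evalue", "flank_bp",
                                     "promoter_len", "max_gap_bp",
                                     "max_intervening_genes",
                                     "sisterhood_min", "min_identity",
                                     "seg_max_evalue", "polyA", "tsd")],
            class = "pipeline_config")
}

#' Run the duplication-mode inference pipeline end to end
#'
#' Stages, in fixed order: obtain inputs (simulate or load), extract and
#' translate gene sequences, harvest the family by similarity to the query,
#' build the Poisson-corrected neighbor-joining tree and midpoint-root it,
#' reconstruct intron loss (Dollo) and map retro events, scan flanks for
#' poly(A)/TSD, chain tandem clusters, call segmental pairs, assign
#' per-gene modes, and scan promoters. Progress is logged to standard
#' error; results never are. Given the same config (and simulation seed)
#' the report and every persisted artifact are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `analysis_report`; see Details. When
#'   `config$out_dir` is set, TSV/Newick/JSON artifacts are also written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(stage, ...) {
    message("[famdup:", stage, "] ", ...)
  }
  # pre-flight: fail before any stage output
  if (is.null(config$simulate)) {
    for (p in c(config$genome_fasta, config$gff3, config$query_fasta)) {
      if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
    }
  }

  if (!is.null(config$simulate)) {
    log_msg("simulate", "seed ", config$simulate$seed)
    dataset <- simulate_family(config$simulate)
    genome <- dataset$genome
    models <- dataset$models
    query_id <- dataset$query_id
  } else {
    log_msg("load", config$genome_fasta)
    dataset <- NULL
    genome <- parse_fasta(config$genome_fasta)
    models <- parse_gff3(config$gff3)
    q <- parse_fasta(config$query_fasta)
    query_id <- names(q)[1L]
  }

  log_msg("extract", nrow(models), " gene models")
  seqs <- extract_all_genes(genome, models,
                            flank_bp = max(config$flank_bp,
                                           config$promoter_len))
  proteins <- vapply(seqs, function(s) {
    if (is.character(s$protein)) as.character(s$protein) else NA_character_
  }, character(1L))
  proteins <- proteins[!is.na(proteins)]

  if (!is.null(config$simulate)) {
    query <- proteins[query_id]
  } else {
    query <- parse_fasta(config$query_fasta)[1L]
  }

  log_msg("harvest", "query ", query_id, " vs ", length(proteins),
          " proteins")
  hits <- find_family(query, proteins, max_evalue = config$max_evalue)
  family <- sort(unique(hits$sseqid))
  if (length(family) < 3L) {
    stop("stage harvest: fewer than 3 family members found", call. = FALSE)
  }

  log_msg("tree", length(family), " family members")
  D <- family_distances(proteins[family])
  tree <- midpoint_root(nj_tree(D))

  group <- if (!is.null(config$anchors)) {
    clade_with_anchors(tree, config$anchors)
  } else family

  log_msg("retro", "Dollo reconstruction")
  fam_models <- models[models$gene_id %in% group, , drop = FALSE]
  states <- as.integer(intron_count(fam_models) > 0L)
  names(states) <- fam_models$gene_id
  # Dollo runs on the subtree spanned by the analysed group
  gtree <- if (length(group) < length(tree$tip.label)) {
    ape::keep.tip(tree, group)
  } else tree
  inference <- dollo_reconstruct(gtree, states)
  retro_events <- infer_retro_events(inference)
  retro_genes <- retro_flagged_genes(retro_events)

  log_msg("flank-scan", "poly(A) and direct repeats")
  retro_tab <- do.call(rbind, lapply(group, function(g) {
    s <- seqs[[g]]
    f3 <- substr(s$flank3, 1L, config$flank_bp)
    f5 <- substr(s$flank5, max(1L, nchar(s$flank5) - config$flank_bp + 1L),
                 nchar(s$flank5))
    pa <- suppressWarnings(do.call(detect_polyA,
                                   c(list(flank3 = f3), config$polyA)))
    dr <- do.call(detect_direct_repeats,
                  c(list(flank5 = f5, flank3 = f3), config$tsd))
    data.frame(gene_id = g, intron_count = s$intron_count,
               retro_flag = g %in% retro_genes,
               polyA_offset = if (is.null(pa)) NA_integer_ else pa$offset_bp,
               polyA_fraction = if (is.null(pa)) NA_real_ else pa$A_fraction,
               tsd_len = if (nrow(dr) == 0) NA_integer_ else dr$length[1L],
               tsd_mismatch = if (nrow(dr) == 0) NA_integer_ else
                 dr$mismatches[1L],
               stringsAsFactors = FALSE)
  }))

  log_msg("tandem", "chaining clusters")
  clusters <- detect_tandem_clusters(
    fam_models, gtree, max_gap_bp = config$max_gap_bp,
    max_intervening_genes = config$max_intervening_genes,
    all_models = models, sisterhood_min = config$sisterhood_min,
    ignore_leaves = retro_genes)

  log_msg("segmental", "all-vs-all CDS comparison")
  pairs <- detect_segmental_pairs(
    seqs[group], models, clusters,
    min_identity = config$min_identity,
    max_evalue = config$seg_max_evalue)

  calls <- assign_modes(sort(group), clusters, pairs, retro_genes)
  m <- match(calls$gene_id, models$gene_id)
  calls$chrom <- models$chrom[m]
  calls$start <- models$start[m]
  calls$end <- models$end[m]

  log_msg("promoter", "element scan")
  dict <- load_element_table()
  template <- stats::setNames(integer(length(dict)),
                              vapply(dict, `[[`, character(1L), "name"))
  prom_counts <- t(vapply(group, function(g) {
    f5 <- seqs[[g]]$flank5
    prom <- substr(f5, max(1L, nchar(f5) - config$promoter_len + 1L),
                   nchar(f5))
    if (!nzchar(prom)) return(template)
    scan_promoter(prom, dict)$counts
  }, template))

  report <- structure(list(
    family_table = hits, family = family, group = sort(group),
    tree = tree, newick = ape::write.tree(tree),
    clusters = clusters, segmental_pairs = pairs,
    retro = list(inference = inference, events = retro_events,
                 table = retro_tab),
    calls = calls, promoter_counts = prom_counts,
    query_id = query_id, config = config,
    truth = if (!is.null(dataset)) dataset$truth else NULL),
    class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    cells <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) sprintf("%.10g", col)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cells, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

# Persist the report deterministically (no timestamps, LF endings).
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_tsv(report$family_table, fp("family.tsv"))
  con <- file(fp("tree.nwk"), open = "wb")
  writeLines(report$newick, con, sep = "\n")
  close(con)
  cl <- do.call(rbind, lapply(report$clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, chrom = cl$chrom,
               members = paste(cl$members, collapse = ","),
               sisterhood_fraction = cl$sisterhood_fraction,
               tandem_origin = cl$tandem_origin, stringsAsFactors = FALSE)
  }))
  if (is.null(cl)) {
    cl <- data.frame(cluster_id = character(0), chrom = character(0),
                     members = character(0),
                     sisterhood_fraction = numeric(0),
                     tandem_origin = logical(0))
  }
  write_tsv(cl, fp("clusters.tsv"))
  write_cluster_bed(report$clusters, report$calls, fp("clusters.bed"))
  write_tsv(report$segmental_pairs, fp("segmental_pairs.tsv"))
  write_tsv(report$retro$table, fp("retro_report.tsv"))
  con <- file(fp("retro_tree.nwk"), open = "wb")
  writeLines(annotate_retro_tree(report$retro$inference), con, sep = "\n")
  close(con)
  write_tsv(report$calls, fp("calls.tsv"))
  pc <- data.frame(gene_id = rownames(report$promoter_counts),
                   report$promoter_counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(pc, fp("promoter_counts.tsv"))
  summary <- list(
    query = report$query_id,
    n_family = length(report$family),
    n_clusters = length(report$clusters),
    n_tandem_origin = sum(vapply(report$clusters, `[[`, logical(1L),
                                 "tandem_origin")),
    n_segmental_pairs = nrow(report$segmental_pairs),
    n_retro_events = length(report$retro$events),
    modes = as.list(table(report$calls$primary_mode)),
    seed = if (!is.null(report$config$simulate))
      report$config$simulate$seed else NA)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  con <- file(fp("report.json"), open = "wb")
  writeLines(json, con, sep = "\n")
  close(con)
  # config echo: sufficient to reproduce the run exactly (the output
  # location is not part of the run's identity)
  cfg <- lapply(unclass(report$config), function(x) {
    if (inherits(x, "sim_config")) unclass(x) else x
  })
  cfg$out_dir <- NULL
  con <- file(fp("config_echo.yaml"), open = "wb")
  writeLines(yaml::as.yaml(cfg), con, sep = "\n")
  close(con)
  invisible(out_dir)
}

# Recompute the reciprocal-best flag on a subset of a pair table.
reciprocal_best_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  ids <- unique(c(pairs$gene_a, pairs$gene_b))
  best <- vapply(ids, function(g) {
    sub <- pairs[pairs$gene_a == g | pairs$gene_b == g, , drop = FALSE]
    sub <- sub[order(-sub$identity_pct,
                     ifelse(sub$gene_a == g, sub$gene_b, sub$gene_a)), ,
               drop = FALSE]
    ifelse(sub$gene_a[1L] == g, sub$gene_b[1L], sub$gene_a[1L])
  }, character(1L))
  pairs[best[pairs$gene_a] == pairs$gene_b &
          best[pairs$gene_b] == pairs$gene_a, , drop = FALSE]
}

#' Score pipeline calls against simulator ground truth
#'
#' Evaluation is event-based, matching how each mechanism is evidenced:
#' a tandem event is recovered when donor and copy share a tandem-origin
#' cluster (cluster precision asks that a cluster's member set equal one
#' truth tandem-connected component); a segmental event is recovered when
#' its pair passes the segmental thresholds (precision is measured over
#' reciprocal-best pairs, the analogue of keeping the highest-identity
#' partner); a retro event is recovered when some inferred loss edge
#' subtends exactly the planted retrocopy and its later copy-descendants
#' (precision over loss edges). A per-gene confusion matrix (primary mode
#' vs the event type that created each gene) is reported alongside.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param truth Truth event table (from the dataset or [read_truth()]).
#' @return A list: `per_mode` data.frame (`mode`, `n_truth`, `n_pred`,
#'   `recall`, `precision`), `confusion` table, `macro` averages.
#' @export
compare_to_truth <- function(report, truth) {
  stopifnot(inherits(report, "analysis_report"))
  calls <- report$calls
  orphans <- setdiff(truth$new_gene_id, calls$gene_id)
  if (length(orphans) > 0) {
    stop("truth genes absent from report calls: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  truth <- truth[order(truth$step), , drop = FALSE]

  # copy-descendant sets per retro event (the retrocopy plus every later
  # gene whose creation chain passes through it)
  retro_truth_sets <- list()
  for (k in which(truth$type == "retro")) {
    set <- truth$new_gene_id[k]
    later <- truth[truth$step > truth$step[k], , drop = FALSE]
    for (j in seq_len(nrow(later))) {
      if (later$donor_gene_id[j] %in% set) {
        set <- c(set, later$new_gene_id[j])
      }
    }
    retro_truth_sets[[truth$event_id[k]]] <- sort(set)
  }
  pred_retro_sets <- lapply(report$retro$events,
                            function(e) sort(e$leaves))
  retro_rec <- vapply(retro_truth_sets, function(s) {
    any(vapply(pred_retro_sets, identical, logical(1L), s))
  }, logical(1L))
  retro_prec <- vapply(pred_retro_sets, function(s) {
    any(vapply(retro_truth_sets, identical, logical(1L), s))
  }, logical(1L))

  # tandem components: union-find over truth tandem edges
  tandem_events <- truth[truth$type == "tandem", , drop = FALSE]
  parent <- stats::setNames(calls$gene_id, calls$gene_id)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (j in seq_len(nrow(tandem_events))) {
    a <- find(tandem_events$donor_gene_id[j])
    b <- find(tandem_events$new_gene_id[j])
    if (a != b) parent[[a]] <- b
  }
  comp <- split(calls$gene_id, vapply(calls$gene_id, find, character(1L)))
  comp <- lapply(comp[lengths(comp) >= 2L], sort)
  pred_clusters <- lapply(Filter(function(cl) isTRUE(cl$tandem_origin),
                                 report$clusters),
                          function(cl) sort(cl$members))
  in_same_cluster <- function(a, b) {
    any(vapply(pred_clusters, function(m) a %in% m && b %in% m,
               logical(1L)))
  }
  tandem_rec <- if (nrow(tandem_events) > 0) {
    vapply(seq_len(nrow(tandem_events)), function(j) {
      in_same_cluster(tandem_events$donor_gene_id[j],
                      tandem_events$new_gene_id[j])
    }, logical(1L))
  } else logical(0)
  tandem_prec <- vapply(pred_clusters, function(m) {
    any(vapply(comp, identical, logical(1L), m))
  }, logical(1L))

  # segmental: recovery by threshold passage, precision over
  # reciprocal-best pairs
  seg_events <- truth[truth$type == "segmental", , drop = FALSE]
  pairs <- report$segmental_pairs
  has_pair <- function(a, b) {
    any(pairs$gene_a == min(a, b) & pairs$gene_b == max(a, b))
  }
  seg_rec <- if (nrow(seg_events) > 0) {
    vapply(seq_len(nrow(seg_events)), function(j) {
      has_pair(seg_events$donor_gene_id[j], seg_events$new_gene_id[j])
    }, logical(1L))
  } else logical(0)
  # segmental event calls: reciprocal-best pairs among genes whose
  # relationship is not already explained by a retro signature
  # (precedence retro > segmental, applied at the event level)
  retro_flagged <- calls$gene_id[calls$retro_signature]
  cand <- pairs[!(pairs$gene_a %in% retro_flagged) &
                  !(pairs$gene_b %in% retro_flagged), , drop = FALSE]
  rb <- reciprocal_best_pairs(cand)
  # a called pair is segmentally related when the unique genealogy path
  # between the two genes crosses a segmental event and no retro event
  parent_of <- stats::setNames(truth$donor_gene_id, truth$new_gene_id)
  type_of <- stats::setNames(truth$type, truth$new_gene_id)
  lineage <- function(g) {
    path <- character(0)
    while (g %in% names(parent_of)) { path <- c(path, g); g <- parent_of[[g]] }
    c(path, g)
  }
  seg_related <- function(a, b) {
    la <- lineage(a); lb <- lineage(b)
    common <- intersect(la, lb)
    if (length(common) == 0) return(FALSE)
    anc <- common[1L]
    steps <- c(la[seq_len(match(anc, la) - 1L)],
               lb[seq_len(match(anc, lb) - 1L)])
    types <- type_of[steps]
    any(types == "segmental") && !any(types == "retro")
  }
  seg_prec <- if (nrow(rb) > 0) {
    vapply(seq_len(nrow(rb)), function(j) {
      seg_related(rb$gene_a[j], rb$gene_b[j])
    }, logical(1L))
  } else logical(0)

  rate <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  per_mode <- data.frame(
    mode = c("tandem", "segmental", "retro"),
    n_truth = c(nrow(tandem_events), nrow(seg_events),
                length(retro_truth_sets)),
    n_pred = c(length(pred_clusters), nrow(rb), length(pred_retro_sets)),
    recall = c(rate(tandem_rec), rate(seg_rec), rate(retro_rec)),
    precision = c(rate(tandem_prec), rate(seg_prec), rate(retro_prec)),
    stringsAsFactors = FALSE)

  truth_mode <- stats::setNames(truth$type, truth$new_gene_id)
  gene_truth <- ifelse(calls$gene_id %in% names(truth_mode),
                       truth_mode[calls$gene_id], "unclassified")
  confusion <- table(truth = gene_truth, called = calls$primary_mode)

  list(per_mode = per_mode, confusion = confusion,
       macro = c(recall = mean(per_mode$recall, na.rm = TRUE),
                 precision = mean(per_mode$precision, na.rm = TRUE)))
}
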