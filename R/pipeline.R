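#' Run the full integration cascade
#'
#' Executes every stage end-to-end from the input files named in
#' `config$paths` and persists each stage's output as a tab-separated table
#' (one directory per run), so any stage can be re-run from intermediates.
#' Stages: consensus intersection of the dual-probe ChIRP peaks (after
#' per-record q filtering), peak-to-gene annotation and feature
#' distribution, NB differential testing in both cell models, direct /
#' indirect target classification, TF-layer identification with cross-model
#' coherence, promoter motif scanning of the common-DEG universe,
#' hierarchical network assembly, ChIP integration into the common
#' direct-target core, pairwise rank-correlation of the TF panel,
#' over-representation with term clustering, and coverage metaprofiles.
#'
#' Required `config$paths` entries: `genome`, `gtf`, `pwms`, `chirp_even`,
#' `chirp_odd`, `chip`, `counts_model_a`, `coldata_model_a`,
#' `counts_model_b`, `coldata_model_b`, `tf_catalog`, `tf_deg_model_b`.
#' Optional: `tf_deg_model_a`, `genesets`, `panel`, `coverage_lnc`,
#' `coverage_tf`.
#'
#' @param config A [pipeline_config()] with populated `paths`.
#' @param out_dir Output directory for stage tables.
#' @param quiet Suppress stage logging.
#' @return A `chirpnet_report`: list with `paths` (stage outputs),
#'   `summary` (consistent counts), and key in-memory results.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) log_stage(...)
  t0 <- Sys.time()
  pth <- function(f) file.path(out_dir, f)
  p <- config$paths
  need <- c("genome", "gtf", "pwms", "chirp_even", "chirp_odd", "chip",
            "counts_model_a", "coldata_model_a", "counts_model_b",
            "coldata_model_b", "tf_catalog", "tf_deg_model_b")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("config$paths is missing: ", paste(missing, collapse = ", "))
  for (nm in names(p)) if (!file.exists(p[[nm]]))
    stop("input file not found (", nm, "): ", p[[nm]])

  say("loading annotation and inputs")
  ann <- read_gtf(p$gtf)
  counts_a <- read_counts(p$counts_model_a, p$coldata_model_a)
  counts_b <- read_counts(p$counts_model_b, p$coldata_model_b)
  for (cm in list(c("model_a", "counts_model_a"), c("model_b", "counts_model_b"))) {
    cc <- if (cm[1] == "model_a") counts_a else counts_b
    unknown <- setdiff(rownames(cc$counts), ann$gene_id)
    if (length(unknown))
      stop("count matrix ", cm[2], " contains gene absent from annotation: ",
           unknown[1])
  }
  catalog <- read_table(p$tf_catalog)
  catalog$is_tf <- as.logical(catalog$is_tf)
  catalog$is_cofactor <- as.logical(catalog$is_cofactor)

  say("consensus: intersecting EVEN/ODD probe-set peaks")
  even <- filter_peaks_q(read_bed(p$chirp_even), config$peak_q)
  odd <- filter_peaks_q(read_bed(p$chirp_odd), config$peak_q)
  consensus <- intersect_consensus(even, odd)
  write_table(consensus, pth("consensus_peaks.tsv"))
  write_bed(consensus[, c("chrom", "start", "end", "name")],
            pth("consensus_peaks.bed"))
  say("consensus: %d peaks (EVEN %d, ODD %d)", nrow(consensus), nrow(even),
      nrow(odd))

  say("annotate: assigning peaks to nearest genes")
  annotation <- annotate_peaks(consensus, ann, config)
  write_table(annotation, pth("peak_annotation.tsv"))
  featdist <- feature_distribution(annotation)
  write_table(data.frame(feature_class = names(featdist),
                         fraction = as.numeric(featdist)),
              pth("feature_distribution.tsv"))

  say("de: differential testing in both cell models")
  de <- list()
  for (m in c("model_a", "model_b")) {
    cc <- if (m == "model_a") counts_a else counts_b
    filt <- filter_low_counts(cc$counts, config$low_count_min_total)
    de[[m]] <- de_test(filt, cc$condition, de_fdr = config$de_fdr,
                       refine_size_factors = TRUE)
    write_table(de[[m]], pth(paste0("deg_", m, ".tsv")))
    say("de %s: %d genes tested, %d DEGs", m, nrow(de[[m]]),
        sum(de[[m]]$padj < config$de_fdr))
  }

  say("integrate: direct/indirect target classification")
  cls <- classify_targets(annotation, de$model_a, config)
  write_table(cls$targets, pth("target_classes.tsv"))
  write_table(cls$summary, pth("classification_summary.tsv"))
  rdgs <- cls$targets$gene_id[cls$targets$class == "RDG"]

  say("integrate: RDG-TF layer with cross-model coherence")
  rdg_tf_tab <- identify_rdg_tfs(cls$targets, de$model_b, catalog, config)
  write_table(rdg_tf_tab, pth("rdg_tf_table.tsv"))
  rdg_tf_ids <- rdg_tf_tab$gene_id[rdg_tf_tab$rdg_tf &
                                     rdg_tf_tab$kind == "tf"]

  common_degs <- intersect(
    de$model_a$gene_id[de$model_a$padj < config$de_fdr],
    de$model_b$gene_id[de$model_b$padj < config$de_fdr])

  say("scan: PWM scanning of %d common-DEG promoters for %d RDG-TFs",
      length(common_degs), length(rdg_tf_ids))
  pwms <- read_meme(p$pwms)
  scan_pwms <- pwms[intersect(names(pwms), rdg_tf_ids)]
  if (length(scan_pwms) > 0L && length(common_degs) > 0L) {
    genome <- read_fasta(p$genome)
    windows <- extract_promoter_windows(ann[ann$gene_id %in% common_degs, ],
                                        genome, config)
    scan <- scan_windows(scan_pwms, windows, config)
    hits <- scan$hits
  } else {
    hits <- data.frame(tf_id = character(), gene_id = character(),
                       strand = character(), offset = integer(),
                       score = numeric(), p = numeric(), q = numeric())
  }
  attr(hits, "scanned_tfs") <- names(scan_pwms)
  write_table(hits, pth("motif_hits.tsv"))

  say("network: assembling TF-to-target edges")
  net <- build_network(rdg_tf_tab, hits, common_degs, cls$targets)
  write_table(net$edges, pth("network_edges.tsv"))

  say("comm: ChIP integration and common direct-target core")
  chip <- filter_peaks_q(read_bed(p$chip), config$peak_q)
  chip_ann <- annotate_peaks(chip, ann, config)
  write_table(chip_ann, pth("chip_annotation.tsv"))
  tf_bound <- unique(chip_ann$target_gene_id[!is.na(chip_ann$target_gene_id)])
  tf_direct_a <- if (!is.null(p$tf_deg_model_a))
    intersect(tf_bound, readLines(p$tf_deg_model_a)) else tf_bound
  lnc_deg_b <- de$model_b$gene_id[de$model_b$padj < config$de_fdr]
  tf_deg_b <- readLines(p$tf_deg_model_b)
  comm <- common_direct_targets(rdgs, tf_direct_a, lnc_deg_b, tf_deg_b)
  write_table(comm$provenance, pth("comm_dg.tsv"))

  if (!is.null(p$panel)) {
    say("panel: pairwise rank correlation")
    ptab <- utils::read.delim(p$panel, check.names = FALSE)
    pm <- as.matrix(ptab[, -1, drop = FALSE])
    rownames(pm) <- ptab[[1]]
    sp <- spearman_matrix(pm)
    write_table(data.frame(gene_id = rownames(sp$R), sp$R,
                           check.names = FALSE), pth("spearman_R.tsv"))
    write_table(data.frame(gene_id = rownames(sp$p), sp$p,
                           check.names = FALSE), pth("spearman_p.tsv"))
  }

  if (!is.null(p$genesets) && length(rdgs) > 0L) {
    say("enrich: over-representation on RDGs")
    sets <- read_gmt(p$genesets)
    enr <- ora(rdgs, sets, universe = de$model_a$gene_id,
               enrich_alpha = config$enrich_alpha)
    write_table(enr, pth("enrichment_rdg.tsv"))
    sig <- enr$term_id[enr$significant]
    if (length(sig) >= 2L) {
      sig_sets <- lapply(sets[sig], intersect, de$model_a$gene_id)
      J <- jaccard_matrix(sig_sets)
      clus <- cluster_terms(J, config$jaccard_edge_min, sig_sets)
      write_table(clus, pth("term_clusters.tsv"))
    }
  }

  chrom_lengths <- NULL
  if (!is.null(p$coverage_lnc) && length(rdgs) > 0L) {
    say("metaprofile: lncRNA signal around RDG TSSs")
    if (!exists("genome", inherits = FALSE)) genome <- read_fasta(p$genome)
    chrom_lengths <- stats::setNames(nchar(genome), names(genome))
    cov <- read_bedgraph(p$coverage_lnc, chrom_lengths)
    anchors <- ann[ann$gene_id %in% rdgs, c("chrom", "tss", "strand")]
    names(anchors)[2] <- "pos"
    mp <- metaprofile(cov, anchors, half_window_bp = 3000L, n_bins = 60L)
    write_table(data.frame(bin = seq_along(mp), mean_signal = as.numeric(mp)),
                pth("metaprofile_rdg_tss.tsv"))
  }
  if (!is.null(p$coverage_tf)) {
    say("metaprofile: TF signal around RDG-assigned peak centres")
    if (is.null(chrom_lengths)) {
      if (!exists("genome", inherits = FALSE)) genome <- read_fasta(p$genome)
      chrom_lengths <- stats::setNames(nchar(genome), names(genome))
    }
    cov_tf <- read_bedgraph(p$coverage_tf, chrom_lengths)
    rdg_peaks <- annotation[annotation$target_gene_id %in% rdgs, ]
    if (nrow(rdg_peaks)) {
      anchors <- data.frame(chrom = rdg_peaks$chrom, pos = rdg_peaks$midpoint,
                            strand = "+")
      mp2 <- metaprofile(cov_tf, anchors, half_window_bp = 3000L,
                         n_bins = 60L)
      write_table(data.frame(bin = seq_along(mp2),
                             mean_signal = as.numeric(mp2)),
                  pth("metaprofile_tf_at_peaks.tsv"))
    }
  }

  summary <- data.frame(
    n_even = nrow(even), n_odd = nrow(odd), n_consensus = nrow(consensus),
    n_deg_a = cls$summary$n_deg, n_up_a = cls$summary$n_up,
    n_down_a = cls$summary$n_down,
    n_rdg = cls$summary$n_rdg, n_rig = cls$summary$n_rig,
    rdg_pct = cls$summary$rdg_pct, rig_pct = cls$summary$rig_pct,
    n_deg_b = sum(de$model_b$padj < config$de_fdr),
    n_common_deg = length(common_degs),
    n_rdg_tf = length(rdg_tf_ids),
    n_edges = nrow(net$edges),
    n_comm_dg = length(comm$gene_ids))
  stopifnot(summary$n_deg_a == summary$n_rdg + summary$n_rig,
            all(comm$gene_ids %in% c(rdgs, character(0))) ||
              length(comm$gene_ids) == 0L)
  write_table(summary, pth("run_summary.tsv"))
  report <- list(
    out_dir = out_dir, paths = list(
      consensus = pth("consensus_peaks.tsv"),
      annotation = pth("peak_annotation.tsv"),
      feature_distribution = pth("feature_distribution.tsv"),
      deg_model_a = pth("deg_model_a.tsv"),
      deg_model_b = pth("deg_model_b.tsv"),
      target_classes = pth("target_classes.tsv"),
      rdg_tf_table = pth("rdg_tf_table.tsv"),
      motif_hits = pth("motif_hits.tsv"),
      network_edges = pth("network_edges.tsv"),
      comm_dg = pth("comm_dg.tsv"),
      run_summary = pth("run_summary.tsv")),
    summary = summary,
    targets = cls$targets, rdg_tf_table = rdg_tf_tab, edges = net$edges,
    comm = comm, feature_distribution = featdist,
    common_degs = common_degs,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "chirpnet_report"
  say("done in %.1f s", report$elapsed_s)
  report
}

#' @export
print.chirpnet_report <- function(x, ...) {
  cat("chirpnet run report (", x$out_dir, ")\n", sep = "")
  s <- x$summary
  cat(sprintf("  consensus peaks: %d (EVEN %d / ODD %d)\n",
              s$n_consensus, s$n_even, s$n_odd))
  cat(sprintf("  DEGs model A: %d (up %d / down %d); model B: %d; common: %d\n",
              s$n_deg_a, s$n_up_a, s$n_down_a, s$n_deg_b, s$n_common_deg))
  cat(sprintf("  RDGs: %d (%.2f%%), RIGs: %d (%.2f%%)\n",
              s$n_rdg, s$rdg_pct, s$n_rig, s$rig_pct))
  cat(sprintf("  RDG-TFs: %d; network edges: %d; comm_DGs: %d\n",
              s$n_rdg_tf, s$n_edges, s$n_comm_dg))
  invisible(x)
}
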