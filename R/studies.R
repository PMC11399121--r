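#' Planted-truth recovery study
#'
#' Runs the synthetic study and the full in-memory cascade over several
#' seeds and measures recovery of the planted truth: consensus recovery of
#' true binding sites (expected near `detect_prob^2` by probe-set
#' independence), RDG precision/recall against planted direct targets,
#' recovery of the planted TF layer, network edge recall against planted
#' TF-to-target pairs (`edge_recall` conditions on the edge's endpoints
#' surviving the upstream stages — it isolates the scanning/network step's
#' sensitivity — while `edge_recall_unconditional` folds in DE power and TF
#' recovery), and the common direct-target core from the four planted
#' membership lists.
#'
#' @param n_seeds Number of independent replicate studies.
#' @param seed Master seed; per-replicate seeds are derived substreams.
#' @param params From [synth_params()].
#' @param config A [pipeline_config()].
#' @return List: `per_seed` data frame and `means` (column means), plus
#'   `expected_consensus_rate = detect_prob^2`.
#' @export
recovery_study <- function(n_seeds = 20L, seed = 1L,
                           params = synth_params(),
                           config = pipeline_config()) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- substream_seed(seed, paste0("recovery_", i))
    gen <- generate_genome(params, s)
    truth <- make_truth(gen, params, s)
    pwms <- make_pwms(names(truth$tf_layer), params, s)
    pl <- plant_motifs(gen$genome, truth, pwms, gen$ann, config, s)
    truth$planted_motif_positions <- pl$motifs
    genome <- pl$genome

    chirp <- simulate_chirp_peaks(truth, gen$chrom_lengths, params, s)
    consensus <- intersect_consensus(
      filter_peaks_q(chirp$even, config$peak_q),
      filter_peaks_q(chirp$odd, config$peak_q))
    # site recovery: true sites overlapped by >= 1 consensus peak
    sites <- truth$true_binding_sites
    rec <- vapply(seq_len(nrow(sites)), function(k) {
      cs <- consensus[consensus$chrom == sites$chrom[k], , drop = FALSE]
      any(cs$start < sites$end[k] & cs$end > sites$start[k])
    }, logical(1))

    annotation <- annotate_peaks(consensus, gen$ann, config)
    de <- lapply(c(model_a = "model_a", model_b = "model_b"), function(m) {
      sim <- simulate_counts(truth, params, m, s)
      de_test(filter_low_counts(sim$counts, config$low_count_min_total),
              sim$condition, de_fdr = config$de_fdr,
              refine_size_factors = TRUE)
    })
    cls <- classify_targets(annotation, de$model_a, config)
    called_rdg <- cls$targets$gene_id[cls$targets$class == "RDG"]
    tp <- length(intersect(called_rdg, truth$direct_target_ids))
    precision <- if (length(called_rdg)) tp / length(called_rdg) else NA_real_
    recall <- tp / length(truth$direct_target_ids)

    catalog <- data.frame(gene_id = gen$ann$gene_id,
                          is_tf = gen$ann$gene_id %in% truth$tf_ids,
                          is_cofactor = gen$ann$gene_id %in% truth$cofactor_ids)
    rdg_tf_tab <- suppressWarnings(
      identify_rdg_tfs(cls$targets, de$model_b, catalog, config))
    recovered_tfs <- rdg_tf_tab$gene_id[rdg_tf_tab$rdg_tf &
                                          rdg_tf_tab$kind == "tf"]
    planted_tfs <- names(truth$tf_layer)
    tf_recall <- length(intersect(recovered_tfs, planted_tfs)) /
      length(planted_tfs)

    common_degs <- intersect(
      de$model_a$gene_id[de$model_a$padj < config$de_fdr],
      de$model_b$gene_id[de$model_b$padj < config$de_fdr])
    scan_pwms <- pwms[intersect(names(pwms), recovered_tfs)]
    edges <- if (length(scan_pwms) && length(common_degs)) {
      windows <- extract_promoter_windows(
        gen$ann[gen$ann$gene_id %in% common_degs, ], genome, config)
      hits <- scan_windows(scan_pwms, windows, config)$hits
      build_network(rdg_tf_tab, hits, common_degs, cls$targets)$edges
    } else data.frame(source_tf_id = character(),
                      target_gene_id = character())
    planted_tab <- do.call(rbind, lapply(planted_tfs, function(tf)
      data.frame(tf = tf, target = c(truth$tf_layer[[tf]]$downstream,
                                     truth$tf_layer[[tf]]$coop))))
    planted_edges <- paste(planted_tab$tf, planted_tab$target)
    got_edges <- paste(edges$source_tf_id, edges$target_gene_id)
    # scan/network sensitivity: recall among edges whose endpoints survived
    # the upstream stages (TF recovered, target in the common-DEG universe)
    findable <- planted_edges[planted_tab$tf %in% recovered_tfs &
                                planted_tab$target %in% common_degs]
    edge_recall <- length(intersect(got_edges, findable)) /
      max(length(findable), 1L)
    edge_recall_unconditional <-
      length(intersect(got_edges, planted_edges)) / length(planted_edges)

    # common core from the simulator's four emitted membership lists
    fl <- truth$comm_flags
    comm <- common_direct_targets(
      fl$gene_id[fl$lnc_direct_a], fl$gene_id[fl$tf_direct_a],
      fl$gene_id[fl$lnc_deg_b], fl$gene_id[fl$tf_deg_b])
    comm_exact <- setequal(comm$gene_ids, fl$gene_id[fl$comm])
    # fully computed route, scored as recovery of the planted core
    tf_direct_a <- intersect(
      unique(annotate_peaks(filter_peaks_q(
        simulate_chip_peaks(truth, gen$chrom_lengths, params, s),
        config$peak_q), gen$ann, config)$target_gene_id),
      truth$tf_deg_a_ids)
    comm2 <- common_direct_targets(
      called_rdg, tf_direct_a,
      de$model_b$gene_id[de$model_b$padj < config$de_fdr],
      truth$tf_deg_b_ids)
    planted_comm <- fl$gene_id[fl$comm]
    comm_recall <- length(intersect(comm2$gene_ids, planted_comm)) /
      length(planted_comm)

    data.frame(
      seed = s, n_sites = nrow(sites), n_sites_recovered = sum(rec),
      consensus_rate = mean(rec),
      rdg_precision = precision, rdg_recall = recall,
      tf_recall = tf_recall, edge_recall = edge_recall,
      edge_recall_unconditional = edge_recall_unconditional,
      comm_exact = as.numeric(comm_exact), comm_recall = comm_recall)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       means = colMeans(per_seed[, -1]),
       expected_consensus_rate = params$detect_prob^2)
}

#' Calibration study for the NB differential test
#'
#' Two simulation checks of the test's statistical behaviour: (1) type-I
#' error on an all-null NB simulation (default 2000 genes, 3 vs 3,
#' dispersion 0.05) as the fraction of raw p below the nominal 0.05; (2)
#' bias of the effect estimate with a planted log2 fold change of 2 (200
#' genes, mean 1000, dispersion 0.01, 5 vs 5, unit size factors so the
#' global shift is identifiable).
#'
#' @param seed Integer seed.
#' @param n_null,null_dispersion,null_reps All-null scenario settings.
#' @param n_effect,effect_lfc,effect_mu,effect_dispersion,effect_reps
#'   Planted-effect scenario settings.
#' @return List: `type1_error`, `mean_lfc`, and the two DE tables.
#' @export
calibration_study <- function(seed = 1L,
                              n_null = 2000L, null_dispersion = 0.05,
                              null_reps = 3L,
                              n_effect = 200L, effect_lfc = 2,
                              effect_mu = 1000, effect_dispersion = 0.01,
                              effect_reps = 5L) {
  set.seed(substream_seed(seed, "calibration_null"))
  mu <- exp(stats::runif(n_null, log(50), log(2000)))
  cond <- rep(c("control", "knockdown"), each = null_reps)
  counts <- matrix(stats::rnbinom(n_null * 2L * null_reps,
                                  mu = rep(mu, 2L * null_reps),
                                  size = 1 / null_dispersion),
                   n_null, 2L * null_reps,
                   dimnames = list(sprintf("null_g%04d", seq_len(n_null)),
                                   paste0("s", seq_len(2L * null_reps))))
  de_null <- de_test(counts, cond, sf = rep(1, 2L * null_reps))
  type1 <- mean(de_null$p < 0.05)

  set.seed(substream_seed(seed, "calibration_effect"))
  cond2 <- rep(c("control", "knockdown"), each = effect_reps)
  mu2 <- matrix(effect_mu, n_effect, 2L * effect_reps)
  mu2[, cond2 == "knockdown"] <- effect_mu * 2^effect_lfc
  counts2 <- matrix(stats::rnbinom(length(mu2), mu = mu2,
                                   size = 1 / effect_dispersion),
                    n_effect, 2L * effect_reps,
                    dimnames = list(sprintf("eff_g%03d", seq_len(n_effect)),
                                    paste0("s", seq_len(2L * effect_reps))))
  de_eff <- de_test(counts2, cond2, sf = rep(1, 2L * effect_reps))
  list(type1_error = type1, mean_lfc = mean(de_eff$log2fc),
       null_table = de_null, effect_table = de_eff)
}
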