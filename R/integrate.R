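#' Classify genes as direct or indirect lncRNA targets
#'
#' The integration at the heart of the cascade: a gene that is
#' differentially expressed upon lncRNA knockdown (`padj < de_fdr`) *and*
#' carries at least one assigned consensus binding peak is a direct target
#' (RDG); a DEG with no assigned peak is an indirect target (RIG); a bound
#' non-DEG is `bound_only`; everything else is `unchanged`. Binding counts
#' regardless of the peak's feature class (promoter, intronic or distal), as
#' nearest-gene assignment places regulatory elements throughout gene bodies
#' and flanking regions.
#'
#' @param peak_annotations From [annotate_peaks()].
#' @param deg_records From [de_test()].
#' @param config A [pipeline_config()] (uses `de_fdr`).
#' @return List: `targets` (data frame `gene_id`, `class`, `de_direction`,
#'   `log2fc`, `padj`, `n_peaks`, `peak_ids`) covering every gene in either
#'   input, and `summary` (counts and two-decimal percentage shares).
#' @export
classify_targets <- function(peak_annotations, deg_records, config) {
  bound <- split(peak_annotations$peak_name, peak_annotations$target_gene_id)
  genes <- sort(union(deg_records$gene_id, names(bound)))
  de <- deg_records[match(genes, deg_records$gene_id), ]
  is_deg <- !is.na(de$padj) & de$padj < config$de_fdr
  has_peak <- genes %in% names(bound)
  class <- ifelse(is_deg & has_peak, "RDG",
                  ifelse(is_deg, "RIG",
                         ifelse(has_peak, "bound_only", "unchanged")))
  targets <- data.frame(
    gene_id = genes, class = class,
    de_direction = ifelse(is.na(de$direction), "ns", de$direction),
    log2fc = de$log2fc, padj = de$padj,
    n_peaks = vapply(genes, function(g)
      length(bound[[g]]), integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  targets$peak_ids <- vapply(genes, function(g)
    paste(bound[[g]], collapse = ","), character(1), USE.NAMES = FALSE)
  n_deg <- sum(is_deg)
  n_rdg <- sum(class == "RDG")
  n_rig <- sum(class == "RIG")
  summary <- data.frame(
    n_deg = n_deg, n_up = sum(is_deg & de$log2fc > 0),
    n_down = sum(is_deg & de$log2fc < 0),
    n_rdg = n_rdg, n_rig = n_rig,
    n_bound_only = sum(class == "bound_only"),
    rdg_pct = if (n_deg > 0) round(100 * n_rdg / n_deg, 2) else NA_real_,
    rig_pct = if (n_deg > 0) round(100 * n_rig / n_deg, 2) else NA_real_)
  list(targets = targets, summary = summary)
}

#' Identify the TF layer (RDG-TFs) with cross-model coherence
#'
#' A gene qualifies as an RDG-TF (or RDG co-factor) iff it is an RDG in the
#' discovery cell model, is flagged as a TF (or co-factor) in the supplied
#' catalog, is a DEG in the second cell model, and its fold change has the
#' same sign in both models ("coherently affected"); magnitude is not
#' thresholded. Catalog genes absent from the expression tables are skipped
#' with a warning.
#'
#' @param targets_a `targets` from [classify_targets()] for the discovery
#'   model.
#' @param deg_b [de_test()] records for the second model.
#' @param tf_catalog Data frame `gene_id`, `is_tf`, `is_cofactor`.
#' @param config A [pipeline_config()].
#' @return Data frame: `gene_id`, `kind` (`tf`/`cofactor`), `log2fc_a`,
#'   `log2fc_b`, `coherent`, `rdg_tf` (qualifies), plus counts as the
#'   `summary` attribute (`n_tf_rdg`, `n_cofactor_rdg`, `n_tf_coherent`,
#'   `n_cofactor_coherent`).
#' @export
identify_rdg_tfs <- function(targets_a, deg_b, tf_catalog, config) {
  cat_rows <- tf_catalog[tf_catalog$is_tf | tf_catalog$is_cofactor, ]
  known <- cat_rows$gene_id %in% targets_a$gene_id |
    cat_rows$gene_id %in% deg_b$gene_id
  if (any(!known))
    warning("catalog gene(s) absent from expression tables skipped: ",
            paste(utils::head(cat_rows$gene_id[!known], 5), collapse = ", "))
  cat_rows <- cat_rows[known, ]
  ta <- targets_a[match(cat_rows$gene_id, targets_a$gene_id), ]
  db <- deg_b[match(cat_rows$gene_id, deg_b$gene_id), ]
  is_rdg_a <- !is.na(ta$class) & ta$class == "RDG"
  deg_in_b <- !is.na(db$padj) & db$padj < config$de_fdr
  coherent <- deg_in_b & !is.na(ta$log2fc) &
    sign(ta$log2fc) == sign(db$log2fc)
  out <- data.frame(
    gene_id = cat_rows$gene_id,
    kind = ifelse(cat_rows$is_tf, "tf", "cofactor"),
    log2fc_a = ta$log2fc, log2fc_b = db$log2fc,
    rdg_a = is_rdg_a, deg_b = deg_in_b, coherent = coherent,
    rdg_tf = is_rdg_a & coherent,
    stringsAsFactors = FALSE)
  attr(out, "summary") <- data.frame(
    n_tf_rdg = sum(is_rdg_a & out$kind == "tf"),
    n_cofactor_rdg = sum(is_rdg_a & out$kind == "cofactor"),
    n_tf_coherent = sum(out$rdg_tf & out$kind == "tf"),
    n_cofactor_coherent = sum(out$rdg_tf & out$kind == "cofactor"))
  out
}

#' Build the hierarchical TF-to-target network
#'
#' An edge TF -> gene exists iff at least one retained motif hit
#' (`q < motif_q`) of that TF's PWM falls in the gene's promoter window and
#' the gene belongs to the common-DEG universe (genes differentially
#' expressed in both cell models); edges are deduplicated and labelled with
#' the target's class (RDG/RIG layer). TFs without a PWM are omitted and
#' listed.
#'
#' @param rdg_tfs Output of [identify_rdg_tfs()] (rows with `rdg_tf`).
#' @param motif_hits `hits` from [scan_windows()].
#' @param common_degs Character vector: the common-DEG universe.
#' @param target_classes `targets` from [classify_targets()].
#' @return List: `edges` (data frame `source_tf_id`, `target_gene_id`,
#'   `target_class`, `n_hits`, `best_q`), `per_tf` counts, and
#'   `tfs_without_pwm`.
#' @export
build_network <- function(rdg_tfs, motif_hits, common_degs, target_classes) {
  tf_ids <- rdg_tfs$gene_id[rdg_tfs$rdg_tf]
  hits <- motif_hits[motif_hits$tf_id %in% tf_ids &
                       motif_hits$gene_id %in% common_degs &
                       motif_hits$gene_id != motif_hits$tf_id, , drop = FALSE]
  if (nrow(hits)) {
    key <- paste(hits$tf_id, hits$gene_id)
    agg_n <- tapply(hits$q, key, length)
    agg_q <- tapply(hits$q, key, min)
    parts <- strsplit(names(agg_n), " ", fixed = TRUE)
    edges <- data.frame(
      source_tf_id = vapply(parts, `[`, character(1), 1L),
      target_gene_id = vapply(parts, `[`, character(1), 2L),
      n_hits = as.integer(agg_n), best_q = as.numeric(agg_q),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source_tf_id = character(),
                        target_gene_id = character(),
                        n_hits = integer(), best_q = numeric())
  }
  cls <- target_classes$class[match(edges$target_gene_id,
                                    target_classes$gene_id)]
  edges$target_class <- ifelse(is.na(cls), "RIG", cls)
  edges <- edges[order(edges$source_tf_id, edges$target_gene_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  per_tf <- if (nrow(edges))
    as.data.frame.matrix(table(edges$source_tf_id, edges$target_class))
  else data.frame()
  scanned <- unique(motif_hits$tf_id)
  list(edges = edges[, c("source_tf_id", "target_gene_id", "target_class",
                         "n_hits", "best_q")],
       per_tf = per_tf,
       tfs_without_pwm = setdiff(tf_ids, c(scanned,
                                           attr(motif_hits, "scanned_tfs"))))
}

#' Derive the common direct-target core
#'
#' The staged gene-list intersection that yields the core of genes regulated
#' by both the lncRNA and the cooperating TF: direct targets of both in the
#' discovery model, further filtered on both knockdowns' DEG lists from the
#' second model. Per-gene provenance flags are recorded; membership holds
#' iff all four flags are true, so the result is invariant to the order of
#' the intersection steps.
#'
#' @param lnc_direct_a,tf_direct_a,lnc_deg_b,tf_deg_b Character vectors of
#'   gene ids.
#' @return List: `gene_ids` (sorted members) and `provenance` (flag data
#'   frame over the union of all four lists).
#' @export
common_direct_targets <- function(lnc_direct_a, tf_direct_a, lnc_deg_b,
                                  tf_deg_b) {
  universe <- sort(unique(c(lnc_direct_a, tf_direct_a, lnc_deg_b, tf_deg_b)))
  prov <- data.frame(
    gene_id = universe,
    lnc_direct_a = universe %in% lnc_direct_a,
    tf_direct_a = universe %in% tf_direct_a,
    lnc_deg_b = universe %in% lnc_deg_b,
    tf_deg_b = universe %in% tf_deg_b,
    stringsAsFactors = FALSE)
  prov$comm <- prov$lnc_direct_a & prov$tf_direct_a & prov$lnc_deg_b &
    prov$tf_deg_b
  list(gene_ids = prov$gene_id[prov$comm], provenance = prov)
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlation (average ranks for ties) between all gene pairs of an
#' expression table, with the t-approximation p-value
#' `t = R sqrt((n - 2) / (1 - R^2))`, two-sided, and significance flags at
#' `p < 0.05`. Constant genes yield undefined correlations (NA, flagged).
#'
#' @param expr Numeric matrix, genes x samples (>= 4 samples).
#' @return List: `R`, `p`, `significant` matrices and `constant_genes`.
#' @export
spearman_matrix <- function(expr) {
  n <- ncol(expr)
  if (n < 4L) stop("need >= 4 samples")
  constant <- apply(expr, 1, function(x) stats::sd(x) == 0)
  R <- suppressWarnings(stats::cor(t(expr), method = "spearman"))
  diag(R) <- 1
  R[constant, ] <- NA; R[, constant] <- NA
  diag(R)[constant] <- NA
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(R = R, p = p, significant = !is.na(p) & p < 0.05,
       constant_genes = rownames(expr)[constant])
}
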