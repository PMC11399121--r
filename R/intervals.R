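#' Dual-probe consensus intersection
#'
#' ChIRP performed with two independent antisense probe sets (EVEN and ODD)
#' yields two peak files; only genomic segments covered by at least one peak
#' from each probe set are retained as true RNA-bound elements. The output is
#' the union of all pairwise EVEN/ODD intersections with overlapping retained
#' segments merged, sorted by position. Provenance (`even_sources`,
#' `odd_sources`) records the originating peak names (comma-joined after
#' merging).
#'
#' @param even,odd Interval data frames (see [read_bed()]). A `name` column
#'   is used for provenance; rows without one are numbered.
#' @return Consensus peak data frame with columns `chrom`, `start`, `end`,
#'   `name`, `even_sources`, `odd_sources`.
#' @export
intersect_consensus <- function(even, odd) {
  out <- empty_intervals()[, c("chrom", "start", "end", "name")]
  out$even_sources <- character(0)
  out$odd_sources <- character(0)
  if (nrow(even) == 0L || nrow(odd) == 0L) return(out)
  if (is.null(even$name)) even$name <- paste0("even_", seq_len(nrow(even)))
  if (is.null(odd$name)) odd$name <- paste0("odd_", seq_len(nrow(odd)))
  res <- list()
  for (ch in sort(intersect(unique(even$chrom), unique(odd$chrom)))) {
    e <- even[even$chrom == ch, , drop = FALSE]
    o <- odd[odd$chrom == ch, , drop = FALSE]
    ir_e <- IRanges::IRanges(e$start + 1L, e$end)  # 1-based closed for IRanges
    ir_o <- IRanges::IRanges(o$start + 1L, o$end)
    hits <- IRanges::findOverlaps(ir_e, ir_o, minoverlap = 1L)
    if (length(hits) == 0L) next
    pi <- IRanges::pintersect(ir_e[S4Vectors::queryHits(hits)],
                              ir_o[S4Vectors::subjectHits(hits)])
    merged <- IRanges::reduce(pi)
    ov <- IRanges::findOverlaps(merged, pi)
    segs <- data.frame(
      chrom = ch,
      start = IRanges::start(merged) - 1L,
      end = IRanges::end(merged),
      stringsAsFactors = FALSE
    )
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    segs$even_sources <- vapply(seq_len(nrow(segs)), function(i) {
      paste(sort(unique(e$name[S4Vectors::queryHits(hits)[sh[qh == i]]])),
            collapse = ",")
    }, character(1))
    segs$odd_sources <- vapply(seq_len(nrow(segs)), function(i) {
      paste(sort(unique(o$name[S4Vectors::subjectHits(hits)[sh[qh == i]]])),
            collapse = ",")
    }, character(1))
    res[[ch]] <- segs
  }
  if (length(res) == 0L) return(out)
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$name <- sprintf("consensus_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "even_sources", "odd_sources")]
}

#' Filter peak records on their q column
#'
#' Applied to incoming peak files before probe-set intersection, mirroring
#' the q cut-off used at peak calling. Records without a `q` column pass
#' unchanged.
#'
#' @param peaks Interval data frame.
#' @param peak_q Threshold; peaks with `q < peak_q` are retained.
#' @export
filter_peaks_q <- function(peaks, peak_q) {
  if (is.null(peaks$q)) return(peaks)
  peaks[peaks$q < peak_q, , drop = FALSE]
}

# midpoint convention: floor((start + end) / 2), 0-based
interval_midpoint <- function(start, end) as.integer(floor((start + end) / 2))

#' Assign peaks to nearest genes and genomic features
#'
#' Each peak is assigned to the gene (same chromosome) whose TSS is nearest
#' to the peak midpoint, with ties broken toward the lexicographically
#' smaller `gene_id`. The signed distance is strand-oriented (positive =
#' downstream of the TSS in transcription direction). The feature class is
#' decided from the midpoint by precedence: promoter (within the TSS window
#' of the target gene) > 5' UTR > 3' UTR > exon > intron > downstream
#' (within `tss_window_bp` past a gene end) > distal intergenic; the
#' UTR/exon/intron/downstream classes consider every gene on the chromosome.
#'
#' @param peaks Consensus peak data frame.
#' @param genes Gene annotation (see [read_gtf()]).
#' @param config A [pipeline_config()].
#' @return Annotation data frame: `peak_name`, `chrom`, `start`, `end`,
#'   `midpoint`, `target_gene_id`, `signed_distance_to_tss`, `feature_class`.
#' @export
annotate_peaks <- function(peaks, genes, config) {
  n <- nrow(peaks)
  out <- data.frame(
    peak_name = if (!is.null(peaks$name)) peaks$name else sprintf("peak_%05d", seq_len(n)),
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    midpoint = interval_midpoint(peaks$start, peaks$end),
    target_gene_id = NA_character_,
    signed_distance_to_tss = NA_integer_,
    feature_class = "distal_intergenic",
    stringsAsFactors = FALSE
  )
  w <- config$tss_window_bp
  by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  in_any <- function(pos, mat_list, rows) {
    for (i in rows) {
      m <- mat_list[[i]]
      if (!is.null(m) && nrow(m) > 0 && any(pos >= m[, 1] & pos < m[, 2]))
        return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n)) {
    rows <- by_chr[[out$chrom[i]]]
    if (is.null(rows)) next
    mid <- out$midpoint[i]
    d <- abs(mid - genes$tss[rows])
    best <- rows[which(d == min(d))]
    if (length(best) > 1L) best <- best[order(genes$gene_id[best])][1]
    tgt <- best
    signed <- mid - genes$tss[tgt]
    if (genes$strand[tgt] == "-") signed <- -signed
    out$target_gene_id[i] <- genes$gene_id[tgt]
    out$signed_distance_to_tss[i] <- signed
    if (abs(signed) <= w) {
      out$feature_class[i] <- "promoter"
    } else if (in_any(mid, genes$utr5, rows)) {
      out$feature_class[i] <- "five_prime_utr"
    } else if (in_any(mid, genes$utr3, rows)) {
      out$feature_class[i] <- "three_prime_utr"
    } else if (in_any(mid, genes$exons, rows)) {
      out$feature_class[i] <- "exon"
    } else if (any(mid >= genes$tx_start[rows] & mid < genes$tx_end[rows])) {
      out$feature_class[i] <- "intron"
    } else {
      gene_end3 <- ifelse(genes$strand[rows] == "+",
                          genes$tx_end[rows], genes$tx_start[rows])
      past <- ifelse(genes$strand[rows] == "+",
                     mid - gene_end3, gene_end3 - 1L - mid)
      if (any(past > 0 & past <= w)) out$feature_class[i] <- "downstream"
    }
  }
  out
}

#' Genomic feature distribution of annotated peaks
#'
#' @param annotations Output of [annotate_peaks()].
#' @return Named numeric vector of fractions per feature class (sums to 1).
#' @export
feature_distribution <- function(annotations) {
  if (nrow(annotations) == 0L) stop("no annotated peaks")
  classes <- c("promoter", "five_prime_utr", "three_prime_utr", "exon",
               "intron", "downstream", "distal_intergenic")
  tab <- table(factor(annotations$feature_class, levels = classes))
  stats::setNames(as.vector(tab) / nrow(annotations), classes)
}

#' Average coverage profile around a set of anchors
#'
#' Computes the mean signal in `n_bins` equal bins over the window
#' `[anchor - half_window_bp, anchor + half_window_bp)`. Windows of minus
#' strand anchors are reversed so that bins run 5' to 3' of the anchored
#' feature. Windows truncated at a chromosome end contribute only their
#' covered bins; missing bins are excluded from the mean (and counted in the
#' `n_truncated` attribute).
#'
#' @param coverage Coverage accessor from [read_bedgraph()].
#' @param anchors Data frame with `chrom`, `pos` (0-based) and `strand`.
#' @param half_window_bp Half window width in bp.
#' @param n_bins Number of bins; must divide `2 * half_window_bp`.
#' @return Numeric vector of length `n_bins` (mean signal per bin), with
#'   attribute `n_truncated`.
#' @export
metaprofile <- function(coverage, anchors, half_window_bp, n_bins) {
  if ((2L * half_window_bp) %% n_bins != 0L)
    stop("n_bins must divide 2 * half_window_bp")
  bw <- (2L * half_window_bp) %/% n_bins
  sums <- numeric(n_bins)
  cnts <- numeric(n_bins)
  n_trunc <- 0L
  for (i in seq_len(nrow(anchors))) {
    cv <- coverage[[anchors$chrom[i]]]
    if (is.null(cv)) next
    w0 <- anchors$pos[i] - half_window_bp           # 0-based window start
    pos <- w0 + seq_len(2L * half_window_bp) - 1L   # 0-based bases
    ok <- pos >= 0L & pos < length(cv)
    if (!all(ok)) n_trunc <- n_trunc + 1L
    vals <- rep(NA_real_, length(pos))
    vals[ok] <- cv[pos[ok] + 1L]
    if (!is.null(anchors$strand) && anchors$strand[i] == "-")
      vals <- rev(vals)
    bm <- matrix(vals, nrow = bw)
    bsum <- colMeans(bm)                             # NA if any base missing
    have <- !is.na(bsum)
    sums[have] <- sums[have] + bsum[have]
    cnts[have] <- cnts[have] + 1
  }
  prof <- ifelse(cnts > 0, sums / cnts, NA_real_)
  attr(prof, "n_truncated") <- n_trunc
  prof
}
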