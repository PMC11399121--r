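#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (restricted to genes
#' with all-positive counts) of the ratio between the sample's count and the
#' gene's geometric mean across samples; factors are then rescaled so their
#' geometric mean is 1. If no gene has all-positive counts the function
#' falls back to total-count ratios with a warning.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) {
    warning("no gene with all-positive counts; falling back to total-count ratios")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    return(stats::setNames(sf, colnames(counts)))
  }
  gm <- exp(lg[ok])
  sf <- apply(counts[ok, , drop = FALSE], 2, function(s) stats::median(s / gm))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Drop genes with low total counts
#'
#' @param counts Integer matrix, genes x samples.
#' @param min_total Minimum raw count summed over all samples.
#' @return The matrix restricted to genes with total `>= min_total`, order
#'   preserved.
#' @export
filter_low_counts <- function(counts, min_total) {
  stopifnot(min_total >= 0)
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, returned in input order. This is a validated
#' front door over [stats::p.adjust()]; the test suite checks it against an
#' independent step-up implementation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald differential test
#'
#' A transparent method-of-moments NB test for knockdown-versus-control
#' designs. Counts are normalized by size factors (median-of-ratios unless
#' supplied); per gene, the dispersion is estimated by moments from the
#' within-condition variance pooled across conditions,
#' `alpha = max((s2 - mu) / mu^2, 1e-8)`, the effect is
#' `log2fc = log2((mu_kd + 0.5) / (mu_ctrl + 0.5))` on normalized group
#' means, its standard error comes from the delta-method NB variance
#' `(1/mu + alpha)/n` per group summed and divided by `ln 2`, and the Wald
#' statistic is referred to a Student t with `n1 + n2 - 2` degrees of
#' freedom (two-sided). Adjustment is Benjamini-Hochberg; genes are labelled
#' `up` / `down` at `padj < de_fdr`, otherwise `ns`.
#'
#' When a large fraction of the transcriptome responds to the knockdown
#' (the situation for a master-regulator perturbation), median-of-ratios
#' factors computed on all genes are biased by the responders, which shows
#' up as a common offset of the null genes' fold changes.
#' `refine_size_factors = TRUE` adds a null-centring pass: the first-pass
#' log2 fold changes are clustered into three groups (down / unchanged /
#' up), and the knockdown-group size factors are rescaled so the cluster
#' nearest zero is centred at zero; shifts beyond 0.5 (outside what
#' normalization bias can produce) are ignored. The correction is symmetric
#' in the condition labels.
#'
#' @param counts Filtered integer matrix, genes x samples.
#' @param condition Per-sample labels; exactly two levels, `control` and
#'   `knockdown` (aliases `CTRL`/`ctrl` and `KD`/`kd` are accepted).
#' @param de_fdr Significance threshold on `padj`.
#' @param sf Optional per-sample size factors; default median-of-ratios.
#' @param refine_size_factors Renormalize on apparently invariant genes.
#' @return Data frame with `gene_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p`, `padj`, `direction`.
#' @export
de_test <- function(counts, condition, de_fdr = 0.1, sf = NULL,
                    refine_size_factors = FALSE) {
  if (refine_size_factors && is.null(sf)) {
    first <- de_test(counts, condition, de_fdr = de_fdr)
    x <- first$log2fc
    init <- unique(c(min(x), x[which.min(abs(x))], max(x)))
    if (length(x) >= 50L && length(init) == 3L) {
      km <- suppressWarnings(stats::kmeans(x, centers = init))
      delta <- km$centers[which.min(abs(km$centers)), 1]
      if (abs(delta) <= 0.5) {
        sf <- size_factors(counts)
        kd0 <- tolower(as.character(condition)) %in% c("kd", "knockdown")
        sf[kd0] <- sf[kd0] * 2^delta
        sf <- sf / exp(mean(log(sf)))
      }
    }
  }
  condition <- tolower(as.character(condition))
  condition[condition %in% c("ctrl", "control")] <- "control"
  condition[condition %in% c("kd", "knockdown")] <- "knockdown"
  if (!setequal(unique(condition), c("control", "knockdown")))
    stop("condition must contain exactly the levels control and knockdown")
  ctrl <- condition == "control"
  kd <- condition == "knockdown"
  nc <- sum(ctrl); nk <- sum(kd)
  if (nc < 2L || nk < 2L) stop("each condition needs >= 2 replicates")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  mu_c <- rowMeans(norm[, ctrl, drop = FALSE])
  mu_k <- rowMeans(norm[, kd, drop = FALSE])
  v_c <- apply(norm[, ctrl, drop = FALSE], 1, stats::var)
  v_k <- apply(norm[, kd, drop = FALSE], 1, stats::var)
  s2 <- ((nc - 1) * v_c + (nk - 1) * v_k) / (nc + nk - 2)
  mu <- (nc * mu_c + nk * mu_k) / (nc + nk)
  alpha <- pmax((s2 - mu) / mu^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  log2fc <- log2((mu_k + 0.5) / (mu_c + 0.5))
  se <- sqrt((1 / pmax(mu_c, 0.5) + alpha) / nc +
             (1 / pmax(mu_k, 0.5) + alpha) / nk) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pt(-abs(stat), df = nc + nk - 2)
  padj <- bh_adjust(p)
  direction <- rep("ns", length(p))
  direction[padj < de_fdr & log2fc > 0] <- "up"
  direction[padj < de_fdr & log2fc < 0] <- "down"
  data.frame(
    gene_id = rownames(counts), base_mean = mu, log2fc = log2fc, se = se,
    stat = stat, p = p, padj = padj, direction = direction,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' NanoString-style panel normalization
#'
#' Two-step geometric-mean normalization: (1) a per-sample technical factor,
#' the grand geometric mean of the positive-control counts divided by the
#' sample's geometric mean of the positive controls; (2) after applying step
#' 1, the `k` housekeeping candidates with the lowest coefficient of
#' variation define an identical second factor.
#'
#' @param raw Numeric matrix, genes x samples (positive controls included as
#'   rows).
#' @param positive_control_ids,housekeeping_candidate_ids Row ids.
#' @param k Number of housekeeping genes retained (lowest CV).
#' @return List: `normalized` matrix, `housekeeping` (chosen ids),
#'   `tech_factors`, `hk_factors`.
#' @export
nanostring_normalize <- function(raw, positive_control_ids,
                                 housekeeping_candidate_ids, k = 3L) {
  stopifnot(k >= 1L, all(positive_control_ids %in% rownames(raw)))
  cand <- intersect(housekeeping_candidate_ids, rownames(raw))
  if (length(cand) < k) stop("fewer than k housekeeping candidates present")
  pc <- raw[positive_control_ids, , drop = FALSE]
  if (any(pc <= 0)) stop("zero positive-control count")
  gmean <- function(x) exp(mean(log(x)))
  samp_gm <- apply(pc, 2, gmean)
  tech <- gmean(samp_gm) / samp_gm
  step1 <- sweep(raw, 2, tech, "*")
  cv <- apply(step1[cand, , drop = FALSE], 1,
              function(x) stats::sd(x) / mean(x))
  chosen <- cand[order(cv, cand)][seq_len(k)]
  hk <- step1[chosen, , drop = FALSE]
  hk_gm <- apply(hk, 2, gmean)
  hkf <- gmean(hk_gm) / hk_gm
  list(normalized = sweep(step1, 2, hkf, "*"),
       housekeeping = chosen, tech_factors = tech, hk_factors = hkf)
}

#' Group fold change with unpaired t-test
#'
#' Per-gene fold change between two sample groups (e.g. metastatic DM versus
#' CTRL cohorts) on normalized values: `FC = mean(DM) / mean(CTRL)`, with a
#' two-tailed unpaired Student t-test and BH adjustment.
#'
#' @param normalized Numeric matrix, genes x samples.
#' @param groups Per-sample labels with exactly two levels.
#' @param test_group,ref_group The numerator and denominator labels
#'   (defaults `"DM"` and `"CTRL"`).
#' @return Data frame `gene_id`, `fc`, `p`, `padj`, `flag` (`"undefined_fc"`
#'   where the reference mean is zero).
#' @export
group_fold_change <- function(normalized, groups, test_group = "DM",
                              ref_group = "CTRL") {
  a <- groups == test_group
  b <- groups == ref_group
  if (sum(a) < 2L || sum(b) < 2L) stop("each group needs >= 2 samples")
  m_a <- rowMeans(normalized[, a, drop = FALSE])
  m_b <- rowMeans(normalized[, b, drop = FALSE])
  fc <- ifelse(m_b > 0, m_a / m_b, NA_real_)
  p <- vapply(seq_len(nrow(normalized)), function(i) {
    x <- normalized[i, a]; y <- normalized[i, b]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y, var.equal = TRUE)$p.value
  }, numeric(1))
  data.frame(gene_id = rownames(normalized), fc = fc, p = p,
             padj = bh_adjust(p),
             flag = ifelse(m_b > 0, "", "undefined_fc"),
             row.names = NULL, stringsAsFactors = FALSE)
}
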