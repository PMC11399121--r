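test_that("consensus intersection keeps only dual-probe overlap", {
  even <- data.frame(chrom = "chr1", start = 100L, end = 200L, name = "e1")
  odd <- data.frame(chrom = "chr1", start = 150L, end = 250L, name = "o1")
  cons <- intersect_consensus(even, odd)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 150L)
  expect_equal(cons$end, 200L)
  expect_equal(cons$even_sources, "e1")
  expect_equal(cons$odd_sources, "o1")
  # disjoint sets give empty output, as do empty inputs
  odd2 <- data.frame(chrom = "chr1", start = 300L, end = 400L, name = "o1")
  expect_equal(nrow(intersect_consensus(even, odd2)), 0L)
  expect_equal(nrow(intersect_consensus(even[0, ], odd)), 0L)
})

test_that("consensus matches the all-pairs brute-force oracle", {
  set.seed(88)
  for (rep in 1:3) {
    even <- random_intervals(120, span = 30000L)
    odd <- random_intervals(120, span = 30000L)
    got <- intersect_consensus(even, odd)
    want <- brute_consensus(even, odd)
    expect_same_intervals(got, want)
  }
})

test_that("consensus is commutative, idempotent, and bp-bounded", {
  set.seed(99)
  even <- random_intervals(80, span = 20000L)
  odd <- random_intervals(80, span = 20000L)
  ab <- intersect_consensus(even, odd)
  ba <- intersect_consensus(odd, even)
  expect_same_intervals(ab, ba)
  # EVEN = ODD reduces to the merged self-overlap of the input
  self <- intersect_consensus(even, even)
  expect_same_intervals(self, intersect_consensus(self, self))
  bp <- function(x) sum(x$end - x$start)
  merged_bp <- function(x) bp(intersect_consensus(x, x))
  expect_lte(bp(ab), min(merged_bp(even), merged_bp(odd)))
})

test_that("peak q filtering applies before intersection when present", {
  pk <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                   name = c("a", "b"), q = c(0.01, 0.2))
  expect_equal(filter_peaks_q(pk, 0.05)$name, "a")
  pk$q <- NULL
  expect_equal(nrow(filter_peaks_q(pk, 0.05)), 2L)
})

test_that("peaks are assigned to the nearest TSS with the stated tie-break", {
  ann <- toy_annotation()
  cfg <- tiny_config()
  pk <- data.frame(chrom = "chr1", start = 9950L, end = 10050L, name = "p1")
  a <- annotate_peaks(pk, ann, cfg)
  expect_equal(a$target_gene_id, "gA")
  expect_equal(a$signed_distance_to_tss, 0L)
  expect_equal(a$feature_class, "promoter")
  # exactly equidistant TSSs resolve to the lexicographically smaller id
  ann2 <- ann
  ann2$tx_end[2] <- 43001L
  ann2$tss[2] <- 43000L  # midpoint 26500 is 16500 from both TSSs
  pk3 <- data.frame(chrom = "chr1", start = 26500L - 50L, end = 26500L + 50L)
  a3 <- annotate_peaks(pk3, ann2, cfg)
  expect_equal(abs(a3$midpoint - ann2$tss[1]), abs(a3$midpoint - ann2$tss[2]))
  expect_equal(a3$target_gene_id, "gA")
  # minus-strand orientation: downstream of gB's TSS means lower coordinates
  pk4 <- data.frame(chrom = "chr1", start = 42000L, end = 42100L)
  a4 <- annotate_peaks(pk4, ann, cfg)
  expect_equal(a4$target_gene_id, "gB")
  expect_gt(a4$signed_distance_to_tss, 0)
  # chromosome with no genes
  pk5 <- data.frame(chrom = "chrX", start = 0L, end = 100L)
  a5 <- annotate_peaks(pk5, ann, cfg)
  expect_true(is.na(a5$target_gene_id))
  expect_equal(a5$feature_class, "distal_intergenic")
})

test_that("feature classes follow midpoint precedence on a generated genome", {
  params <- small_params()
  gen <- generate_genome(params, seed = 5)
  cfg <- tiny_config()
  set.seed(10)
  pk <- random_intervals(150, chroms = names(gen$chrom_lengths),
                         span = params$chrom_length, max_width = 300L)
  got <- annotate_peaks(pk, gen$ann, cfg)
  # independent oracle: exhaustive scan over genes for target and class
  ann <- gen$ann
  for (i in seq_len(nrow(pk))) {
    mid <- (pk$start[i] + pk$end[i]) %/% 2L
    rows <- which(ann$chrom == pk$chrom[i])
    d <- abs(mid - ann$tss[rows])
    cand <- rows[d == min(d)]
    tgt <- cand[order(ann$gene_id[cand])][1]
    expect_equal(got$target_gene_id[i], ann$gene_id[tgt])
    in_feat <- function(col) any(vapply(rows, function(r) {
      m <- ann[[col]][[r]]
      !is.null(m) && nrow(m) > 0 && any(mid >= m[, 1] & mid < m[, 2])
    }, logical(1)))
    cls <- if (min(d) <= cfg$tss_window_bp) "promoter"
    else if (in_feat("utr5")) "five_prime_utr"
    else if (in_feat("utr3")) "three_prime_utr"
    else if (in_feat("exons")) "exon"
    else if (any(mid >= ann$tx_start[rows] & mid < ann$tx_end[rows])) "intron"
    else {
      end3 <- ifelse(ann$strand[rows] == "+", ann$tx_end[rows],
                     ann$tx_start[rows])
      past <- ifelse(ann$strand[rows] == "+", mid - end3, end3 - 1L - mid)
      if (any(past > 0 & past <= cfg$tss_window_bp)) "downstream"
      else "distal_intergenic"
    }
    expect_equal(got$feature_class[i], cls)
  }
})

test_that("feature distribution sums to one and ignores input order", {
  ann <- data.frame(feature_class = c(rep("intron", 6), rep("promoter", 3),
                                      "distal_intergenic"))
  fr <- feature_distribution(ann)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(fr["intron"]), 0.6)
  expect_equal(unname(fr["promoter"]), 0.3)
  expect_equal(feature_distribution(ann[sample(nrow(ann)), , drop = FALSE]),
               fr)
  expect_error(feature_distribution(ann[0, , drop = FALSE]), "no annotated")
  all_intron <- data.frame(feature_class = rep("intron", 4))
  expect_equal(unname(feature_distribution(all_intron)["intron"]), 1)
})

test_that("metaprofile averages binned coverage with strand awareness", {
  cov <- list(chr1 = rep(2.5, 4000))
  anchors <- data.frame(chrom = "chr1", pos = 2000L, strand = "+")
  mp <- metaprofile(cov, anchors, half_window_bp = 500L, n_bins = 10L)
  expect_equal(as.numeric(mp), rep(2.5, 10))
  # single anchor equals the binned window coverage
  cov2 <- list(chr1 = seq_len(4000) / 100)
  mp2 <- metaprofile(cov2, anchors, half_window_bp = 500L, n_bins = 10L)
  win <- cov2$chr1[1501:2500]
  expect_equal(as.numeric(mp2), colMeans(matrix(win, nrow = 100)))
  # minus-strand anchor reverses its window
  anchors_m <- data.frame(chrom = "chr1", pos = 2000L, strand = "-")
  mp3 <- metaprofile(cov2, anchors_m, half_window_bp = 500L, n_bins = 10L)
  expect_equal(as.numeric(mp3), rev(as.numeric(mp2)))
  # two unit pulses symmetric around the centre average to a two-bump profile
  # pulses at window indices 490 and 509, mirror images in [pos-500, pos+500)
  cov4 <- list(chr1 = numeric(4000))
  cov4$chr1[1990 + 1] <- 1
  cov4$chr1[2009 + 1] <- 1
  mp4 <- metaprofile(cov4, rbind(anchors, anchors), 500L, 100L)
  direct <- colMeans(matrix(cov4$chr1[1501:2500], nrow = 10))
  expect_equal(as.numeric(mp4), direct)
  expect_equal(as.numeric(mp4), rev(as.numeric(mp4)))
  # off-chromosome windows are truncated, flagged, excluded from missing bins
  anchors_edge <- data.frame(chrom = "chr1", pos = 100L, strand = "+")
  mp5 <- metaprofile(cov, rbind(anchors, anchors_edge), 500L, 10L)
  expect_equal(attr(mp5, "n_truncated"), 1L)
  expect_equal(as.numeric(mp5), rep(2.5, 10))
})
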