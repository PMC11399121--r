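test_that("log-odds scoring matches hand arithmetic and attains its maximum at consensus", {
  # rows equal to background score 0 for every k-mer
  flat <- new_pwm("flat", matrix(0.25, 3, 4), pseudocount = 0)
  for (k in c("AAA", "ACG", "TTT")) expect_equal(log_odds_score(flat, k), 0)
  # single-position PWM, uniform background
  p1 <- new_pwm("p1", matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4), pseudocount = 0)
  expect_equal(log_odds_score(p1, "A"), log2(0.7 / 0.25))
  expect_equal(log_odds_score(p1, "C"), log2(0.1 / 0.25))
  expect_equal(log_odds_score(p1, "N"), 0)
  expect_error(log_odds_score(p1, "X"), "invalid character")
  expect_error(log_odds_score(p1, "AC"), "length")
  # consensus maximizes the score over the full k-mer space (L = 5)
  set.seed(4)
  pwm <- make_pwms("tf", synth_params(pwm_length = 5L), seed = 4)$tf
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 5)))
  scores <- vapply(kmers, function(k) log_odds_score(pwm, k), numeric(1))
  expect_equal(max(scores),
               log_odds_score(pwm, pwm_consensus(pwm)))
})

test_that("exact p-values agree with exhaustive enumeration and are monotone", {
  set.seed(9)
  pwm <- make_pwms("tf", synth_params(pwm_length = 5L, pwm_major = 0.8),
                   seed = 9)$tf
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 5)))
  # enumerate with the same eps discretization the scanner uses
  ints <- vapply(kmers, function(k) {
    idx <- match(strsplit(k, "")[[1]], c("A", "C", "G", "T"))
    sum(pwm$ints[cbind(1:5, idx)])
  }, numeric(1))
  probs <- rep(1 / 4^5, length(kmers))
  for (s_int in sort(unique(ints))) {
    p_enum <- sum(probs[ints >= s_int])
    p_dp <- pwm_pvalue(pwm, s_int * pwm$eps)
    expect_equal(p_dp, p_enum, tolerance = 1e-9)
  }
  # boundaries
  expect_equal(pwm_pvalue(pwm, min(ints) * pwm$eps - 1), 1)
  expect_equal(pwm_pvalue(pwm, max(ints) * pwm$eps + 1), 0)
  # non-increasing in score
  grid <- seq(min(ints) * pwm$eps - 0.5, max(ints) * pwm$eps + 0.5,
              length.out = 50)
  pv <- vapply(grid, function(s) pwm_pvalue(pwm, s), numeric(1))
  expect_true(all(diff(pv) <= 1e-15))
})

test_that("promoter windows follow strand-aware geometry", {
  cfg <- tiny_config()  # 1500 up, 500 down
  chrom <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  genome <- c(chr1 = chrom)
  gplus <- data.frame(gene_id = "gp", chrom = "chr1", strand = "+",
                      tss = 5000L, stringsAsFactors = FALSE)
  w <- extract_promoter_window(gplus, genome, cfg)
  expect_equal(w$genomic_start, 3500L)
  expect_equal(w$genomic_end, 5500L)
  expect_equal(w$off_start, -1500L)
  expect_equal(w$seq, substr(chrom, 3501, 5500))
  expect_false(w$truncated)
  gminus <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-",
                       tss = 5000L, stringsAsFactors = FALSE)
  wm <- extract_promoter_window(gminus, genome, cfg)
  expect_equal(wm$genomic_start, 4501L)
  expect_equal(wm$genomic_end, 6501L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 4502, 6501))))
  expect_equal(wm$seq, rc)
  # base at offset 0 is the TSS base on the gene strand
  tss_base <- substr(chrom, 5001, 5001)
  expect_equal(substr(w$seq, 1501, 1501), tss_base)
  expect_equal(substr(wm$seq, 1501, 1501),
               chartr("ACGT", "TGCA", tss_base))
  # truncation at the chromosome end is flagged
  gedge <- data.frame(gene_id = "ge", chrom = "chr1", strand = "+",
                      tss = 400L, stringsAsFactors = FALSE)
  we <- extract_promoter_window(gedge, genome, cfg)
  expect_true(we$truncated)
  expect_equal(we$genomic_start, 0L)
})

test_that("scanning recovers planted consensus and mirrors reverse complements", {
  cfg <- tiny_config()
  set.seed(21)
  pwm <- make_pwms("TF1", synth_params(), seed = 21)$TF1
  L <- pwm_length(pwm)
  cons <- pwm_consensus(pwm)
  mkwin <- function(gene_id, seq) list(gene_id = gene_id, seq = seq,
                                       off_start = -1500L)
  bgseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  seq1 <- bgseq(2000)
  offset <- -200L
  pos <- offset + 1500L  # 0-based within-window start
  substr(seq1, pos + 1L, pos + L) <- cons
  scan <- scan_windows(list(TF1 = pwm), list(mkwin("gX", seq1)), cfg,
                       keep_all = TRUE)
  hit <- scan$hits[scan$hits$strand == "+", ]
  expect_true(any(hit$gene_id == "gX" & hit$offset == offset))
  expect_true(all(scan$hits$q < cfg$motif_q))
  # q-values are BH over the full scored table per PWM
  expect_equal(scan$all$q, bh_adjust(scan$all$p))
  expect_equal(unname(scan$n_scored["TF1"]), nrow(scan$all))
  # scanning the reverse complement mirrors offsets and strands
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq1)))
  scan_rc <- scan_windows(list(TF1 = pwm), list(mkwin("gX", rc)), cfg)
  h1 <- scan$hits
  h2 <- scan_rc$hits
  expect_equal(nrow(h1), nrow(h2))
  # a + hit at window position p maps to a - hit at mirrored position
  win_len <- nchar(seq1)
  mirror <- function(off, strand) {
    start <- off + 1500L
    m <- win_len - start - L
    cbind(m - 1500L, ifelse(strand == "+", "-", "+"))
  }
  m1 <- mirror(h1$offset, h1$strand)
  key1 <- sort(paste(m1[, 1], m1[, 2], round(h1$score, 6)))
  key2 <- sort(paste(h2$offset, h2$strand, round(h2$score, 6)))
  expect_equal(key1, key2)
  # a PWM longer than its window is skipped with a warning
  expect_warning(
    empty <- scan_windows(list(TF1 = pwm), list(mkwin("tiny", "ACGT")), cfg),
    "skipped")
  expect_equal(nrow(empty$hits), 0L)
})

test_that("background-only windows yield no hits at the default threshold", {
  cfg <- tiny_config()
  set.seed(33)
  pwm <- make_pwms("TF1", synth_params(), seed = 33)$TF1
  wins <- lapply(1:20, function(i)
    list(gene_id = paste0("g", i),
         seq = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""),
         off_start = -1500L))
  scan <- scan_windows(list(TF1 = pwm), wins, cfg)
  expect_equal(nrow(scan$hits), 0L)
})
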