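# Shared fixtures and independent oracles used across test files.

tiny_config <- function(...) pipeline_config(...)

# small simulator parameterization used where scale is irrelevant
small_params <- function(...) {
  synth_params(
    n_genes = 80L, chrom_length = 300000L,
    n_tfs = 8L, n_cofactors = 4L,
    n_direct = 20L, n_tf_direct = 4L, n_cofactor_direct = 2L,
    n_bound_only = 6L, n_incoherent = 1L,
    downstream_range = c(3L, 8L), coop_range = c(1L, 2L),
    comm_core_size = 5L, chip_extra = 10L, tf_deg_extra = 12L,
    panel_samples = 12L, ...
  )
}

# hand-built two-gene annotation on one chromosome, matching read_gtf() shape
toy_annotation <- function() {
  ann <- data.frame(
    gene_id = c("gA", "gB"), gene_name = c("geneA", "geneB"),
    chrom = "chr1", strand = c("+", "-"),
    tx_start = c(10000L, 40000L), tx_end = c(13000L, 43000L),
    stringsAsFactors = FALSE
  )
  ann$tss <- ifelse(ann$strand == "+", ann$tx_start, ann$tx_end - 1L)
  ann$exons <- list(
    rbind(c(10000L, 10500L), c(12000L, 13000L)),
    rbind(c(40000L, 41000L), c(42500L, 43000L))
  )
  ann$utr5 <- list(cbind(10000L, 10150L), cbind(42850L, 43000L))
  ann$utr3 <- list(cbind(12850L, 13000L), cbind(40000L, 40150L))
  rownames(ann) <- ann$gene_id
  ann
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 100000L,
                             max_width = 500L) {
  start <- sample.int(span - max_width, n, replace = TRUE) - 1L
  w <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w,
             name = sprintf("iv_%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# O(n^2) consensus oracle: all pairwise intersections, merged per chromosome
brute_consensus <- function(even, odd) {
  segs <- list()
  for (i in seq_len(nrow(even))) for (j in seq_len(nrow(odd))) {
    if (even$chrom[i] != odd$chrom[j]) next
    s <- max(even$start[i], odd$start[j])
    e <- min(even$end[i], odd$end[j])
    if (s < e) segs[[length(segs) + 1L]] <-
        data.frame(chrom = even$chrom[i], start = s, end = e)
  }
  if (!length(segs)) return(data.frame(chrom = character(),
                                       start = integer(), end = integer()))
  d <- do.call(rbind, segs)
  d <- d[order(d$chrom, d$start, d$end), ]
  out <- list()
  for (ch in unique(d$chrom)) {
    x <- d[d$chrom == ch, ]
    cur_s <- x$start[1]; cur_e <- x$end[1]
    for (k in seq_len(nrow(x))[-1]) {
      if (x$start[k] <= cur_e) cur_e <- max(cur_e, x$end[k])
      else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                              end = cur_e)
        cur_s <- x$start[k]; cur_e <- x$end[k]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                          end = cur_e)
  }
  d <- do.call(rbind, out)
  d[order(d$chrom, d$start), ]
}

# independent BH step-up implementation
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force upper hypergeometric tail
brute_hyper_tail <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

expect_same_intervals <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(as.character(a$chrom), as.character(b$chrom))
  expect_equal(as.integer(a$start), as.integer(b$start))
  expect_equal(as.integer(a$end), as.integer(b$end))
}
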