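test_that("genome generation is deterministic and structurally sound", {
  params <- small_params()
  g1 <- generate_genome(params, seed = 3)
  g2 <- generate_genome(params, seed = 3)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$ann$tx_start, g2$ann$tx_start)
  expect_equal(nrow(g1$ann), params$n_genes)
  # exhaustive containment scan: every exon inside its gene bounds
  for (i in seq_len(nrow(g1$ann))) {
    ex <- g1$ann$exons[[i]]
    expect_true(all(ex[, 1] >= g1$ann$tx_start[i]))
    expect_true(all(ex[, 2] <= g1$ann$tx_end[i]))
    expect_true(all(ex[, 1] < ex[, 2]))
    expect_gte(nrow(ex), 1L)
  }
  # TSS convention by strand
  plus <- g1$ann$strand == "+"
  expect_equal(g1$ann$tss[plus], g1$ann$tx_start[plus])
  expect_equal(g1$ann$tss[!plus], g1$ann$tx_end[!plus] - 1L)
  # genes non-overlapping within a chromosome
  for (ch in unique(g1$ann$chrom)) {
    a <- g1$ann[g1$ann$chrom == ch, ]
    a <- a[order(a$tx_start), ]
    expect_true(all(utils::head(a$tx_end, -1) <= utils::tail(a$tx_start, -1)))
  }
  expect_error(generate_genome(small_params(chrom_length = 10000L), 1),
               "infeasible packing")
})

test_that("planted motifs appear verbatim at their recorded offsets", {
  params <- small_params()
  cfg <- tiny_config()
  s <- 14L
  gen <- generate_genome(params, s)
  truth <- make_truth(gen, params, s)
  pwms <- make_pwms(names(truth$tf_layer), params, s)
  pl <- plant_motifs(gen$genome, truth, pwms, gen$ann, cfg, s)
  expect_gt(nrow(pl$motifs), 0)
  revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (i in seq_len(nrow(pl$motifs))) {
    rec <- pl$motifs[i, ]
    win <- extract_promoter_window(gen$ann[rec$gene_id, ], pl$genome, cfg)
    L <- pwm_length(pwms[[rec$tf_id]])
    start <- rec$offset - win$off_start + 1L
    sub <- substr(win$seq, start, start + L - 1L)
    cons <- pwm_consensus(pwms[[rec$tf_id]])
    expect_equal(sub, if (rec$strand == "+") cons else revcomp(cons))
    expect_true(rec$offset >= -cfg$motif_upstream_bp)
    expect_lt(rec$offset, cfg$motif_downstream_bp)
  }
  # an empty TF layer leaves the genome untouched
  truth0 <- truth
  truth0$tf_layer <- list()
  pl0 <- plant_motifs(gen$genome, truth0, pwms, gen$ann, cfg, s)
  expect_identical(pl0$genome, gen$genome)
  expect_equal(nrow(pl0$motifs), 0L)
})

test_that("planted truth satisfies its structural invariants", {
  params <- small_params()
  truth <- make_truth(generate_genome(params, 8), params, 8)
  expect_length(intersect(truth$direct_target_ids, truth$indirect_target_ids),
                0)
  expect_true(all(names(truth$tf_layer) %in% truth$direct_target_ids))
  downstream_all <- unlist(lapply(truth$tf_layer, `[[`, "downstream"))
  expect_setequal(truth$indirect_target_ids, downstream_all)
  # every coop target is itself direct
  coop_all <- unlist(lapply(truth$tf_layer, `[[`, "coop"))
  expect_true(all(coop_all %in% truth$direct_target_ids))
  # comm flag is the AND of the four memberships
  fl <- truth$comm_flags
  expect_equal(fl$comm, fl$lnc_direct_a & fl$tf_direct_a & fl$lnc_deg_b &
                 fl$tf_deg_b)
  expect_true(all(truth$comm_core_ids %in% fl$gene_id[fl$comm]))
})

test_that("simulated counts follow the requested NB model", {
  params <- small_params()
  gen <- generate_genome(params, 6)
  truth <- make_truth(gen, params, 6)
  sim <- simulate_counts(truth, params, "model_a", 6)
  expect_true(all(sim$counts >= 0))
  expect_true(is.integer(sim$counts))
  expect_identical(simulate_counts(truth, params, "model_a", 6)$counts,
                   sim$counts)
  # zero dispersion collapses to Poisson: variance ~ mean on high-mean genes
  flat_truth <- list(
    baseline_mean = setNames(rep(5000, 300), sprintf("g%03d", 1:300)),
    planted_effects = matrix(0, 300, 2,
                             dimnames = list(sprintf("g%03d", 1:300),
                                             c("model_a", "model_b"))))
  p0 <- synth_params(dispersion = 0, replicates = 30L, libsize_sdlog = 0)
  s0 <- simulate_counts(flat_truth, p0, "model_a", 2)
  ratio <- apply(s0$counts, 1, var) / rowMeans(s0$counts)
  expect_gt(mean(ratio), 0.8)
  expect_lt(mean(ratio), 1.2)
  # all-null simulation: two-group mean log-ratio centred at zero
  p1 <- synth_params(dispersion = 0.05, replicates = 3L, libsize_sdlog = 0)
  big_ids <- sprintf("g%05d", 1:10000)
  big_truth <- list(
    baseline_mean = setNames(rep(500, 10000), big_ids),
    planted_effects = matrix(0, 10000, 2,
                             dimnames = list(big_ids,
                                             c("model_a", "model_b"))))
  s1 <- simulate_counts(big_truth, p1, "model_a", 3)
  kd <- s1$condition == "knockdown"
  lr <- log2(rowMeans(s1$counts[, kd]) + 0.5) -
    log2(rowMeans(s1$counts[, !kd]) + 0.5)
  expect_lt(abs(median(lr)), 0.02)
  # planted effect -1 at mu = 1000: KD/control mean ratio near 0.5
  eff_ids <- sprintf("e%03d", 1:200)
  eff_truth <- list(
    baseline_mean = setNames(rep(1000, 200), eff_ids),
    planted_effects = matrix(c(rep(-1, 200), rep(0, 200)), 200, 2,
                             dimnames = list(eff_ids,
                                             c("model_a", "model_b"))))
  p2 <- synth_params(dispersion = 0.05, replicates = 50L, libsize_sdlog = 0)
  s2 <- simulate_counts(eff_truth, p2, "model_a", 4)
  kd2 <- s2$condition == "knockdown"
  rat <- rowMeans(s2$counts[, kd2]) / rowMeans(s2$counts[, !kd2])
  expect_gt(mean(rat), 0.45)
  expect_lt(mean(rat), 0.55)
})

test_that("dual-probe peak simulation honours its noiseless and degenerate limits", {
  params <- small_params(jitter_bp = 0L, detect_prob = 1, noise_rate = 0)
  gen <- generate_genome(params, 9)
  truth <- make_truth(gen, params, 9)
  chirp <- simulate_chirp_peaks(truth, gen$chrom_lengths, params, 9)
  sites <- truth$true_binding_sites[order(truth$true_binding_sites$chrom,
                                          truth$true_binding_sites$start), ]
  expect_same_intervals(chirp$even, sites)
  expect_same_intervals(chirp$odd, sites)
  # truth sites map into the emitted files under the noiseless config
  cons <- intersect_consensus(chirp$even, chirp$odd)
  expect_equal(nrow(cons), nrow(sites))
  p0 <- small_params(detect_prob = 0, noise_rate = 0)
  chirp0 <- simulate_chirp_peaks(truth, gen$chrom_lengths, p0, 9)
  expect_equal(nrow(chirp0$even), 0L)
  expect_equal(nrow(chirp0$odd), 0L)
})

test_that("coverage tracks are bumps over background with the right maxima", {
  params <- small_params()
  lens <- c(chr1 = 50000L)
  flat <- simulate_coverage(data.frame(chrom = character(), start = integer(),
                                       end = integer()), lens, params)
  expect_true(all(flat$value == params$coverage_background))
  pk <- data.frame(chrom = "chr1", start = 24800L, end = 25200L)
  tr <- simulate_coverage(pk, lens, params)
  expect_equal(tr$start[which.max(tr$value)], 25000L - params$coverage_bin)
  expect_true(all(tr$value >= params$coverage_background))
  # metaprofile over the peak midpoint peaks at the centre bin
  f <- tempfile(fileext = ".bedGraph")
  getFromNamespace("write_bedgraph", "chirpnet")(tr, f)
  cov <- read_bedgraph(f, lens)
  mp <- metaprofile(cov, data.frame(chrom = "chr1", pos = 25000L,
                                    strand = "+"),
                    half_window_bp = 2000L, n_bins = 40L)
  expect_true(which.max(mp) %in% c(20L, 21L))
})

test_that("the full study writes every input plus consistent truth tables", {
  dir <- tempfile("study_")
  params <- small_params()
  out <- simulate_study(dir, params, seed = 12, coverage = FALSE)
  for (f in unlist(out$paths)) expect_true(file.exists(f))
  tg <- read_table(file.path(dir, "truth", "truth_genes.tsv"))
  expect_equal(nrow(tg), params$n_genes)
  expect_equal(sum(tg$role == "direct"), params$n_direct)
  expect_equal(sum(tg$comm), sum(out$truth$comm_flags$comm))
  # emitted annotation reparses to the in-memory one
  ann <- read_gtf(out$paths$gtf)
  expect_equal(ann$gene_id, out$ann$gene_id)
  expect_equal(ann$tss, out$ann$tss)
  # determinism: a second run is byte-identical on key tables
  dir2 <- tempfile("study2_")
  simulate_study(dir2, params, seed = 12, coverage = FALSE)
  for (f in c("chirp_even.bed", "counts_model_a.tsv", "genes.gtf",
              "truth/truth_genes.tsv"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
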