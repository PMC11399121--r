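test_that("target classes partition the gene universe by binding and DE", {
  cfg <- tiny_config()
  deg <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    base_mean = 100, log2fc = c(1.2, -0.8, 0.1, 0.5), se = 0.2,
    stat = 1, p = c(0.001, 0.002, 0.9, 0.8),
    padj = c(0.004, 0.008, 0.95, 0.9),
    direction = c("up", "down", "ns", "ns"), stringsAsFactors = FALSE)
  ann <- data.frame(
    peak_name = c("p1", "p2"), chrom = "chr1", start = c(1L, 50L),
    end = c(10L, 60L), midpoint = c(5L, 55L),
    target_gene_id = c("g1", "g4"), signed_distance_to_tss = 0L,
    feature_class = "promoter", stringsAsFactors = FALSE)
  cls <- classify_targets(ann, deg, cfg)
  got <- setNames(cls$targets$class, cls$targets$gene_id)
  expect_equal(got[["g1"]], "RDG")        # DEG with an assigned peak
  expect_equal(got[["g2"]], "RIG")        # DEG without a peak
  expect_equal(got[["g4"]], "bound_only") # peak without DE
  expect_equal(got[["g3"]], "unchanged")
  expect_equal(sort(cls$targets$gene_id), c("g1", "g2", "g3", "g4"))
  expect_equal(cls$summary$n_deg, cls$summary$n_rdg + cls$summary$n_rig)
})

test_that("classification shares reproduce the published-scale arithmetic", {
  # a universe with 3471 DEGs of which 1190 carry peaks gives the printed
  # 34.28% / 65.72% split
  cfg <- tiny_config()
  n_deg <- 3471L
  n_rdg <- 1190L
  ids <- sprintf("G%05d", seq_len(4000L))
  deg <- data.frame(
    gene_id = ids, base_mean = 10,
    log2fc = rep(c(1, -1), length.out = 4000L), se = 0.1, stat = 5,
    p = c(rep(1e-6, n_deg), rep(0.9, 4000L - n_deg)),
    padj = c(rep(1e-4, n_deg), rep(0.95, 4000L - n_deg)),
    direction = "up", stringsAsFactors = FALSE)
  ann <- data.frame(
    peak_name = sprintf("p%04d", seq_len(n_rdg)), chrom = "chr1",
    start = 1L, end = 10L, midpoint = 5L,
    target_gene_id = ids[seq_len(n_rdg)],
    signed_distance_to_tss = 0L, feature_class = "promoter",
    stringsAsFactors = FALSE)
  s <- classify_targets(ann, deg, cfg)$summary
  expect_equal(s$n_deg, 3471L)
  expect_equal(s$n_rdg, 1190L)
  expect_equal(s$n_rig, 2281L)
  expect_equal(s$rdg_pct, 34.28)
  expect_equal(s$rig_pct, 65.72)
})

test_that("RDG-TF selection applies catalog, binding, and coherence filters", {
  cfg <- tiny_config()
  targets <- data.frame(
    gene_id = c("tf_ok", "tf_flip", "tf_unbound", "cof_ok", "other"),
    class = c("RDG", "RDG", "RIG", "RDG", "RDG"),
    de_direction = "down",
    log2fc = c(-1, -1, -1, 2, 1), padj = 0.01,
    n_peaks = c(1L, 1L, 0L, 1L, 1L), stringsAsFactors = FALSE)
  deg_b <- data.frame(
    gene_id = targets$gene_id, base_mean = 50,
    log2fc = c(-0.8, 0.9, -0.7, 1.5, 1), se = 0.1, stat = 1,
    p = 0.001, padj = c(0.01, 0.01, 0.01, 0.01, 0.5),
    direction = "down", stringsAsFactors = FALSE)
  catalog <- data.frame(
    gene_id = c("tf_ok", "tf_flip", "tf_unbound", "cof_ok", "tf_missing"),
    is_tf = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    is_cofactor = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_warning(tab <- identify_rdg_tfs(targets, deg_b, catalog, cfg),
                 "tf_missing")
  got <- setNames(tab$rdg_tf, tab$gene_id)
  expect_true(got[["tf_ok"]])        # down in both models, bound in A
  expect_false(got[["tf_flip"]])     # incoherent sign
  expect_false(got[["tf_unbound"]])  # not an RDG in A
  expect_true(got[["cof_ok"]])
  s <- attr(tab, "summary")
  expect_equal(s$n_tf_coherent, 1L)
  expect_equal(s$n_cofactor_coherent, 1L)
})

test_that("the planted TF layer is fully recovered in the noiseless limit", {
  params <- small_params(jitter_bp = 0L, detect_prob = 1, noise_rate = 0,
                         effect_range = c(1.5, 2), tf_effect_range = c(1.5, 2),
                         dispersion = 0.005)
  cfg <- tiny_config()
  s <- 2024L
  gen <- generate_genome(params, s)
  truth <- make_truth(gen, params, s)
  chirp <- simulate_chirp_peaks(truth, gen$chrom_lengths, params, s)
  cons <- intersect_consensus(chirp$even, chirp$odd)
  annot <- annotate_peaks(cons, gen$ann, cfg)
  de <- lapply(c(a = "model_a", b = "model_b"), function(m) {
    sim <- simulate_counts(truth, params, m, s)
    de_test(filter_low_counts(sim$counts, 10L), sim$condition,
            refine_size_factors = TRUE)
  })
  cls <- classify_targets(annot, de$a, cfg)
  catalog <- data.frame(gene_id = gen$ann$gene_id,
                        is_tf = gen$ann$gene_id %in% truth$tf_ids,
                        is_cofactor = gen$ann$gene_id %in% truth$cofactor_ids)
  tab <- suppressWarnings(identify_rdg_tfs(cls$targets, de$b, catalog, cfg))
  recovered <- tab$gene_id[tab$rdg_tf & tab$kind == "tf"]
  expect_true(all(names(truth$tf_layer) %in% recovered))
})

test_that("network edges require retained hits inside the common-DEG universe", {
  rdg_tfs <- data.frame(gene_id = c("TF1", "TF2"), kind = "tf",
                        rdg_tf = c(TRUE, TRUE), stringsAsFactors = FALSE)
  classes <- data.frame(gene_id = c("t1", "t2", "t3"),
                        class = c("RDG", "RIG", "RIG"),
                        stringsAsFactors = FALSE)
  hits <- data.frame(
    tf_id = c("TF1", "TF1", "TF1", "TF2"),
    gene_id = c("t1", "t1", "t3", "t2"),
    strand = "+", offset = c(-100L, -400L, -10L, -50L),
    score = 15, p = 1e-8, q = 1e-4, stringsAsFactors = FALSE)
  net <- build_network(rdg_tfs, hits, common_degs = c("t1", "t2"), classes)
  expect_equal(nrow(net$edges), 2L)  # t3 outside the universe; t1 dedup'd
  e <- net$edges[net$edges$source_tf_id == "TF1", ]
  expect_equal(e$target_gene_id, "t1")
  expect_equal(e$n_hits, 2L)
  expect_equal(e$target_class, "RDG")
  expect_true(all(net$edges$target_gene_id %in% c("t1", "t2")))
  # no hits at all: empty network
  net0 <- build_network(rdg_tfs, hits[0, ], c("t1"), classes)
  expect_equal(nrow(net0$edges), 0L)
})

test_that("the common direct-target core is order-invariant set logic", {
  comm <- common_direct_targets(c("a", "b", "c"), c("b", "c", "d"),
                                c("b", "c", "e"), c("c", "f", "b"))
  expect_setequal(comm$gene_ids, c("b", "c"))
  prov <- comm$provenance
  expect_true(all(prov$comm == (prov$lnc_direct_a & prov$tf_direct_a &
                                  prov$lnc_deg_b & prov$tf_deg_b)))
  # gene direct for both in A but missing one B list is excluded
  expect_false("d" %in% comm$gene_ids)
  # invariance to the order of intersection steps, on random collections
  set.seed(61)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:20) {
    ls <- replicate(4, sample(pool, sample(10:40, 1)), simplify = FALSE)
    ref <- Reduce(intersect, ls)
    for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
      got <- common_direct_targets(ls[[perm[1]]], ls[[perm[2]]],
                                   ls[[perm[3]]], ls[[perm[4]]])$gene_ids
      expect_setequal(got, ref)
    }
  }
})

test_that("rank correlation matches rank-then-Pearson with tie handling", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(inc = x, dec = -x, tied = c(1, 1, 2, 2, 3, 3))
  colnames(m) <- paste0("s", 1:6)
  sp <- spearman_matrix(m)
  expect_equal(sp$R["inc", "dec"], -1)
  expect_equal(unname(diag(sp$R)), rep(1, 3))
  # oracle: average ranks then Pearson
  r1 <- rank(m["inc", ]); r2 <- rank(m["tied", ])
  expect_equal(sp$R["inc", "tied"], cor(r1, r2))
  # t-approximation p-value
  R <- sp$R["inc", "tied"]
  tstat <- R * sqrt((6 - 2) / (1 - R^2))
  expect_equal(sp$p["inc", "tied"], 2 * pt(-abs(tstat), df = 4))
  expect_true(sp$significant["inc", "dec"])
  # constant genes are flagged with undefined correlations
  m2 <- rbind(m, flat = rep(2, 6))
  sp2 <- spearman_matrix(m2)
  expect_equal(sp2$constant_genes, "flat")
  expect_true(all(is.na(sp2$R["flat", ])))
  expect_error(spearman_matrix(m[, 1:3]), ">= 4 samples")
})
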