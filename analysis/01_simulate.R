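#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emulates the full input set of the integrative study: a toy genome and
# annotation, dual-probe ChIRP peak files, a cooperating-TF ChIP peak file,
# knockdown/control count matrices for two cell models, PWMs with planted
# promoter motifs, TF catalog, TF-knockdown DEG lists, gene sets, a tumor
# expression panel, and coverage tracks — together with the planted-truth
# tables everything downstream is scored against.

library(chirpnet)

seed <- 1L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 1L) seed <- as.integer(args[[1]])

study_dir <- file.path("results", "synthetic_study")
out <- simulate_study(study_dir, synth_params(), seed = seed,
                      coverage = TRUE)
cfg <- pipeline_config(random_seed = seed, paths = out$paths)
write_config(cfg, file.path("results", "pipeline_config.yaml"))

truth <- out$truth
message(sprintf("wrote synthetic study to %s", study_dir))
message(sprintf("  genes: %d, direct targets: %d (of which %d TFs), indirect: %d",
                nrow(out$ann), length(truth$direct_target_ids),
                length(truth$tf_layer), length(truth$indirect_target_ids)))
message(sprintf("  true ChIRP sites: %d, ChIP-bound genes: %d, planted comm core: %d",
                nrow(truth$true_binding_sites), length(truth$chip_gene_ids),
                sum(truth$comm_flags$comm)))
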