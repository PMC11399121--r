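#!/usr/bin/env Rscript
# Stage 3 — score the cascade against the planted truth.
#
# Compares the run's outputs with the simulator's truth tables: consensus
# recovery of true binding sites, RDG precision/recall, TF-layer recovery,
# network edge recall, and the common direct-target core; then repeats the
# measurement over independent seeds for stable statistics
# (recovery_study()) and writes both tables under results/.

library(chirpnet)

cfg <- read_config(file.path("results", "pipeline_config.yaml"))
truth_genes <- read_table(file.path("results", "synthetic_study", "truth",
                                    "truth_genes.tsv"))
targets <- read_table(file.path("results", "run", "target_classes.tsv"))
edges <- read_table(file.path("results", "run", "network_edges.tsv"))
truth_edges <- read_table(file.path("results", "synthetic_study", "truth",
                                    "truth_edges.tsv"))

direct <- truth_genes$gene_id[truth_genes$role == "direct"]
called <- targets$gene_id[targets$class == "RDG"]
tp <- length(intersect(called, direct))
single <- data.frame(
  rdg_precision = tp / length(called),
  rdg_recall = tp / length(direct),
  edge_recall = mean(paste(truth_edges$tf_id, truth_edges$target_gene_id) %in%
                       paste(edges$source_tf_id, edges$target_gene_id)))
write_table(single, file.path("results", "recovery_single_run.tsv"))
message(sprintf("this run: RDG precision %.3f, recall %.3f, edge recall %.3f",
                single$rdg_precision, single$rdg_recall, single$edge_recall))

rec <- recovery_study(n_seeds = 20L, seed = cfg$random_seed)
write_table(rec$per_seed, file.path("results", "recovery_per_seed.tsv"))
write_table(data.frame(metric = names(rec$means),
                       mean = as.numeric(rec$means)),
            file.path("results", "recovery_means.tsv"))
message(sprintf(paste0("20 seeds: consensus %.3f (expect %.3f), RDG P %.3f",
                       " / R %.3f, TF recall %.3f, edge recall %.3f"),
                rec$means[["consensus_rate"]], rec$expected_consensus_rate,
                rec$means[["rdg_precision"]], rec$means[["rdg_recall"]],
                rec$means[["tf_recall"]], rec$means[["edge_recall"]]))
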