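#!/usr/bin/env Rscript
# Stage 2 — run the integration cascade end-to-end.
#
# Consensus intersection of the EVEN/ODD probe sets, peak-to-gene annotation
# with the genomic feature distribution, NB differential testing in both
# cell models, RDG/RIG classification, RDG-TF selection with cross-model
# coherence, promoter scanning of the common-DEG universe, network assembly,
# ChIP integration into the common direct-target core, the TF correlation
# matrix, enrichment with term clustering, and coverage metaprofiles. Every
# stage output lands as a TSV under results/run/.

library(chirpnet)

cfg <- read_config(file.path("results", "pipeline_config.yaml"))
report <- run_pipeline(cfg, file.path("results", "run"))
print(report)
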