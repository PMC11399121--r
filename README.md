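# chirpnet

Integrative mapping of an enhancer-associated lncRNA's direct target
program from ChIRP-seq and CRISPRi-knockdown RNA-seq.

## The problem

An enhancer-associated lncRNA that acts on chromatin leaves two
genome-wide footprints: where it binds (ChIRP-seq, performed with two
independent antisense probe sets, EVEN and ODD, whose peak intersection
defines true binding) and what responds when it is silenced (knockdown
RNA-seq in two cell models). Neither alone separates **direct** targets —
bound *and* deregulated — from **indirect** ones deregulated through
downstream transcription factors. `chirpnet` implements that integration
as a reusable, tested cascade for analysts working on chromatin-associated
RNAs:

* consensus binding elements from dual-probe peak intersection
  (EVEN ∩ ODD, q-filtered, minimum overlap 1 bp);
* nearest-gene annotation by TSS distance with a ±3 kb promoter window and
  midpoint-precedence feature classes;
* an in-house negative-binomial Wald test (median-of-ratios normalization,
  method-of-moments dispersion `α̂ = max((s²−µ̂)/µ̂², 10⁻⁸)`, Student-t
  reference with n₁+n₂−2 df) at BH FDR 0.1;
* direct/indirect classification: RDG = DEG with ≥ 1 assigned consensus
  peak, RIG = DEG without binding, so |DEG| = |RDG| + |RIG|;
* the TF layer: catalog-flagged RDGs coherently deregulated (same fold
  change sign) in both cell models;
* PWM scanning of −1.5 kb/+0.5 kb promoter windows with **exact** p-values
  (dynamic programming over the discretized score distribution, BH q < 0.05
  per PWM across all scanned positions) and a hierarchical TF → RDG/RIG
  edge list restricted to the common-DEG universe;
* the common direct-target core shared with a cooperating TF's ChIP
  binding, by staged four-list intersection with per-gene provenance flags;
* hypergeometric over-representation with Jaccard term clustering,
  Spearman correlation matrices, coverage metaprofiles, NanoString-style
  panel normalization, and the ΔΔCt / % Input / fold-over-control assay
  formulas.

A first-class synthetic-data module (`simulate_study()`) emulates every
input with a planted two-layer truth (lncRNA → TFs → downstream genes, NB
count noise, jittered partially-detected dual-probe peaks, background
promoters with planted consensus motifs), so the whole cascade is
verifiable against known ground truth.

## Worked example

The analysis is organised as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate.R 1        # synthetic study, seed 1
Rscript analysis/02_run_cascade.R       # full cascade -> results/run/*.tsv
Rscript analysis/03_score_recovery.R    # score vs planted truth, 20 seeds
Rscript analysis/04_calibration.R       # NB-test calibration
Rscript analysis/05_reported_identities.R
```

`02_run_cascade.R` ends by printing the run report, here for seed 1:

```
chirpnet run report (results/run)
  consensus peaks: 134 (EVEN 184 / ODD 170)
  DEGs model A: 195 (up 134 / down 61); model B: 191; common: 187
  RDGs: 60 (30.77%), RIGs: 135 (69.23%)
  RDG-TFs: 8; network edges: 150; comm_DGs: 11
```

Reading it: of 195 knockdown-responsive genes in the discovery model, 60
carry a consensus binding element and are called direct targets (the
planted truth has exactly 60 direct targets); all 8 planted TF-layer
members pass the coherence filter; 150 promoter-motif edges connect them
to common DEGs; and 11 genes survive the four-way intersection with the
cooperating TF's binding and knockdown lists (15 planted — the deficit is
ChIP detection at 0.9 and model-B DE power). `03_score_recovery.R` then
reports, averaged over 20 independent seeds:

```
20 seeds: consensus 0.816 (expect 0.810), RDG P 0.959 / R 0.953,
TF recall 0.981, edge recall 1.000
```

— consensus site recovery sits on the detect_prob² = 0.81 expectation from
probe-set independence, direct-target classification runs at ~0.95
precision/recall under the default noise, and the scanning/network step
finds every planted edge whose endpoints survive the upstream stages.
`04_calibration.R` prints the test's type-I error at nominal 0.05 (0.0525
on an all-null 3 vs 3 simulation) and the mean estimated log2FC at a
planted effect of 2 (2.0015).

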