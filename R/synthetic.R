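#' Synthetic study parameters
#'
#' Defaults define the simulated study conditions: a toy genome of 2
#' chromosomes x 1 Mb carrying 300 non-overlapping genes; a catalog of 20
#' TFs and 10 transcription co-factors; a two-layer planted truth in which
#' the lncRNA directly binds and perturbs 60 genes (8 of them TFs) and the 8
#' TF-layer members each propagate the perturbation to 5-30 downstream
#' genes; negative-binomial counts for two cell models at 3 vs 3 replicates;
#' and jittered, partially detected dual-probe ChIRP peaks plus a
#' cooperating-TF ChIP experiment. See the methods vignette for the
#' rationale behind each default.
#'
#' @param ... Overrides for any default listed below.
#' @return Named list of parameters.
#' @export
synth_params <- function(...) {
  p <- list(
    n_chrom = 2L, chrom_length = 1000000L, n_genes = 300L,
    n_tfs = 20L, n_cofactors = 10L,
    n_direct = 60L, n_tf_direct = 8L, n_cofactor_direct = 4L,
    n_bound_only = 20L, n_incoherent = 2L,
    downstream_range = c(5L, 30L), coop_range = c(2L, 4L),
    effect_range = c(0.8, 2), tf_effect_range = c(1.2, 2),
    baseline_meanlog = log(300), baseline_sdlog = 1, baseline_floor = 50,
    dispersion = 0.02, dispersion_cap = 5,
    replicates = 3L, libsize_sdlog = 0.1,
    sites_per_direct = 2L, sites_per_tf_direct = 5L,
    site_width = c(200L, 400L),
    jitter_bp = 50L, detect_prob = 0.9, noise_rate = 20,
    pwm_length = 12L, pwm_major = 0.95,
    comm_core_size = 15L, chip_extra = 30L, tf_deg_extra = 40L,
    panel_samples = 40L,
    coverage_bin = 10L, shape_sd_bp = 150, coverage_background = 1,
    coverage_amplitude = 8
  )
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

#' Generate the toy genome and annotation
#'
#' Genes are laid out on a regular slot grid (non-overlapping, alternating
#' strands), each with 2-4 exons and terminal UTR features, and chromosome
#' sequence is i.i.d. uniform over A/C/G/T so the PWM scanning null is exact
#' by construction. The TSS is `tx_start` for plus-strand genes and
#' `tx_end - 1` for minus-strand genes.
#'
#' @param params From [synth_params()] (needs >= 2 chromosomes, >= 50 genes).
#' @param seed Integer seed.
#' @return List: `genome` (named character vector), `ann` (gene annotation
#'   as from [read_gtf()]), `chrom_lengths`.
#' @export
generate_genome <- function(params = synth_params(), seed = 1L) {
  stopifnot(params$n_chrom >= 2L, params$n_genes >= 50L)
  set.seed(substream_seed(seed, "genome"))
  per_chrom <- ceiling(params$n_genes / params$n_chrom)
  slot <- params$chrom_length %/% per_chrom
  if (slot < 6000L)
    stop("infeasible packing: ", params$n_genes, " genes need chromosomes of ",
         "at least ", per_chrom * 6000L, " bp")
  chroms <- paste0("chr", seq_len(params$n_chrom))
  genome <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), params$chrom_length, TRUE),
          collapse = ""), character(1))
  rows <- list()
  g <- 0L
  for (ci in seq_along(chroms)) {
    for (si in seq_len(per_chrom)) {
      if (g >= params$n_genes) break
      g <- g + 1L
      s0 <- (si - 1L) * slot
      strand <- if (g %% 2L == 1L) "+" else "-"
      body <- sample(1400:3000, 1L)
      if (strand == "+") {
        tx_start <- s0 + 2000L
        tx_end <- tx_start + body
      } else {
        tx_end <- s0 + slot - 2000L
        tx_start <- tx_end - body
      }
      n_ex <- sample(2:4, 1L)
      ex_len <- rep(300L, n_ex)
      spare <- body - sum(ex_len) - 100L * (n_ex - 1L)
      add <- diff(c(0, sort(sample(0:spare, n_ex - 1L, TRUE)), spare))
      ex_len <- ex_len + add
      in_len <- rep(100L, n_ex - 1L)
      starts <- tx_start + cumsum(c(0L, ex_len[-n_ex] + in_len))
      exons <- cbind(starts, starts + ex_len)
      first <- if (strand == "+") 1L else n_ex
      last <- if (strand == "+") n_ex else 1L
      utr5 <- if (strand == "+")
        cbind(exons[first, 1], exons[first, 1] + 150L)
      else cbind(exons[first, 2] - 150L, exons[first, 2])
      utr3 <- if (strand == "+")
        cbind(exons[last, 2] - 150L, exons[last, 2])
      else cbind(exons[last, 1], exons[last, 1] + 150L)
      rows[[g]] <- list(
        gene_id = sprintf("SYNG%04d", g), gene_name = sprintf("Syn%04d", g),
        chrom = chroms[ci], strand = strand,
        tx_start = tx_start, tx_end = tx_end,
        tss = if (strand == "+") tx_start else tx_end - 1L,
        exons = exons, utr5 = utr5, utr3 = utr3
      )
    }
  }
  ann <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    gene_name = vapply(rows, `[[`, character(1), "gene_name"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    tx_start = as.integer(vapply(rows, `[[`, numeric(1), "tx_start")),
    tx_end = as.integer(vapply(rows, `[[`, numeric(1), "tx_end")),
    tss = as.integer(vapply(rows, `[[`, numeric(1), "tss")),
    stringsAsFactors = FALSE
  )
  ann$exons <- lapply(rows, `[[`, "exons")
  ann$utr5 <- lapply(rows, `[[`, "utr5")
  ann$utr3 <- lapply(rows, `[[`, "utr3")
  rownames(ann) <- ann$gene_id
  list(genome = genome, ann = ann,
       chrom_lengths = stats::setNames(rep(params$chrom_length,
                                           params$n_chrom), chroms))
}

#' Plant the two-layer regulatory truth
#'
#' Assigns gene roles (direct / indirect / bound-only / null), the TF layer
#' with its downstream genes, per-model planted log2 fold changes (same sign
#' in both cell models except for a small incoherent set), true ChIRP
#' binding sites, cooperating-TF ChIP sites, and the four membership flags
#' from which the common direct-target core follows.
#'
#' @param gen Output of [generate_genome()].
#' @param params From [synth_params()].
#' @param seed Integer seed.
#' @return A `chirpnet_truth` list; see fields in the implementation and the
#'   tables written by [simulate_study()].
#' @export
make_truth <- function(gen, params = synth_params(), seed = 1L) {
  set.seed(substream_seed(seed, "truth"))
  ann <- gen$ann
  ids <- ann$gene_id
  n <- length(ids)
  tf_ids <- sample(ids, params$n_tfs)
  cof_ids <- sample(setdiff(ids, tf_ids), params$n_cofactors)
  tf_direct <- sample(tf_ids, params$n_tf_direct)
  cof_direct <- sample(cof_ids, params$n_cofactor_direct)
  other_direct <- sample(setdiff(ids, c(tf_ids, cof_ids)),
                         params$n_direct - params$n_tf_direct -
                           params$n_cofactor_direct)
  direct <- c(tf_direct, cof_direct, other_direct)
  pool <- setdiff(ids, direct)
  bound_only <- sample(pool, params$n_bound_only)
  pool <- setdiff(pool, bound_only)

  sign_of <- stats::setNames(sample(c(-1, 1), n, TRUE), ids)
  eff <- matrix(0, n, 2, dimnames = list(ids, c("model_a", "model_b")))
  draw_mag <- function(k, range) stats::runif(k, range[1], range[2])
  eff[direct, 1] <- sign_of[direct] * draw_mag(length(direct), params$effect_range)
  eff[direct, 2] <- sign_of[direct] * draw_mag(length(direct), params$effect_range)
  eff[tf_direct, 1] <- sign_of[tf_direct] * draw_mag(length(tf_direct),
                                                     params$tf_effect_range)
  eff[tf_direct, 2] <- sign_of[tf_direct] * draw_mag(length(tf_direct),
                                                     params$tf_effect_range)
  incoherent <- sample(other_direct, params$n_incoherent)
  eff[incoherent, 2] <- -eff[incoherent, 2]

  tf_layer <- list()
  indirect <- character(0)
  for (tf in tf_direct) {
    n_down <- sample(params$downstream_range[1]:params$downstream_range[2], 1L)
    n_down <- min(n_down, length(pool))
    down <- if (n_down > 0L) sample(pool, n_down) else character(0)
    pool <- setdiff(pool, down)
    n_coop <- sample(params$coop_range[1]:params$coop_range[2], 1L)
    coop <- sample(setdiff(direct, tf), n_coop)
    tf_layer[[tf]] <- list(sign = unname(sign_of[tf]),
                           downstream = down, coop = coop)
    indirect <- c(indirect, down)
    eff[down, 1] <- sign_of[tf] * draw_mag(length(down), params$effect_range)
    eff[down, 2] <- sign_of[tf] * draw_mag(length(down), params$effect_range)
  }

  # Sites sit on a per-gene grid (700 bp pitch, from 1.7 kb upstream of the
  # TSS into the gene body) with small positional noise, which keeps every
  # site assigned to its own gene's TSS and keeps detections of distinct
  # sites from overlapping after endpoint jitter, so per-site consensus
  # recovery stays an independent Bernoulli(detect_prob^2) draw.
  place_sites <- function(gene_rows, n_sites) {
    out <- list()
    for (i in seq_len(nrow(gene_rows))) {
      gr <- gene_rows[i, ]
      body <- gr$tx_end - gr$tx_start
      n_slots <- (body - 200L + 1700L) %/% 700L + 1L
      m <- n_sites[i]
      stopifnot(m <= n_slots)
      slots <- sort(sample.int(n_slots, m)) - 1L
      off <- -1700L + slots * 700L + sample(-50:50, m, TRUE)
      mid <- if (gr$strand == "+") gr$tss + off else gr$tss - off
      w <- sample(params$site_width[1]:params$site_width[2], m, TRUE)
      start <- pmax(0L, as.integer(mid - w %/% 2L))
      out[[i]] <- data.frame(
        chrom = gr$chrom, start = start, end = start + w,
        gene_id = gr$gene_id, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  n_sites <- ifelse(c(direct, bound_only) %in% tf_direct,
                    params$sites_per_tf_direct, params$sites_per_direct)
  n_sites[match(bound_only, c(direct, bound_only))] <- 1L
  sites <- place_sites(ann[c(direct, bound_only), ], n_sites)
  sites$name <- sprintf("site_%04d", seq_len(nrow(sites)))

  # cooperating TF (ChIP): binds a core of direct targets plus extras
  coherent_direct <- setdiff(direct, incoherent)
  comm_core <- sample(setdiff(coherent_direct, tf_direct),
                      params$comm_core_size)
  chip_genes <- unique(c(comm_core,
                         sample(setdiff(ids, comm_core), params$chip_extra)))
  chip_rows <- ann[chip_genes, ]
  chip_sites <- place_sites(chip_rows, rep(1L, nrow(chip_rows)))
  chip_sites$name <- sprintf("chip_site_%04d", seq_len(nrow(chip_sites)))

  tf_deg_a <- unique(c(comm_core, sample(setdiff(ids, comm_core),
                                         params$tf_deg_extra)))
  tf_deg_b <- unique(c(comm_core, sample(setdiff(ids, comm_core),
                                         params$tf_deg_extra)))

  flags <- data.frame(
    gene_id = ids,
    lnc_direct_a = ids %in% direct,
    tf_direct_a = ids %in% chip_genes & ids %in% tf_deg_a,
    lnc_deg_b = eff[, "model_b"] != 0,
    tf_deg_b = ids %in% tf_deg_b,
    stringsAsFactors = FALSE
  )
  flags$comm <- flags$lnc_direct_a & flags$tf_direct_a &
    flags$lnc_deg_b & flags$tf_deg_b

  role <- rep("null", n)
  role[ids %in% direct] <- "direct"
  role[ids %in% indirect] <- "indirect"
  role[ids %in% bound_only] <- "bound_only"

  baseline <- pmax(stats::rlnorm(n, params$baseline_meanlog,
                                 params$baseline_sdlog),
                   params$baseline_floor)
  names(baseline) <- ids

  truth <- list(
    direct_target_ids = direct, indirect_target_ids = indirect,
    bound_only_ids = bound_only, tf_ids = tf_ids, cofactor_ids = cof_ids,
    tf_layer = tf_layer, incoherent_ids = incoherent,
    planted_effects = eff, baseline_mean = baseline, role = stats::setNames(role, ids),
    true_binding_sites = sites, chip_sites = chip_sites,
    chip_gene_ids = chip_genes, comm_core_ids = comm_core,
    tf_deg_a_ids = tf_deg_a, tf_deg_b_ids = tf_deg_b, comm_flags = flags,
    noise_peak_rate = params$noise_rate,
    planted_motif_positions = NULL
  )
  class(truth) <- "chirpnet_truth"
  truth
}

#' Build well-separated synthetic PWMs
#'
#' One motif per TF-layer member: a random consensus of `pwm_length` bases
#' with probability `pwm_major` at each consensus base (~19 bits of total
#' information at the defaults).
#'
#' @param tf_ids Character vector of TF ids.
#' @param params From [synth_params()].
#' @param seed Integer seed.
#' @return Named list of [new_pwm()] objects.
#' @export
make_pwms <- function(tf_ids, params = synth_params(), seed = 1L) {
  set.seed(substream_seed(seed, "pwms"))
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (tf in tf_ids) {
    cons <- sample(4L, params$pwm_length, TRUE)
    mat <- matrix((1 - params$pwm_major) / 3, params$pwm_length, 4L)
    mat[cbind(seq_len(params$pwm_length), cons)] <- params$pwm_major
    colnames(mat) <- bases
    out[[tf]] <- new_pwm(tf, mat)
  }
  out
}

#' Plant motif consensus sequences in promoter windows
#'
#' For every TF-layer edge the TF's consensus is written into the target's
#' promoter window at a uniformly drawn offset in
#' `[-motif_upstream_bp, motif_downstream_bp - L]`, on a random strand;
#' overlaps with previously planted motifs in the same window are re-drawn
#' (bounded retries).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param truth From [make_truth()] (uses `tf_layer`).
#' @param pwms From [make_pwms()].
#' @param ann Gene annotation.
#' @param config A [pipeline_config()] (window geometry).
#' @param seed Integer seed.
#' @param max_retry Retries per motif before failing.
#' @return List: mutated `genome` and `motifs` data frame
#'   (`tf_id`, `gene_id`, `offset`, `strand`).
#' @export
plant_motifs <- function(genome, truth, pwms, ann, config, seed = 1L,
                         max_retry = 50L) {
  set.seed(substream_seed(seed, "plant"))
  up <- config$motif_upstream_bp
  dn <- config$motif_downstream_bp
  occupied <- list()
  recs <- list()
  revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (tf in names(truth$tf_layer)) {
    pwm <- pwms[[tf]]
    if (is.null(pwm)) next
    L <- pwm_length(pwm)
    stopifnot(L <= up + dn)
    cons <- pwm_consensus(pwm)
    targets <- c(truth$tf_layer[[tf]]$downstream, truth$tf_layer[[tf]]$coop)
    for (g in targets) {
      gr <- ann[g, ]
      placed <- FALSE
      for (try in seq_len(max_retry)) {
        off <- sample(seq.int(-up, dn - L), 1L)
        span <- c(off, off + L - 1L)
        prev <- occupied[[g]]
        clash <- !is.null(prev) &&
          any(span[1] <= prev[, 2] & span[2] >= prev[, 1])
        if (clash) next
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") cons else revcomp(cons)
        # map window offsets to genomic coordinates and write the insert
        if (gr$strand == "+") {
          g_lo <- gr$tss + off                       # 0-based
          genomic_ins <- ins
        } else {
          g_lo <- gr$tss - off - L + 1L
          genomic_ins <- revcomp(ins)
        }
        substr(genome[[gr$chrom]], g_lo + 1L, g_lo + L) <- genomic_ins
        occupied[[g]] <- rbind(prev, span)
        recs[[length(recs) + 1L]] <- data.frame(
          tf_id = tf, gene_id = g, offset = off, strand = strand,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place motif for ", tf, " in promoter of ", g,
             " after ", max_retry, " retries")
    }
  }
  motifs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(tf_id = character(), gene_id = character(),
               offset = integer(), strand = character())
  list(genome = genome, motifs = motifs)
}

#' Simulate NB count matrices for one cell model
#'
#' Control means are the per-gene baselines; knockdown means are scaled by
#' `2^(planted effect)` before noise. Counts are negative binomial with
#' variance `mu + dispersion * mu^2` and per-sample library-size factors.
#'
#' @param truth From [make_truth()].
#' @param params From [synth_params()] (needs `replicates >= 2`).
#' @param cell_model `"model_a"` or `"model_b"`.
#' @param seed Integer seed.
#' @return List: `counts` (integer matrix), `condition` (named vector),
#'   `size_factors` (true per-sample factors).
#' @export
simulate_counts <- function(truth, params = synth_params(),
                            cell_model = "model_a", seed = 1L) {
  stopifnot(params$replicates >= 2L)
  set.seed(substream_seed(seed, paste0("counts_", cell_model)))
  mu0 <- truth$baseline_mean
  lfc <- truth$planted_effects[names(mu0), cell_model]
  nrep <- params$replicates
  sf <- stats::rlnorm(2L * nrep, 0, params$libsize_sdlog)
  condition <- stats::setNames(
    rep(c("control", "knockdown"), each = nrep),
    paste0(cell_model, "_", rep(c("ctrl", "kd"), each = nrep),
           rep(seq_len(nrep), 2L)))
  names(sf) <- names(condition)
  mu <- matrix(rep(mu0, 2L * nrep), ncol = 2L * nrep,
               dimnames = list(names(mu0), names(condition)))
  mu[, condition == "knockdown"] <- mu[, condition == "knockdown"] * 2^lfc
  mu <- sweep(mu, 2, sf, "*")
  disp <- min(params$dispersion, params$dispersion_cap)
  counts <- if (disp > 0)
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / disp), nrow(mu))
  else matrix(stats::rpois(length(mu), lambda = mu), nrow(mu))
  dimnames(counts) <- dimnames(mu)
  storage.mode(counts) <- "integer"
  list(counts = counts, condition = condition, size_factors = sf)
}

# shared detection/jitter/noise model for one probe set or ChIP experiment
detect_peaks <- function(sites, chrom_lengths, params, prefix) {
  keep <- stats::runif(nrow(sites)) < params$detect_prob
  det <- sites[keep, c("chrom", "start", "end"), drop = FALSE]
  j <- params$jitter_bp
  if (nrow(det) && j > 0) {
    det$start <- pmax(0L, det$start + sample(seq.int(-j, j), nrow(det), TRUE))
    det$end <- det$end + sample(seq.int(-j, j), nrow(det), TRUE)
    bad <- det$end <= det$start
    det$end[bad] <- det$start[bad] + 50L
  }
  n_noise <- stats::rpois(1L, params$noise_rate *
                            sum(chrom_lengths) / 1e6)
  if (n_noise > 0) {
    ch <- sample(names(chrom_lengths), n_noise, TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    w <- sample(params$site_width[1]:params$site_width[2], n_noise, TRUE)
    s <- vapply(seq_len(n_noise), function(i)
      sample.int(chrom_lengths[[ch[i]]] - w[i], 1L) - 1L, numeric(1))
    noise <- data.frame(chrom = ch, start = as.integer(s),
                        end = as.integer(s + w), stringsAsFactors = FALSE)
    det <- rbind(det, noise)
    is_noise <- c(rep(FALSE, sum(keep)), rep(TRUE, n_noise))
  } else is_noise <- rep(FALSE, nrow(det))
  if (nrow(det) == 0L) {
    det <- empty_intervals()
    det$q <- numeric(0)
    return(det)
  }
  o <- order(det$chrom, det$start)
  det <- det[o, , drop = FALSE]
  is_noise <- is_noise[o]
  det$name <- sprintf("%s_%05d", prefix, seq_len(nrow(det)))
  det$score <- 0
  det$strand <- "."
  # q column: true peaks strongly significant; a fraction of noise peaks weak
  nq <- nrow(det)
  det$q <- stats::runif(nq, 1e-6, 0.04)
  weak <- which(is_noise & stats::runif(nq) < 0.3)
  det$q[weak] <- stats::runif(length(weak), 0.06, 0.5)
  rownames(det) <- NULL
  det
}

#' Simulate dual-probe ChIRP peak files
#'
#' Each true binding site appears in the EVEN and ODD probe-set files
#' independently with probability `detect_prob`, endpoints jittered
#' uniformly within `+/- jitter_bp`; noise peaks are placed uniformly with
#' count `Poisson(noise_rate x genome Mb)` per probe set. Peaks carry a q
#' column (true sites well below, a fraction of noise peaks above, the usual
#' q cut-off).
#'
#' @param truth From [make_truth()].
#' @param chrom_lengths Named chromosome lengths.
#' @param params From [synth_params()].
#' @param seed Integer seed.
#' @return List of two interval data frames, `even` and `odd`.
#' @export
simulate_chirp_peaks <- function(truth, chrom_lengths,
                                 params = synth_params(), seed = 1L) {
  set.seed(substream_seed(seed, "chirp"))
  list(even = detect_peaks(truth$true_binding_sites, chrom_lengths, params,
                           "even"),
       odd = detect_peaks(truth$true_binding_sites, chrom_lengths, params,
                          "odd"))
}

#' @rdname simulate_chirp_peaks
#' @export
simulate_chip_peaks <- function(truth, chrom_lengths,
                                params = synth_params(), seed = 1L) {
  set.seed(substream_seed(seed, "chip"))
  detect_peaks(truth$chip_sites, chrom_lengths, params, "chip")
}

#' Simulate a coverage track
#'
#' The track is a sum of Gaussian-shaped bumps centred on peak midpoints
#' over a flat background, emitted as fixed-width bedGraph bins; coverage is
#' non-negative everywhere.
#'
#' @param peaks Interval data frame (bump centres = midpoints).
#' @param chrom_lengths Named chromosome lengths.
#' @param params From [synth_params()] (`shape_sd_bp > 0`, `coverage_bin`,
#'   `coverage_background`, `coverage_amplitude`).
#' @return bedGraph-style data frame `chrom`, `start`, `end`, `value`.
#' @export
simulate_coverage <- function(peaks, chrom_lengths, params = synth_params()) {
  stopifnot(params$shape_sd_bp > 0)
  bw <- params$coverage_bin
  sd <- params$shape_sd_bp
  out <- list()
  for (ch in names(chrom_lengths)) {
    nb <- chrom_lengths[[ch]] %/% bw
    centers <- (seq_len(nb) - 0.5) * bw
    v <- rep(params$coverage_background, nb)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk)) {
      mids <- interval_midpoint(pk$start, pk$end)
      for (m in mids) {
        lo <- max(1L, as.integer((m - 4 * sd) %/% bw))
        hi <- min(nb, as.integer((m + 4 * sd) %/% bw) + 1L)
        idx <- lo:hi
        v[idx] <- v[idx] +
          params$coverage_amplitude * exp(-(centers[idx] - m)^2 / (2 * sd^2))
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = (seq_len(nb) - 1L) * bw,
                            end = seq_len(nb) * bw, value = v,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# correlated TF expression panel emulating a tumor cohort (for the pairwise
# rank-correlation matrix): one latent program with signed loadings
simulate_panel <- function(tf_ids, n_samples, seed) {
  set.seed(substream_seed(seed, "panel"))
  f <- stats::rnorm(n_samples)
  loading <- stats::runif(length(tf_ids), 0.5, 1.5) *
    sample(c(1, 1, 1, -1), length(tf_ids), TRUE)
  m <- t(vapply(seq_along(tf_ids), function(i)
    2^(8 + loading[i] * f + stats::rnorm(n_samples, 0, 0.7)),
    numeric(n_samples)))
  rownames(m) <- tf_ids
  colnames(m) <- sprintf("tumor_%02d", seq_len(n_samples))
  m
}

# gene-set collection with structured terms over the planted truth plus
# random terms, for the over-representation stage
simulate_genesets <- function(truth, all_ids, seed) {
  set.seed(substream_seed(seed, "gmt"))
  sets <- list()
  add <- function(id, desc, genes) {
    g <- unique(genes)
    attr(g, "description") <- desc
    sets[[id]] <<- g
  }
  add("SET_DIRECT_PROGRAM", "planted direct targets plus background",
      c(truth$direct_target_ids, sample(all_ids, 20)))
  for (tf in names(truth$tf_layer))
    add(paste0("SET_", tf, "_DOWNSTREAM"), paste("downstream of", tf),
        c(truth$tf_layer[[tf]]$downstream, sample(all_ids, 5)))
  for (k in seq_len(15))
    add(sprintf("SET_RANDOM_%02d", k), "random background term",
        sample(all_ids, sample(10:50, 1)))
  sets
}

#' Simulate the full synthetic study to disk
#'
#' Writes every input the integration pipeline consumes (genome FASTA,
#' annotation GTF, PWMs, dual-probe ChIRP BEDs, TF ChIP BED, count matrices
#' and condition maps for two cell models, TF catalog, TF-knockdown DEG
#' lists, gene sets, expression panel, optional coverage tracks) plus the
#' planted-truth tables, under one directory.
#'
#' @param out_dir Output directory (created).
#' @param params From [synth_params()].
#' @param seed Master seed; every stage draws a named substream from it.
#' @param config A [pipeline_config()]; window geometry for motif planting.
#' @param coverage Also write bedGraph coverage tracks (slower, larger).
#' @return Invisibly, a list with `paths`, `truth`, `params`, and the
#'   in-memory `ann`.
#' @export
simulate_study <- function(out_dir, params = synth_params(), seed = 1L,
                           config = pipeline_config(random_seed = seed),
                           coverage = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  gen <- generate_genome(params, seed)
  truth <- make_truth(gen, params, seed)
  pwms <- make_pwms(names(truth$tf_layer), params, seed)
  pl <- plant_motifs(gen$genome, truth, pwms, gen$ann, config, seed)
  truth$planted_motif_positions <- pl$motifs
  genome <- pl$genome

  write_fasta(genome, pth("genome.fa"))
  write_gtf(gen$ann, pth("genes.gtf"))
  write_meme(pwms, pth("pwms.meme"))
  chirp <- simulate_chirp_peaks(truth, gen$chrom_lengths, params, seed)
  write_bed(chirp$even, pth("chirp_even.bed"))
  write_bed(chirp$odd, pth("chirp_odd.bed"))
  chip <- simulate_chip_peaks(truth, gen$chrom_lengths, params, seed)
  write_bed(chip, pth("chip_tf.bed"))
  for (m in c("model_a", "model_b")) {
    sim <- simulate_counts(truth, params, m, seed)
    write_counts(sim$counts, sim$condition,
                 pth(paste0("counts_", m, ".tsv")),
                 pth(paste0("coldata_", m, ".tsv")))
  }
  catalog <- data.frame(
    gene_id = gen$ann$gene_id,
    is_tf = gen$ann$gene_id %in% truth$tf_ids,
    is_cofactor = gen$ann$gene_id %in% truth$cofactor_ids)
  write_table(catalog, pth("tf_catalog.tsv"))
  writeLines(truth$tf_deg_a_ids, pth("tf_deg_model_a.txt"))
  writeLines(truth$tf_deg_b_ids, pth("tf_deg_model_b.txt"))
  write_gmt(simulate_genesets(truth, gen$ann$gene_id, seed),
            pth("genesets.gmt"))
  panel <- simulate_panel(names(truth$tf_layer), params$panel_samples, seed)
  utils::write.table(data.frame(gene_id = rownames(panel), panel),
                     pth("panel_expr.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (coverage) {
    write_bedgraph(simulate_coverage(truth$true_binding_sites,
                                     gen$chrom_lengths, params),
                   pth("coverage_lnc.bedGraph"))
    write_bedgraph(simulate_coverage(truth$chip_sites, gen$chrom_lengths,
                                     params),
                   pth("coverage_tf.bedGraph"))
  }
  # truth tables
  dir.create(pth("truth"), showWarnings = FALSE)
  tg <- data.frame(
    gene_id = gen$ann$gene_id,
    role = unname(truth$role[gen$ann$gene_id]),
    lfc_model_a = truth$planted_effects[gen$ann$gene_id, "model_a"],
    lfc_model_b = truth$planted_effects[gen$ann$gene_id, "model_b"],
    baseline_mean = unname(truth$baseline_mean[gen$ann$gene_id]))
  tg <- merge(tg, truth$comm_flags, by = "gene_id", sort = TRUE)
  write_table(tg, pth("truth", "truth_genes.tsv"))
  write_bed(truth$true_binding_sites[, c("chrom", "start", "end", "name")],
            pth("truth", "truth_sites.bed"))
  write_table(truth$planted_motif_positions, pth("truth", "truth_motifs.tsv"))
  edges <- do.call(rbind, lapply(names(truth$tf_layer), function(tf) {
    tl <- truth$tf_layer[[tf]]
    data.frame(tf_id = tf, target_gene_id = c(tl$downstream, tl$coop),
               target_planted_class = rep(c("RIG", "RDG"),
                                          c(length(tl$downstream),
                                            length(tl$coop))))
  }))
  write_table(edges, pth("truth", "truth_edges.tsv"))

  paths <- list(
    genome = pth("genome.fa"), gtf = pth("genes.gtf"),
    pwms = pth("pwms.meme"),
    chirp_even = pth("chirp_even.bed"), chirp_odd = pth("chirp_odd.bed"),
    chip = pth("chip_tf.bed"),
    counts_model_a = pth("counts_model_a.tsv"),
    coldata_model_a = pth("coldata_model_a.tsv"),
    counts_model_b = pth("counts_model_b.tsv"),
    coldata_model_b = pth("coldata_model_b.tsv"),
    tf_catalog = pth("tf_catalog.tsv"),
    tf_deg_model_a = pth("tf_deg_model_a.txt"),
    tf_deg_model_b = pth("tf_deg_model_b.txt"),
    genesets = pth("genesets.gmt"),
    panel = pth("panel_expr.tsv"))
  if (coverage) {
    paths$coverage_lnc <- pth("coverage_lnc.bedGraph")
    paths$coverage_tf <- pth("coverage_tf.bedGraph")
  }
  invisible(list(paths = paths, truth = truth, params = params,
                 ann = gen$ann, chrom_lengths = gen$chrom_lengths))
}
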