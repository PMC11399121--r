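#' Position weight matrices
#'
#' A PWM is a per-position nucleotide probability model of a TF binding
#' motif. Probabilities receive a pseudocount (default 0.01, rows
#' renormalized) so every log-odds score is finite; scoring is
#' `sum_i log2(p_i(x_i) / bg(x_i))` in bits against an i.i.d. background.
#' Exact p-values are computed by dynamic programming over the score
#' distribution discretized at `eps` bits, the same discretization used when
#' scanning, so scanned scores and p-values are mutually consistent.
#'
#' @param tf_id Motif / TF identifier.
#' @param mat L x 4 probability matrix, columns A, C, G, T.
#' @param bg Background frequencies (length 4, summing to 1).
#' @param pseudocount Added to every probability before renormalization.
#' @param eps Score discretization granularity in bits.
#' @return An object of class `chirpnet_pwm`.
#' @export
new_pwm <- function(tf_id, mat, bg = rep(0.25, 4), pseudocount = 0.01,
                    eps = 1e-3) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4L, all(mat >= 0), abs(sum(bg) - 1) < 1e-6)
  mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  lo <- sweep(log2(mat), 2, log2(bg), "-")
  ints <- matrix(as.integer(round(lo / eps)), nrow(mat), 4L)
  pwm <- list(tf_id = tf_id, mat = mat, bg = bg, eps = eps,
              log_odds = lo, ints = ints)
  class(pwm) <- "chirpnet_pwm"
  pwm
}

#' @rdname new_pwm
#' @param pwm A `chirpnet_pwm`.
#' @export
pwm_length <- function(pwm) nrow(pwm$mat)

#' @rdname new_pwm
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[max.col(pwm$mat, ties.method = "first")],
        collapse = "")
}

#' Total information content of a PWM
#'
#' `sum_i sum_b p_i(b) log2(p_i(b) / bg(b))` in bits.
#'
#' @param pwm A `chirpnet_pwm`.
#' @export
pwm_information <- function(pwm) {
  sum(pwm$mat * sweep(log2(pwm$mat), 2, log2(pwm$bg), "-"))
}

#' Log-odds score of a k-mer
#'
#' @param pwm A `chirpnet_pwm`.
#' @param kmer Character string of length `pwm_length(pwm)` over ACGTN;
#'   an N contributes 0 to the score.
#' @return Score in bits.
#' @export
log_odds_score <- function(pwm, kmer) {
  ch <- strsplit(toupper(kmer), "")[[1]]
  if (length(ch) != pwm_length(pwm))
    stop("k-mer length ", length(ch), " != PWM length ", pwm_length(pwm))
  idx <- match(ch, c("A", "C", "G", "T"))
  if (any(is.na(idx) & ch != "N"))
    stop("invalid character in k-mer: ", ch[is.na(idx) & ch != "N"][1])
  s <- 0
  for (i in seq_along(ch)) if (!is.na(idx[i])) s <- s + pwm$log_odds[i, idx[i]]
  unname(s)
}

# Exact null distribution of the discretized score: returns integer smin and
# the tail vector `tail`, where tail[k] = P(S_int >= smin + k - 1).
pwm_null_tail <- function(pwm) {
  if (!is.null(pwm$.tail)) return(pwm$.tail)
  ints <- pwm$ints
  L <- nrow(ints)
  smin <- sum(apply(ints, 1, min))
  smax <- sum(apply(ints, 1, max))
  width <- smax - smin + 1L
  dist <- numeric(width)
  cur_min <- 0L
  dist[1] <- 1
  cur_len <- 1L
  for (i in seq_len(L)) {
    row <- ints[i, ]
    new_min <- cur_min + min(row)
    new_len <- cur_len + max(row) - min(row)
    nd <- numeric(new_len)
    for (b in 1:4) {
      off <- row[b] - min(row)
      nd[(off + 1L):(off + cur_len)] <-
        nd[(off + 1L):(off + cur_len)] + dist[seq_len(cur_len)] * pwm$bg[b]
    }
    dist <- nd
    cur_min <- new_min
    cur_len <- new_len
  }
  stopifnot(cur_min == smin, cur_len == width)
  tail <- rev(cumsum(rev(dist)))
  list(smin = smin, smax = smax, tail = tail)
}

#' Exact PWM score p-value
#'
#' `P(S >= score)` for a single scored position under the i.i.d. background
#' null, computed by dynamic programming over the discretized score
#' distribution.
#'
#' @param pwm A `chirpnet_pwm`.
#' @param score Score in bits.
#' @return p-value in `[0, 1]`.
#' @export
pwm_pvalue <- function(pwm, score) {
  nt <- pwm_null_tail(pwm)
  s_int <- as.integer(round(score / pwm$eps))
  ifelse(s_int <= nt$smin, 1,
         ifelse(s_int > nt$smax, 0, nt$tail[s_int - nt$smin + 1L]))
}

#' Read / write PWMs in minimal MEME motif text
#'
#' Supports the subset of the MEME motif format needed here: an optional
#' background line and, per motif, `MOTIF <id>` followed by a
#' `letter-probability matrix:` header and its rows.
#'
#' @param path File path.
#' @param ... Passed to [new_pwm()] (e.g. `pseudocount`).
#' @return `read_meme()`: named list of `chirpnet_pwm`.
#' @export
read_meme <- function(path, ...) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bgl <- which(startsWith(lines, "Background letter frequencies"))
  if (length(bgl)) {
    f <- strsplit(lines[bgl[1] + 1L], "\\s+")[[1]]
    bg <- as.numeric(f[c(2, 4, 6, 8)])
  }
  starts <- which(startsWith(lines, "MOTIF"))
  pwms <- list()
  for (s in starts) {
    id <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- s + which(startsWith(lines[(s + 1):length(lines)],
                                "letter-probability matrix"))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]])))
    pwms[[id]] <- new_pwm(id, mat, bg = bg, ...)
  }
  pwms
}

#' @rdname read_meme
#' @param pwms Named list of `chirpnet_pwm` (raw probabilities are written
#'   without the pseudocount being undone).
#' @export
write_meme <- function(pwms, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           sprintf("A %.6f C %.6f G %.6f T %.6f",
                   pwms[[1]]$bg[1], pwms[[1]]$bg[2],
                   pwms[[1]]$bg[3], pwms[[1]]$bg[4]), "")
  for (pwm in pwms) {
    out <- c(out, sprintf("MOTIF %s", pwm$tf_id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     pwm_length(pwm)),
             apply(pwm$mat, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                   r[1], r[2], r[3], r[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract a strand-aware promoter window
#'
#' The window covers `[TSS - motif_upstream_bp, TSS + motif_downstream_bp)`
#' in transcription orientation; for minus-strand genes the genomic span is
#' reverse-complemented so the returned sequence runs 5' to 3' of the gene.
#' Windows exceeding chromosome bounds are truncated and flagged.
#'
#' @param gene One-row slice of a gene annotation.
#' @param genome Named character vector of chromosome sequences.
#' @param config A [pipeline_config()].
#' @return List: `gene_id`, `seq`, `off_start` (offset of the first sequence
#'   base relative to the TSS), `genomic_start`, `genomic_end`, `truncated`.
#' @export
extract_promoter_window <- function(gene, genome, config) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq)) stop("chromosome absent from genome: ", gene$chrom)
  up <- config$motif_upstream_bp
  dn <- config$motif_downstream_bp
  L <- nchar(chrom_seq)
  if (gene$strand == "+") {
    g_lo <- gene$tss - up
    g_hi <- gene$tss + dn
  } else {
    g_lo <- gene$tss - dn + 1L
    g_hi <- gene$tss + up + 1L
  }
  lo <- max(g_lo, 0L)
  hi <- min(g_hi, L)
  truncated <- (lo != g_lo) || (hi != g_hi)
  s <- substr(chrom_seq, lo + 1L, hi)
  if (gene$strand == "+") {
    off_start <- lo - gene$tss
  } else {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    off_start <- gene$tss - hi + 1L
  }
  list(gene_id = gene$gene_id, seq = s, off_start = off_start,
       genomic_start = lo, genomic_end = hi, truncated = truncated)
}

#' @rdname extract_promoter_window
#' @param genes Gene annotation data frame.
#' @export
extract_promoter_windows <- function(genes, genome, config) {
  lapply(seq_len(nrow(genes)), function(i)
    extract_promoter_window(genes[i, , drop = FALSE], genome, config))
}

seq_codes <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T", "N"))
  x[is.na(x)] <- 5L
  x
}

# Integer scores at every start position of a code vector; positions whose
# window crosses a masked base (code 0) are NA. N (code 5) contributes 0.
score_positions <- function(pwm, codes, mask = NULL) {
  L <- pwm_length(pwm)
  P <- length(codes) - L + 1L
  if (P < 1L) return(integer(0))
  ints5 <- cbind(pwm$ints, 0L)
  s <- integer(P)
  for (i in seq_len(L)) s <- s + ints5[i, codes[i:(i + P - 1L)]]
  if (!is.null(mask)) {
    cs <- cumsum(mask)
    bad <- (cs[seq_len(P) + L - 1L] - c(0, cs)[seq_len(P)]) > 0
    s[bad] <- NA_integer_
  }
  s
}

#' Scan promoter windows with a PWM collection
#'
#' Every start position on both strands of every window is scored; exact
#' p-values come from the discretized null, and q-values are BH-adjusted per
#' PWM across all scored positions of that PWM's scan. Hits with
#' `q < motif_q` are retained, sorted by (tf, gene, offset). Windows shorter
#' than a PWM are skipped for that PWM with a warning.
#'
#' Offsets locate the 5'-most base of the match in transcription
#' orientation, relative to the TSS; strand `+` means the match lies on the
#' gene-sense strand of the window.
#'
#' @param pwms Named list of `chirpnet_pwm`.
#' @param windows List of promoter windows from
#'   [extract_promoter_windows()].
#' @param config A [pipeline_config()] (uses `motif_q`).
#' @param keep_all Also return the full scored-position table (can be very
#'   large; intended for small inputs).
#' @return List: `hits` (data frame `tf_id`, `gene_id`, `strand`, `offset`,
#'   `score`, `p`, `q`), `n_scored` (named vector per PWM), and `all` when
#'   `keep_all = TRUE`.
#' @export
scan_windows <- function(pwms, windows, config, keep_all = FALSE) {
  stopifnot(length(windows) > 0L)
  hit_list <- list()
  all_list <- list()
  n_scored <- stats::setNames(integer(length(pwms)), names(pwms))
  win_seqs <- vapply(windows, `[[`, character(1), "seq")
  win_rc <- vapply(win_seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
  win_ids <- vapply(windows, `[[`, character(1), "gene_id")
  win_off <- vapply(windows, `[[`, numeric(1), "off_start")
  win_len <- nchar(win_seqs)
  for (nm in names(pwms)) {
    pwm <- pwms[[nm]]
    L <- pwm_length(pwm)
    use <- win_len >= L
    if (!all(use))
      warning(sum(!use), " window(s) shorter than PWM ", nm, " skipped")
    if (!any(use)) next
    idx <- which(use)
    score_strand <- function(seqs) {
      sep <- rep(0L, L - 1L)
      codes <- unlist(lapply(seqs, function(s) c(seq_codes(s), sep)))
      codes <- codes[seq_len(length(codes) - (L - 1L))]
      mask <- codes == 0L
      codes[mask] <- 5L
      s <- score_positions(pwm, codes, mask)
      # map concatenated positions back to window / within-window position
      starts <- cumsum(c(0L, (win_len[idx] + L - 1L)))[seq_along(idx)]
      pos_tab <- do.call(rbind, lapply(seq_along(idx), function(k) {
        npos <- win_len[idx[k]] - L + 1L
        cbind(win = idx[k], within = seq_len(npos),
              concat = starts[k] + seq_len(npos))
      }))
      cbind(pos_tab, s_int = s[pos_tab[, "concat"]])
    }
    fw <- score_strand(win_seqs[idx])
    rv <- score_strand(win_rc[idx])
    nt <- pwm_null_tail(pwm)
    p_of <- function(s_int) {
      ifelse(s_int <= nt$smin, 1,
             ifelse(s_int > nt$smax, 0, nt$tail[pmin(pmax(
               s_int - nt$smin + 1L, 1L), length(nt$tail))]))
    }
    tab <- data.frame(
      win = c(fw[, "win"], rv[, "win"]),
      within = c(fw[, "within"], rv[, "within"]),
      strand = rep(c("+", "-"), c(nrow(fw), nrow(rv))),
      s_int = c(fw[, "s_int"], rv[, "s_int"]),
      stringsAsFactors = FALSE
    )
    tab <- tab[!is.na(tab$s_int), , drop = FALSE]
    tab$p <- p_of(tab$s_int)
    tab$q <- bh_adjust(tab$p)
    n_scored[nm] <- nrow(tab)
    # offset of the match 5'-most base in window orientation
    wl <- win_len[tab$win]
    fwd_start <- tab$within - 1L
    rev_start <- wl - (tab$within - 1L) - L
    tab$offset <- win_off[tab$win] +
      ifelse(tab$strand == "+", fwd_start, rev_start)
    tab$gene_id <- win_ids[tab$win]
    tab$tf_id <- nm
    tab$score <- tab$s_int * pwm$eps
    keep_cols <- c("tf_id", "gene_id", "strand", "offset", "score", "p", "q")
    if (keep_all) all_list[[nm]] <- tab[, keep_cols]
    hit_list[[nm]] <- tab[tab$q < config$motif_q, keep_cols, drop = FALSE]
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(tf_id = character(), gene_id = character(),
               strand = character(), offset = integer(), score = numeric(),
               p = numeric(), q = numeric())
  hits <- hits[order(hits$tf_id, hits$gene_id, hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  out <- list(hits = hits, n_scored = n_scored)
  if (keep_all) out$all <- do.call(rbind, all_list)
  out
}
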