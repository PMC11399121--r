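#' Standard-format input/output
#'
#' All genomic intervals are held internally in 0-based half-open
#' coordinates; conversion happens only at the file boundary (BED is already
#' 0-based half-open, GTF is 1-based inclusive and converted on read).
#'
#' @name chirpnet-io
NULL

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Read a BED file of peaks or intervals
#'
#' BED3 to BED6 are accepted; a seventh numeric column, when present, is read
#' as a per-record q-value (`q`), the convention used for peak files exported
#' after peak calling.
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), and any of `name`, `score`, `strand`, `q` present in the
#'   file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) return(empty_intervals())
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  extra <- if (nfield >= 7L) c(q = "numeric") else character()
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED", extraCols = extra),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e))
  )
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(mc)) df$name <- as.character(mc$name)
  if ("score" %in% names(mc)) df$score <- as.numeric(mc$score)
  if (nfield >= 6L) df$strand <- as.character(GenomicRanges::strand(gr))
  if ("q" %in% names(mc)) df$q <- as.numeric(mc$q)
  df
}

#' Write intervals as BED
#'
#' Columns beyond `chrom`/`start`/`end` are written in BED order (`name`,
#' `score`, `strand`, then `q` as an extra column) when present.
#'
#' @param intervals Data frame in internal interval form.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  for (opt in c("name", "score", "strand", "q")) {
    if (opt %in% names(intervals)) cols <- c(cols, opt) else break
  }
  out <- intervals[, cols, drop = FALSE]
  if ("score" %in% names(out)) out$score <- format(out$score, trim = TRUE)
  if ("q" %in% names(out)) out$q <- format(out$q, trim = TRUE, digits = 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Expects the GENCODE dialect: `gene` and `exon` features carrying `gene_id`
#' and `gene_name` attributes; `five_prime_utr` / `three_prime_utr` features
#' are used when present. GTF's 1-based inclusive coordinates are converted
#' to 0-based half-open on read.
#'
#' @param path GTF file path.
#' @return A gene annotation data frame: one row per gene with `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `tx_start`, `tx_end`, `tss` and
#'   list-columns `exons`, `utr5`, `utr3` (two-column start/end matrices).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF file ", path, ": ",
                                          conditionMessage(e)))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    stringsAsFactors = FALSE
  )
  df$gene_name <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else df$gene_id
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("GTF file ", path, " contains no gene features")
  sub_mat <- function(type, gid) {
    s <- df[df$type == type & df$gene_id == gid, c("start", "end"), drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    as.matrix(s)
  }
  ann <- data.frame(
    gene_id = genes$gene_id, gene_name = genes$gene_name,
    chrom = genes$chrom, strand = genes$strand,
    tx_start = genes$start, tx_end = genes$end,
    stringsAsFactors = FALSE
  )
  ann$tss <- ifelse(ann$strand == "+", ann$tx_start, ann$tx_end - 1L)
  ann$exons <- lapply(ann$gene_id, function(g) sub_mat("exon", g))
  ann$utr5 <- lapply(ann$gene_id, function(g) sub_mat("five_prime_utr", g))
  ann$utr3 <- lapply(ann$gene_id, function(g) sub_mat("three_prime_utr", g))
  ann <- ann[order(ann$chrom, ann$tx_start, ann$gene_id), , drop = FALSE]
  rownames(ann) <- ann$gene_id
  ann
}

# Writes the GENCODE-dialect GTF emitted by the synthetic generator.
write_gtf <- function(ann, path) {
  lines <- character(0)
  for (i in seq_len(nrow(ann))) {
    at <- sprintf('gene_id "%s"; gene_name "%s";',
                  ann$gene_id[i], ann$gene_name[i])
    fmt <- function(type, s, e) {
      sprintf("%s\tchirpnet\t%s\t%d\t%d\t.\t%s\t.\t%s",
              ann$chrom[i], type, s + 1L, e, ann$strand[i], at)
    }
    lines <- c(lines, fmt("gene", ann$tx_start[i], ann$tx_end[i]))
    ex <- ann$exons[[i]]
    for (j in seq_len(nrow(ex))) lines <- c(lines, fmt("exon", ex[j, 1], ex[j, 2]))
    for (u in list(c("five_prime_utr", "utr5"), c("three_prime_utr", "utr3"))) {
      m <- ann[[u[2]]][[i]]
      if (!is.null(m)) for (j in seq_len(nrow(m)))
        lines <- c(lines, fmt(u[1], m[j, 1], m[j, 2]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genome sequence (FASTA)
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  x <- toupper(as.character(ss))
  names(x) <- sub("\\s.*$", "", names(ss))
  x
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph path.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A coverage accessor: a named list of per-base numeric vectors,
#'   one per chromosome (position `i` of the vector is base `i - 1`).
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("malformed bedGraph file ", path,
                                          ": ", conditionMessage(e)))
  cov <- lapply(chrom_lengths, function(L) numeric(L))
  ch <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  v <- as.numeric(gr$score)
  for (cname in names(cov)) {
    idx <- which(ch == cname)
    for (i in idx) {
      to <- min(e[i], length(cov[[cname]]))
      if (s[i] < to) cov[[cname]][(s[i] + 1L):to] <- v[i]
    }
  }
  cov
}

write_bedgraph <- function(track, path) {
  # track: data.frame chrom,start,end,value (0-based half-open bins)
  utils::write.table(
    data.frame(track$chrom, track$start, track$end,
               format(track$value, trim = TRUE, digits = 8)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT path (tab-separated: term id, description, gene ids...).
#' @return Named list of character vectors; the `description` attribute on
#'   each element carries the term description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path, " (needs >= 3 fields)")
    genes <- unique(f[-(1:2)])
    attr(genes, "description") <- f[2]
    sets[[f[1]]] <- genes
  }
  sets
}

write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- nm
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix with its condition map
#'
#' @param counts_path TSV of raw counts: first column `gene_id`, remaining
#'   columns one per sample.
#' @param coldata_path TSV with columns `sample` and `condition`.
#' @return List with `counts` (integer matrix, genes x samples) and
#'   `condition` (named character vector).
#' @export
read_counts <- function(counts_path, coldata_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicate gene ids in ", counts_path, ": ",
         tab[[1]][duplicated(tab[[1]])][1])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab[[1]]
  cd <- utils::read.delim(coldata_path, stringsAsFactors = FALSE)
  if (!all(colnames(counts) %in% cd$sample))
    stop("sample without a condition in ", coldata_path, ": ",
         setdiff(colnames(counts), cd$sample)[1])
  condition <- stats::setNames(cd$condition, cd$sample)[colnames(counts)]
  list(counts = counts, condition = condition)
}

write_counts <- function(counts, condition, counts_path, coldata_path) {
  utils::write.table(
    data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
    counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(condition), condition = unname(condition)),
    coldata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Write a result table
#'
#' Stage outputs are plain tab-separated tables with a header, so any stage
#' can be re-run from persisted files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  for (j in which(is_list))
    x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","), character(1))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
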