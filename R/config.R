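#' Pipeline configuration
#'
#' Collects every threshold and convention the integration cascade uses,
#' together with the input file paths, so that any stage can be re-run from
#' persisted intermediates under identical settings.
#'
#' @param tss_window_bp Promoter half-width (bp) for peak-to-gene annotation.
#'   A peak whose midpoint lies within this distance of its target gene's TSS
#'   is classified as promoter-bound.
#' @param motif_upstream_bp,motif_downstream_bp Promoter window for motif
#'   scanning, measured from the TSS in transcription orientation.
#' @param de_fdr BH-adjusted significance threshold for the differential test.
#' @param motif_q BH q-value threshold for retained motif hits.
#' @param peak_q q threshold applied to incoming peak records when the peak
#'   file carries a q column (filtering happens before probe-set intersection).
#' @param enrich_alpha BH-adjusted threshold for over-representation results.
#' @param low_count_min_total Minimum raw count summed over all samples for a
#'   gene to enter the differential test.
#' @param jaccard_edge_min Minimum Jaccard similarity for an edge in the
#'   term-clustering graph.
#' @param random_seed Master seed; all stochastic stages draw from named
#'   substreams derived from it (see [substream_seed()]).
#' @param paths Named list of input file paths (see [run_pipeline()] for the
#'   names that the full cascade expects).
#' @return An object of class `chirpnet_config` (a validated named list).
#' @seealso [read_config()], [write_config()], [run_pipeline()]
#' @export
pipeline_config <- function(tss_window_bp = 3000L,
                            motif_upstream_bp = 1500L,
                            motif_downstream_bp = 500L,
                            de_fdr = 0.1,
                            motif_q = 0.05,
                            peak_q = 0.05,
                            enrich_alpha = 0.05,
                            low_count_min_total = 10L,
                            jaccard_edge_min = 0.2,
                            random_seed = 1L,
                            paths = list()) {
  cfg <- list(
    tss_window_bp = as.integer(tss_window_bp),
    motif_upstream_bp = as.integer(motif_upstream_bp),
    motif_downstream_bp = as.integer(motif_downstream_bp),
    de_fdr = as.numeric(de_fdr),
    motif_q = as.numeric(motif_q),
    peak_q = as.numeric(peak_q),
    enrich_alpha = as.numeric(enrich_alpha),
    low_count_min_total = as.integer(low_count_min_total),
    jaccard_edge_min = as.numeric(jaccard_edge_min),
    random_seed = as.integer(random_seed),
    paths = paths
  )
  class(cfg) <- "chirpnet_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config Object to validate.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "chirpnet_config"))
  with(config, {
    if (tss_window_bp <= 0L) stop("tss_window_bp must be > 0")
    if (motif_upstream_bp <= 0L || motif_downstream_bp <= 0L)
      stop("motif window widths must be > 0")
    if (!(de_fdr >= 0 && de_fdr <= 1)) stop("de_fdr must lie in [0, 1]")
    for (nm in c("motif_q", "peak_q", "enrich_alpha")) {
      v <- config[[nm]]
      if (!(v >= 0 && v <= 1)) stop(nm, " must lie in [0, 1]")
    }
    if (low_count_min_total < 0L) stop("low_count_min_total must be >= 0")
    if (!(jaccard_edge_min >= 0 && jaccard_edge_min <= 1))
      stop("jaccard_edge_min must lie in [0, 1]")
  })
  invisible(config)
}

#' Read / write a configuration file
#'
#' The on-disk representation is YAML; a config round-trips losslessly
#' through `write_config()` / `read_config()`.
#'
#' @param config A `chirpnet_config`.
#' @param path File path.
#' @return `read_config()` returns a `chirpnet_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Derive a named random substream seed
#'
#' Every stochastic stage seeds R's RNG with a deterministic function of the
#' master seed and its own stream name, so stages are reproducible
#' individually and independent of execution order.
#'
#' @param master_seed Integer master seed.
#' @param stream Character stream name (e.g. `"counts_model_a"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master_seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1977326743  # 7^11
  as.integer((as.numeric(master_seed) %% 1977326743 * 31 + h) %% 2147483647)
}

#' @export
print.chirpnet_config <- function(x, ...) {
  cat("chirpnet pipeline configuration\n")
  for (nm in setdiff(names(x), "paths"))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  if (length(x$paths)) {
    cat("  paths:\n")
    for (nm in names(x$paths)) cat(sprintf("    %-20s %s\n", nm, x$paths[[nm]]))
  }
  invisible(x)
}

log_stage <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}
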