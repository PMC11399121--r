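#' Published summary counts of the reference study
#'
#' The study's printed per-stage counts (DEG totals, class sizes, predicted
#' TF target totals, intersection sizes), shipped as a small table so the
#' arithmetic identities that connect them can be recomputed.
#'
#' @return Named numeric vector.
#' @export
published_counts <- function() {
  f <- system.file("extdata", "published_summary_counts.tsv",
                   package = "chirpnet", mustWork = TRUE)
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  stats::setNames(tab$value, tab$quantity)
}

#' Recompute the study's consistency identities
#'
#' Eight arithmetic identities over the published per-stage counts: the DEG
#' total as the sum of up- and downregulated genes, the up/down percentage
#' shares, the DEG total as the sum of direct (RDG) and indirect (RIG)
#' targets, the RDG/RIG percentage shares, the cooperating TF's predicted
#' target total as the sum of its RDG and RIG targets, and containment of
#' the final common direct-target core in the discovery-model intersection.
#' Each derived value is recomputed from the primitive counts and compared
#' with the printed one at printed precision.
#'
#' @return Data frame: `identity`, `computed`, `reported`, `match`.
#' @export
reported_identities <- function() {
  ct <- published_counts()
  pct <- function(x, tot) round(100 * x / tot, 2)
  rows <- list(
    c("deg_total_equals_up_plus_down",
      ct[["model_a_deg_up"]] + ct[["model_a_deg_down"]],
      ct[["model_a_deg_total"]]),
    c("up_share_pct",
      pct(ct[["model_a_deg_up"]], ct[["model_a_deg_total"]]),
      ct[["up_pct"]]),
    c("down_share_pct",
      pct(ct[["model_a_deg_down"]], ct[["model_a_deg_total"]]),
      ct[["down_pct"]]),
    c("deg_total_equals_rdg_plus_rig",
      ct[["rdg_count"]] + ct[["rig_count"]],
      ct[["model_a_deg_total"]]),
    c("rdg_share_pct",
      pct(ct[["rdg_count"]], ct[["model_a_deg_total"]]),
      ct[["rdg_pct"]]),
    c("rig_share_pct",
      pct(ct[["rig_count"]], ct[["model_a_deg_total"]]),
      ct[["rig_pct"]]),
    c("tf_predicted_total_equals_rdg_plus_rig",
      ct[["tf_predicted_rdg"]] + ct[["tf_predicted_rig"]],
      ct[["tf_predicted_total"]]),
    c("comm_core_within_discovery_intersection",
      as.numeric(ct[["comm_dgs"]] <= ct[["common_direct_model_a"]] &
                   ct[["common_direct_model_a"]] <= ct[["rdg_count"]]),
      1))
  out <- data.frame(
    identity = vapply(rows, `[`, character(1), 1L),
    computed = as.numeric(vapply(rows, `[`, character(1), 2L)),
    reported = as.numeric(vapply(rows, `[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  out$match <- out$computed == out$reported
  out
}
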