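#' Relative expression by the 2^-ddCt method
#'
#' Per well, `dCt = Ct_target - mean(reference Cts)` (arithmetic mean over
#' reference genes, equivalent to a geometric mean of linear quantities);
#' `ddCt = dCt - mean(dCt over control replicates)`; relative expression is
#' `2^-ddCt`, so the control condition averages to 1 on the dCt scale.
#'
#' @param samples Data frame with columns `condition`, `ct_target`, and one
#'   or more `ct_ref*` columns (or a list-column `ct_refs`).
#' @param control_condition Label of the calibrator condition.
#' @return The input with `dct`, `ddct` and `rel_expr` columns added.
#' @export
ddct_relative_expression <- function(samples, control_condition = "control") {
  ref_cols <- grep("^ct_ref", names(samples), value = TRUE)
  if (length(ref_cols) == 0L) stop("no reference Ct columns (ct_ref*)")
  refs <- as.matrix(samples[, ref_cols, drop = FALSE])
  if (any(!is.finite(refs)) || any(!is.finite(samples$ct_target)))
    stop("Ct values must be finite")
  dct <- samples$ct_target - rowMeans(refs)
  ctrl <- samples$condition == control_condition
  if (!any(ctrl)) stop("no replicate of control condition '",
                       control_condition, "'")
  ddct <- dct - mean(dct[ctrl])
  samples$dct <- dct
  samples$ddct <- ddct
  samples$rel_expr <- 2^(-ddct)
  samples
}

#' Pulldown signal as percent of input
#'
#' The input Ct is first adjusted for the input dilution
#' (`ct_input - log2(1 / input_fraction)`), then
#' `percent = 100 x 2^(adjusted_input_ct - ct_ip)`: equal Cts at an input
#' fraction of 0.01 mean the IP holds 1% of the material.
#'
#' @param ct_ip IP/pulldown Ct.
#' @param ct_input Input Ct.
#' @param input_fraction Fraction of material used as input, in `(0, 1]`.
#' @return Percent of input (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  stopifnot(all(input_fraction > 0), all(input_fraction <= 1))
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Fold enrichment over a control measurement
#'
#' Used both for RIP (IP over IgG) and for knockdown-versus-control ChIP
#' signal ratios. A zero control yields NA with a flag attribute.
#'
#' @param ip_value,control_value Numeric (vectorized).
#' @return Fold values; positions with zero control are NA and listed in the
#'   `undefined` attribute.
#' @export
fold_over_control <- function(ip_value, control_value) {
  fold <- ifelse(control_value > 0, ip_value / control_value, NA_real_)
  attr(fold, "undefined") <- which(!(control_value > 0))
  fold
}
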