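# qPCR validation arithmetic: McrBC-digestion methylation estimates,
# reference-normalized expression, and the two-sample comparison used for
# validation panels.

#' Methylation level from McrBC-digestion qPCR
#'
#' McrBC cuts methylated templates, so the digestion-resistant fraction
#' measures unmethylated DNA; the methylation level is
#' `1 - (McrBC / Input) = 1 - efficiency^-(cq_mcrbc - cq_input)`. Values
#' below zero (McrBC quantity exceeding input) are returned as-is with a
#' warning rather than clamped.
#'
#' @param cq_mcrbc,cq_input Quantification cycles (finite; vectors recycle).
#' @param efficiency Amplification efficiency, fold per cycle, in (1, 2]
#'   (default 2).
#' @return Methylation level(s), at most 1.
#' @export
methylation_level <- function(cq_mcrbc, cq_input, efficiency = 2) {
  .check_qpcr_args(c(cq_mcrbc, cq_input), efficiency)
  out <- 1 - efficiency^(-(cq_mcrbc - cq_input))
  if (any(out < 0)) {
    warning("methylation_level below 0 (McrBC signal exceeds input); reported raw")
  }
  out
}

#' Reference-normalized relative expression from qPCR
#'
#' `efficiency^-(cq_target - cq_reference)`: the target quantity as a ratio
#' to the reference transcript (e.g. Tbp).
#'
#' @param cq_target,cq_reference Quantification cycles (finite).
#' @param efficiency Amplification efficiency in (1, 2] (default 2).
#' @return Expression ratio(s), > 0.
#' @export
relative_expression <- function(cq_target, cq_reference, efficiency = 2) {
  .check_qpcr_args(c(cq_target, cq_reference), efficiency)
  efficiency^(-(cq_target - cq_reference))
}

.check_qpcr_args <- function(cq, efficiency) {
  if (any(!is.finite(cq))) stop_validation("Cq values must be finite")
  if (!(efficiency > 1 && efficiency <= 2)) {
    stop_validation("efficiency must lie in (1, 2]")
  }
}

#' Welch two-sample comparison
#'
#' Two-tailed heteroscedastic (unequal-variance) Student's t-test with
#' Satterthwaite degrees of freedom, as used for validation panels across
#' individuals.
#'
#' @param values_a,values_b Numeric vectors with at least 2 values each.
#' @return List: t statistic (a minus b), degrees of freedom, two-sided p.
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_validation("group_compare needs >= 2 values per group")
  }
  na <- length(values_a); nb <- length(values_b)
  va <- stats::var(values_a) / na
  vb <- stats::var(values_b) / nb
  se <- sqrt(va + vb)
  if (se == 0) return(list(t = 0, df = na + nb - 2, p = 1))
  t <- (mean(values_a) - mean(values_b)) / se
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Summarize a qPCR Cq table into per-sample levels
#'
#' Technical replicates are averaged per (sample_id, assay) before the
#' ratio arithmetic; each sample then yields a methylation level (assays
#' mcrbc vs input) or an expression ratio (target vs reference).
#'
#' @param cq_table Long Cq data frame: sample_id, timepoint, assay,
#'   replicate, cq (a `gene` column is carried through when present).
#' @param mode "methylation" or "expression".
#' @param efficiency Amplification efficiency (default 2).
#' @return Data frame: sample_id, timepoint (and gene), level.
#' @export
summarize_qpcr <- function(cq_table, mode = c("methylation", "expression"),
                           efficiency = 2) {
  mode <- match.arg(mode)
  assays <- if (mode == "methylation") c("mcrbc", "input") else c("target", "reference")
  if (!all(assays %in% cq_table$assay)) {
    stop_validation("cq_table lacks assays: %s", paste(assays, collapse = ", "))
  }
  mean_cq <- stats::aggregate(cq ~ sample_id + assay, data = cq_table, FUN = mean)
  samp <- unique(cq_table[, intersect(c("sample_id", "timepoint", "gene"),
                                      names(cq_table)), drop = FALSE])
  cq_of <- function(a) {
    mean_cq$cq[match(paste(samp$sample_id, a),
                     paste(mean_cq$sample_id, mean_cq$assay))]
  }
  samp$level <- if (mode == "methylation") {
    methylation_level(cq_of("mcrbc"), cq_of("input"), efficiency)
  } else {
    relative_expression(cq_of("target"), cq_of("reference"), efficiency)
  }
  rownames(samp) <- NULL
  samp
}

#' Compare qPCR levels between two timepoints
#'
#' @param levels Output of [summarize_qpcr()].
#' @param timepoint_a,timepoint_b Timepoint labels to compare.
#' @return [group_compare()] result plus group means.
#' @export
qpcr_compare_timepoints <- function(levels, timepoint_a, timepoint_b) {
  a <- levels$level[levels$timepoint == timepoint_a]
  b <- levels$level[levels$timepoint == timepoint_b]
  res <- group_compare(a, b)
  res$mean_a <- mean(a)
  res$mean_b <- mean(b)
  res
}
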