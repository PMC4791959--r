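# Expression-array summarisation: RMA-style probe-set summarisation by
# median polish, a quality-metric row filter, and fold-change calling.

#' Summarize one probe set into per-sample expression by median polish
#'
#' Fits the additive model `log2(signal) = overall + probe + sample`
#' robustly (iterative removal of row and column medians, tolerance 1e-6,
#' at most 10 iterations) and returns `overall + sample effect` per sample.
#' Input probes are expected to be background-corrected and
#' quantile-normalized already (see [normalize_expression_probes()]).
#'
#' @param probe_matrix Numeric matrix, probes x samples, of log2 intensities.
#' @return Named numeric vector of per-sample log2 expression.
#' @export
rma_summarize <- function(probe_matrix) {
  probe_matrix <- as.matrix(probe_matrix)
  if (nrow(probe_matrix) == 0 || ncol(probe_matrix) == 0) {
    stop_validation("empty probe set")
  }
  if (nrow(probe_matrix) == 1) {
    return(stats::setNames(as.numeric(probe_matrix[1, ]),
                           colnames(probe_matrix)))
  }
  fit <- stats::medpolish(probe_matrix, eps = 1e-6, maxiter = 10L,
                          trace.iter = FALSE)
  stats::setNames(fit$overall + fit$col, colnames(probe_matrix))
}

#' Normalize expression probes and summarize per transcript
#'
#' Reshapes a long probe table to probes x samples, applies the shared
#' background correction and quantile normalization, log2-transforms, and
#' median-polishes each transcript's probe set.
#'
#' @param probes Long data frame: probe_id, transcript_id, sample, signal.
#' @param se_metric Optional data frame (transcript_id, se_metric); missing
#'   transcripts default to 1.0.
#' @param annotation Optional `gene_annotation` used to attach gene symbols.
#' @param floor,bg_quantile Passed to [background_correct()].
#' @return An `expression_table` data frame: transcript_id, gene_symbol,
#'   one column per sample (log2 expression), se_metric.
#' @export
summarize_expression <- function(probes, se_metric = NULL, annotation = NULL,
                                 floor = 1, bg_quantile = 0.05) {
  samples <- unique(probes$sample)
  ids <- unique(probes$probe_id)
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  m[cbind(match(probes$probe_id, ids), match(probes$sample, samples))] <-
    probes$signal
  if (any(is.na(m))) stop_validation("every probe needs a value in every sample")
  m <- log2(quantile_normalize(background_correct(m, floor, bg_quantile)))
  tx_of <- probes$transcript_id[match(ids, probes$probe_id)]
  tx_ids <- unique(tx_of)
  expr <- t(vapply(tx_ids, function(tid) {
    rma_summarize(m[tx_of == tid, , drop = FALSE])
  }, numeric(length(samples))))
  out <- data.frame(transcript_id = tx_ids, stringsAsFactors = FALSE)
  out$gene_symbol <- if (!is.null(annotation)) {
    annotation$transcripts$gene_symbol[
      match(tx_ids, annotation$transcripts$transcript_id)]
  } else tx_ids
  out <- cbind(out, as.data.frame(expr))
  out$se_metric <- if (!is.null(se_metric)) {
    v <- se_metric$se_metric[match(tx_ids, se_metric$transcript_id)]
    ifelse(is.na(v), 1.0, v)
  } else 1.0
  attr(out, "samples") <- samples
  class(out) <- c("expression_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Filter an expression table on its quality metric
#'
#' Retains rows whose `se_metric` is at least `threshold` (rows strictly
#' below are removed, as per the array vendor's reported filter); the number
#' removed is reported via `message()`.
#'
#' @param table An `expression_table`.
#' @param threshold Retention threshold (default 0.8; boundary kept).
#' @return The filtered table.
#' @export
se_filter <- function(table, threshold = 0.8) {
  if (is.null(table$se_metric)) stop_validation("table lacks se_metric")
  keep <- table$se_metric >= threshold
  message(sprintf("se_filter: kept %d of %d transcripts (se_metric >= %g)",
                  sum(keep), length(keep), threshold))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially expressed transcripts between two samples
#'
#' Includes every transcript with `|log2FC| >= log2(min_fold)` ("at least"
#' an n-fold change: the boundary is included).
#'
#' @param table An `expression_table`.
#' @param contrast Ordered pair `c("A", "B")`; fold change is B minus A on
#'   the log2 scale.
#' @param min_fold Fold-change threshold (e.g. 2 or 1.5).
#' @return Data frame: transcript_id, gene_symbol, log2_fold_change,
#'   direction ("up"/"down"), contrast.
#' @export
call_differential <- function(table, contrast, min_fold = 2.0) {
  if (!all(contrast %in% names(table))) {
    stop_validation("unknown sample label(s): %s",
                    paste(setdiff(contrast, names(table)), collapse = ", "))
  }
  lfc <- table[[contrast[2]]] - table[[contrast[1]]]
  keep <- abs(lfc) >= log2(min_fold)
  data.frame(
    transcript_id = table$transcript_id[keep],
    gene_symbol = table$gene_symbol[keep],
    log2_fold_change = lfc[keep],
    direction = ifelse(lfc[keep] >= 0, "up", "down"),
    contrast = paste(contrast, collapse = ":"),
    stringsAsFactors = FALSE
  )
}
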