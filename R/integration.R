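# Methylome-transcriptome integration: pair DMRs with transcripts changing
# expression, classify pairs into the four methylation x expression
# quadrants, and track DMRs retained across contrasts.

.quadrants <- c("meth_up_expr_up", "meth_up_expr_down",
                "meth_down_expr_up", "meth_down_expr_down")

#' Pair annotated DMRs with expression changes
#'
#' One pair is emitted for every (DMR, transcript) mapping whose transcript
#' shows a qualifying expression change in the same contrast. Intergenic
#' mappings never pair (they have no transcript anchor); flagged
#' downstream-strip mappings do.
#'
#' @param dmr_annotations `mappings` data frame from [classify_dmrs()]
#'   (needs transcript_id, category, direction, mean_delta_ks, contrast).
#' @param de_calls Data frame from [call_differential()] at the pairing
#'   threshold (typically min_fold 1.5).
#' @return Data frame of pairs: dmr_id, transcript_id, gene_symbol,
#'   location_category, quadrant, delta_ks, log2_fold_change, contrast.
#' @export
pair_dmrs_with_expression <- function(dmr_annotations, de_calls) {
  ann <- dmr_annotations[!is.na(dmr_annotations$transcript_id) &
                           dmr_annotations$category != "intergenic", ,
                         drop = FALSE]
  if (nrow(ann) > 0 && nrow(de_calls) > 0) {
    ct_a <- unique(ann$contrast)
    ct_b <- unique(de_calls$contrast)
    if (length(ct_a) == 1 && length(ct_b) == 1 && !identical(ct_a, ct_b)) {
      stop_validation("contrast mismatch: DMRs are %s, expression is %s",
                      ct_a, ct_b)
    }
  }
  i <- match(ann$transcript_id, de_calls$transcript_id)
  keep <- !is.na(i)
  ann <- ann[keep, , drop = FALSE]
  i <- i[keep]
  meth_up <- ann$direction == "gain"
  expr_up <- de_calls$log2_fold_change[i] >= 0
  quadrant <- ifelse(meth_up,
                     ifelse(expr_up, "meth_up_expr_up", "meth_up_expr_down"),
                     ifelse(expr_up, "meth_down_expr_up", "meth_down_expr_down"))
  out <- data.frame(
    dmr_id = ann$dmr_id, transcript_id = ann$transcript_id,
    gene_symbol = ann$gene_symbol, location_category = ann$category,
    quadrant = quadrant, delta_ks = ann$mean_delta_ks,
    log2_fold_change = de_calls$log2_fold_change[i],
    contrast = ann$contrast, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Quadrant x location count table
#'
#' @param pairs Data frame from [pair_dmrs_with_expression()].
#' @return Data frame with one row per quadrant and columns distal,
#'   proximal, intragenic, total; the grand total equals `nrow(pairs)`.
#' @export
quadrant_counts <- function(pairs) {
  cats <- c("distal", "proximal", "intragenic")
  tb <- table(factor(pairs$quadrant, levels = .quadrants),
              factor(pairs$location_category, levels = cats))
  out <- as.data.frame.matrix(tb)
  out <- cbind(quadrant = .quadrants, out, total = rowSums(out))
  rownames(out) <- NULL
  out
}

#' Split pairs into positively and inversely correlated gene sets
#'
#' Positive correlation: methylation and expression move together (1st and
#' 3rd quadrants of the delta-KS vs log2FC plane); inverse: they oppose.
#' Also returns the dot-plot coordinates (delta_ks, log2_fold_change).
#'
#' @param pairs Data frame from [pair_dmrs_with_expression()].
#' @return List: `positive` and `inverse` (character vectors of gene
#'   symbols) and `dotplot` (gene_symbol, delta_ks, log2_fold_change,
#'   quadrant).
#' @export
correlation_gene_sets <- function(pairs) {
  pos <- pairs$quadrant %in% c("meth_up_expr_up", "meth_down_expr_down")
  list(
    positive = unique(pairs$gene_symbol[pos]),
    inverse = unique(pairs$gene_symbol[!pos]),
    dotplot = pairs[, c("gene_symbol", "delta_ks", "log2_fold_change",
                        "quadrant")]
  )
}

#' DMRs retained across later contrasts
#'
#' Returns the DMRs of the first (earliest) contrast whose span overlaps, by
#' at least one bp and with the same direction, a DMR in every later
#' contrast — methylation changes established early and retained.
#'
#' @param dmrs_first DMR data frame for the earliest contrast (e.g. d1:d7).
#' @param ... One or more DMR data frames for later contrasts sharing the
#'   same baseline (e.g. d1:w2, d1:w8).
#' @return Subset of `dmrs_first`.
#' @export
retained_changes <- function(dmrs_first, ...) {
  later <- list(...)
  if (length(later) == 0 || nrow(dmrs_first) == 0) return(dmrs_first)
  keep <- rep(TRUE, nrow(dmrs_first))
  gr1 <- GenomicRanges::GRanges(dmrs_first$chrom,
                                IRanges::IRanges(dmrs_first$start,
                                                 dmrs_first$end))
  for (d in later) {
    if (nrow(d) == 0) return(dmrs_first[0, , drop = FALSE])
    gr2 <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
    ov <- GenomicRanges::findOverlaps(gr1, gr2)
    same_dir <- dmrs_first$direction[S4Vectors::queryHits(ov)] ==
      d$direction[S4Vectors::subjectHits(ov)]
    keep <- keep & seq_len(nrow(dmrs_first)) %in%
      unique(S4Vectors::queryHits(ov)[same_dir])
  }
  out <- dmrs_first[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
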