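# TSS-anchored classification of DMRs: proximal, distal, intragenic,
# intergenic. Distances are signed along the gene: positive upstream of the
# TSS, negative downstream, measured from the DMR midpoint.

#' Signed strand-aware distance from a position to a TSS
#'
#' Positive when the position lies upstream (5') of the TSS, negative
#' downstream, on either strand.
#'
#' @param midpoint Numeric position(s) (e.g. DMR midpoints).
#' @param tss TSS position(s).
#' @param strand "+" or "-" (recycled).
#' @return Signed distance(s) in bp.
#' @export
signed_tss_distance <- function(midpoint, tss, strand) {
  ifelse(strand == "+", tss - midpoint, midpoint - tss)
}

# category precedence used when one DMR maps several ways
.category_rank <- c(proximal = 1, distal = 2, intragenic = 3, intergenic = 4)

#' Classify DMRs against a gene and CpG-island annotation
#'
#' For every transcript whose promoter window contains the DMR midpoint the
#' signed TSS distance `d` gives: proximal when `-100 <= d <= +500`, distal
#' when `+500 < d <= +5000`; the downstream strip `-500 <= d < -100`, which
#' the coordinate rules leave uncovered, is assigned to distal and flagged.
#' A DMR overlapping a CpG island contained inside a transcript span maps to
#' that transcript as intragenic. A DMR overlapping a CpG island but mapping
#' to no transcript at all is intergenic. Precedence per transcript is
#' proximal > distal > intragenic; each DMR's primary category comes from
#' its nearest-TSS window mapping, falling back to intragenic, then
#' intergenic.
#'
#' @param dmrs Data frame from [call_dmrs()].
#' @param annotation A `gene_annotation`.
#' @return List with `mappings` (dmr_id, transcript_id, gene_symbol,
#'   category, signed_tss_distance, flagged, direction, mean_delta_ks,
#'   contrast; one row per (DMR, transcript) pairing, intergenic rows carry
#'   NA transcript) and `primary` (one row per classified DMR, by
#'   precedence and nearest TSS).
#' @export
classify_dmrs <- function(dmrs, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  tx <- annotation$transcripts
  isl <- annotation$cpg_islands
  empty <- data.frame(
    dmr_id = character(0), transcript_id = character(0),
    gene_symbol = character(0), category = character(0),
    signed_tss_distance = numeric(0), flagged = logical(0),
    direction = character(0), mean_delta_ks = numeric(0),
    contrast = character(0), stringsAsFactors = FALSE
  )
  if (nrow(dmrs) == 0) return(list(mappings = empty, primary = empty))

  # CpG islands contained in transcript spans (intragenic anchors)
  if (nrow(isl) > 0) {
    gr_isl <- GenomicRanges::GRanges(isl$chrom,
                                     IRanges::IRanges(isl$start, isl$end))
    gr_tx <- GenomicRanges::GRanges(tx$chrom,
                                    IRanges::IRanges(tx$tx_start, tx$tx_end))
    gr_dmr <- GenomicRanges::GRanges(dmrs$chrom,
                                     IRanges::IRanges(dmrs$start, dmrs$end))
    isl_in_tx <- GenomicRanges::findOverlaps(gr_isl, gr_tx, type = "within")
    dmr_on_isl <- GenomicRanges::findOverlaps(gr_dmr, gr_isl)
  } else {
    isl_in_tx <- dmr_on_isl <- NULL
  }

  rows <- list()
  for (i in seq_len(nrow(dmrs))) {
    mid <- (dmrs$start[i] + dmrs$end[i]) / 2
    cand <- which(tx$chrom == dmrs$chrom[i])
    found <- FALSE
    if (length(cand) > 0) {
      d <- signed_tss_distance(mid, tx$tss[cand], tx$strand[cand])
      prox <- d >= -100 & d <= 500
      dist <- d > 500 & d <= 5000
      strip <- d >= -500 & d < -100
      hit <- which(prox | dist | strip)
      for (h in hit) {
        found <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          dmr_id = dmrs$dmr_id[i], transcript_id = tx$transcript_id[cand[h]],
          gene_symbol = tx$gene_symbol[cand[h]],
          category = if (prox[h]) "proximal" else "distal",
          signed_tss_distance = d[h], flagged = strip[h],
          stringsAsFactors = FALSE
        )
      }
    }
    # intragenic: DMR overlaps a CpG island lying within a transcript
    if (!is.null(dmr_on_isl)) {
      my_isl <- S4Vectors::subjectHits(dmr_on_isl)[
        S4Vectors::queryHits(dmr_on_isl) == i]
      if (length(my_isl) > 0 && length(isl_in_tx) > 0) {
        host_tx <- unique(S4Vectors::subjectHits(isl_in_tx)[
          S4Vectors::queryHits(isl_in_tx) %in% my_isl])
        for (h in host_tx) {
          found <- TRUE
          d <- signed_tss_distance(mid, tx$tss[h], tx$strand[h])
          rows[[length(rows) + 1L]] <- data.frame(
            dmr_id = dmrs$dmr_id[i], transcript_id = tx$transcript_id[h],
            gene_symbol = tx$gene_symbol[h],
            category = "intragenic", signed_tss_distance = d,
            flagged = FALSE, stringsAsFactors = FALSE
          )
        }
      }
      if (!found && length(my_isl) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          dmr_id = dmrs$dmr_id[i], transcript_id = NA_character_,
          gene_symbol = NA_character_, category = "intergenic",
          signed_tss_distance = NA_real_, flagged = FALSE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) return(list(mappings = empty, primary = empty))
  mappings <- do.call(rbind, rows)
  extra <- match(mappings$dmr_id, dmrs$dmr_id)
  mappings$direction <- dmrs$direction[extra]
  mappings$mean_delta_ks <- dmrs$mean_delta_ks[extra]
  mappings$contrast <- dmrs$contrast[extra]

  # primary category: precedence rank, then nearest TSS
  ord <- order(mappings$dmr_id, .category_rank[mappings$category],
               abs(mappings$signed_tss_distance))
  primary <- mappings[ord, , drop = FALSE]
  primary <- primary[!duplicated(primary$dmr_id), , drop = FALSE]
  rownames(primary) <- rownames(mappings) <- NULL
  list(mappings = mappings, primary = primary)
}

#' Genome-location distribution of classified DMRs
#'
#' Each DMR is counted once, by its primary (highest-precedence) category.
#'
#' @param classified Result of [classify_dmrs()] (or its `primary` element).
#' @return Named integer vector over proximal, distal, intragenic,
#'   intergenic.
#' @export
location_distribution <- function(classified) {
  primary <- if (is.data.frame(classified)) classified else classified$primary
  out <- c(proximal = 0L, distal = 0L, intragenic = 0L, intergenic = 0L)
  if (nrow(primary) > 0) {
    tb <- table(factor(primary$category, levels = names(out)))
    out[] <- as.integer(tb)
  }
  out
}
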