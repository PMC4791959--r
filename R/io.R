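# Plain-text interchange formats: probe/expression/Cq tables as TSV with
# header, annotation as BED6 (transcripts) + BED4 (CpG islands), DMRs as
# BED6+. Internal coordinates are 1-based inclusive; BED files are written
# 0-based half-open.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a long probe table
#'
#' Columns: probe_id, chrom, start, end, sample, ip_signal, input_signal,
#' plus log2_ratio when present.
#'
#' @param track Probe data frame.
#' @param path File path.
#' @return The path (write) or the data frame (read).
#' @export
write_probe_table <- function(track, path) write_tsv(track, path)

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  df <- read_tsv(path)
  need <- c("probe_id", "chrom", "start", "end", "sample", "ip_signal",
            "input_signal")
  if (!all(need %in% names(df))) {
    stop_validation("probe table %s lacks columns: %s", path,
                    paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' Write / read a gene annotation as BED
#'
#' Transcripts go to BED6 (name = transcript_id, strand used; the TSS is
#' recovered from the strand-appropriate span edge), CpG islands to BED4.
#'
#' @param annotation A `gene_annotation`.
#' @param transcripts_path,cpg_path File paths.
#' @return Invisibly, the paths (write) or a `gene_annotation` (read).
#' @export
write_annotation_bed <- function(annotation, transcripts_path, cpg_path) {
  tx <- annotation$transcripts
  write.table(
    data.frame(tx$chrom, tx$tx_start - 1, tx$tx_end, tx$transcript_id,
               0L, tx$strand),
    transcripts_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  isl <- annotation$cpg_islands
  write.table(
    data.frame(isl$chrom, isl$start - 1, isl$end, isl$island_id),
    cpg_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(c(transcripts_path, cpg_path))
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(transcripts_path, cpg_path) {
  tx <- utils::read.delim(transcripts_path, header = FALSE,
                          stringsAsFactors = FALSE)
  names(tx) <- c("chrom", "start0", "end", "transcript_id", "score", "strand")
  transcripts <- data.frame(
    transcript_id = tx$transcript_id, gene_symbol = tx$transcript_id,
    chrom = tx$chrom, strand = tx$strand,
    tss = ifelse(tx$strand == "+", tx$start0 + 1, tx$end),
    tx_start = tx$start0 + 1, tx_end = tx$end, stringsAsFactors = FALSE
  )
  isl <- utils::read.delim(cpg_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(isl) > 0) {
    names(isl) <- c("chrom", "start0", "end", "island_id")
    cpg <- data.frame(island_id = isl$island_id, chrom = isl$chrom,
                      start = isl$start0 + 1, end = isl$end,
                      stringsAsFactors = FALSE)
  } else {
    cpg <- data.frame(island_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE)
  }
  gene_annotation(transcripts, cpg)
}

#' Write DMRs as BED6+ text
#'
#' Standard six columns (score = `mean_delta_ks * 100` clamped to 0-1000,
#' strand '.') followed by direction, contrast, n_probes, mean_delta_log2.
#'
#' @param dmrs Data frame from [call_dmrs()].
#' @param path File path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(1000, pmax(0, round(abs(dmrs$mean_delta_ks) * 100)))
  write.table(
    data.frame(dmrs$chrom, dmrs$start - 1, dmrs$end, dmrs$dmr_id, score, ".",
               dmrs$direction, dmrs$contrast, dmrs$n_probes,
               dmrs$mean_delta_log2),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a KS score track as wiggle-like TSV
#'
#' @param ks A `ks_track` data frame.
#' @param path File path.
#' @export
write_ks_track <- function(ks, path) {
  write_tsv(ks[, c("chrom", "position", "sample", "ks_score",
                   "n_window_probes")], path)
}
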