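# Threshold-based DMR calling: maximal runs of >= 3 consecutive probes whose
# per-probe log2-ratio difference and KS-score difference both clear the
# thresholds in the same direction.

#' Per-probe deltas between two contrasted samples
#'
#' @param track_a,track_b Data frames for samples A and B with columns
#'   probe_id, chrom, start, end, log2_ratio, ks_score (one row per probe,
#'   identical probe sets and order).
#' @param contrast Optional label "A:B" recorded on the output.
#' @return Data frame: probe_id, chrom, start, end, delta_log2
#'   (`B - A`), delta_ks (`B - A`), contrast.
#' @export
probe_deltas <- function(track_a, track_b, contrast = NA_character_) {
  if (nrow(track_a) != nrow(track_b) ||
      !identical(track_a$probe_id, track_b$probe_id)) {
    stop_validation("tracks must cover identical probe sets in identical order")
  }
  data.frame(
    probe_id = track_a$probe_id, chrom = track_a$chrom,
    start = track_a$start, end = track_a$end,
    delta_log2 = track_b$log2_ratio - track_a$log2_ratio,
    delta_ks = track_b$ks_score - track_a$ks_score,
    contrast = contrast, stringsAsFactors = FALSE
  )
}

#' Join a normalized single-sample probe track with its KS track
#'
#' Attaches `ks_score` and `n_window_probes` by probe id, producing the
#' combined per-sample table that [probe_deltas()] consumes.
#'
#' @param track Single-sample probe data frame with `log2_ratio`.
#' @param ks Matching `ks_track` from [score_track()].
#' @return `track` with `ks_score` and `n_window_probes` columns.
#' @export
combine_track_scores <- function(track, ks) {
  i <- match(track$probe_id, ks$probe_id)
  if (any(is.na(i))) stop_validation("ks track does not cover all probes")
  track$ks_score <- ks$ks_score[i]
  track$n_window_probes <- ks$n_window_probes[i]
  track
}

#' Call differentially methylated regions from per-probe deltas
#'
#' A gain DMR is a maximal run of at least `min_probes` consecutive probes
#' with `delta_log2 >= log2(min_fold)` and `delta_ks >= min_delta_ks`
#' ("not less than": probes exactly at threshold pass). Losses use the
#' negated thresholds. Runs break at chromosome boundaries and at
#' inter-probe gaps (next start minus previous end, minus 1) larger than
#' `max_gap_bp`, so regions never bridge untiled genome.
#'
#' @param deltas Data frame from [probe_deltas()], sorted by (chrom, start).
#' @param min_probes Minimum consecutive passing probes (default 3).
#' @param min_fold Minimum fold change; per-probe threshold is
#'   `log2(min_fold)` (default 2).
#' @param min_delta_ks Minimum KS-score difference (default 1.0).
#' @param max_gap_bp Maximum bridged inter-probe gap (default 500).
#' @return Data frame of DMRs: dmr_id, chrom, start (first probe start), end
#'   (last probe end), n_probes, direction ("gain"/"loss" of B relative to
#'   A), contrast, mean_delta_log2, mean_delta_ks, size_bp.
#' @export
call_dmrs <- function(deltas, min_probes = 3L, min_fold = 2.0,
                      min_delta_ks = 1.0, max_gap_bp = 500) {
  if (min_probes <= 0 || min_fold <= 0 || min_delta_ks <= 0) {
    stop_validation("thresholds must be > 0")
  }
  if (!is_genomically_sorted(deltas$chrom, deltas$start)) {
    stop_validation("deltas must be sorted by (chrom, start)")
  }
  n <- nrow(deltas)
  empty <- data.frame(
    dmr_id = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), n_probes = integer(0), direction = character(0),
    contrast = character(0), mean_delta_log2 = numeric(0),
    mean_delta_ks = numeric(0), size_bp = numeric(0), stringsAsFactors = FALSE
  )
  if (n == 0) return(empty)
  lfc <- log2(min_fold)
  gap <- c(Inf, deltas$start[-1] - deltas$end[-n] - 1)
  new_chrom <- c(TRUE, deltas$chrom[-1] != deltas$chrom[-n])
  seg <- cumsum(new_chrom | gap > max_gap_bp)
  out <- list()
  for (dir in c("gain", "loss")) {
    pass <- if (dir == "gain") {
      deltas$delta_log2 >= lfc & deltas$delta_ks >= min_delta_ks
    } else {
      deltas$delta_log2 <= -lfc & deltas$delta_ks <= -min_delta_ks
    }
    # maximal runs of TRUE within segments
    run_id <- cumsum(c(TRUE, pass[-1] != pass[-n] | seg[-1] != seg[-n]))
    for (rid in unique(run_id[pass])) {
      idx <- which(run_id == rid)
      if (length(idx) < min_probes) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = deltas$chrom[idx[1]],
        start = deltas$start[idx[1]], end = deltas$end[idx[length(idx)]],
        n_probes = length(idx), direction = dir,
        contrast = deltas$contrast[idx[1]],
        mean_delta_log2 = mean(deltas$delta_log2[idx]),
        mean_delta_ks = mean(deltas$delta_ks[idx]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[genomic_order(res$chrom, res$start), , drop = FALSE]
  res$size_bp <- res$end - res$start + 1
  res$dmr_id <- sprintf("DMR%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("dmr_id", "chrom", "start", "end", "n_probes", "direction",
          "contrast", "mean_delta_log2", "mean_delta_ks", "size_bp")]
}

#' Summarize a DMR list
#'
#' Counts by direction and contrast plus a size histogram with the standard
#' reporting bins (< 500, 500-750, 750-1000, >= 1000 bp).
#'
#' @param dmrs Data frame from [call_dmrs()].
#' @return List with `counts` (data frame contrast, gains, losses) and
#'   `size_histogram` (named integer vector).
#' @export
summarize_dmrs <- function(dmrs) {
  bins <- c("<500" = 0L, "500-750" = 0L, "750-1000" = 0L, ">=1000" = 0L)
  if (nrow(dmrs) > 0) {
    cut_idx <- findInterval(dmrs$size_bp, c(500, 750, 1000)) + 1L
    tb <- tabulate(cut_idx, nbins = 4L)
    bins[] <- tb
    counts <- do.call(rbind, lapply(unique(dmrs$contrast), function(ct) {
      d <- dmrs[dmrs$contrast == ct, , drop = FALSE]
      data.frame(contrast = ct,
                 gains = sum(d$direction == "gain"),
                 losses = sum(d$direction == "loss"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    counts <- data.frame(contrast = character(0), gains = integer(0),
                         losses = integer(0), stringsAsFactors = FALSE)
  }
  list(counts = counts, size_histogram = bins)
}

#' Evaluate called DMRs against planted truth
#'
#' A planted region is recovered when a called DMR of the same direction
#' overlaps it by at least one bp; a called DMR is a true positive when it
#' overlaps a same-direction planted region.
#'
#' @param called Data frame from [call_dmrs()].
#' @param truth Planted-DMR data frame (chrom, start, end, direction).
#' @return List: sensitivity, precision, tp, fp, fn (NA rates when a
#'   denominator is empty).
#' @export
evaluate_dmr_recovery <- function(called, truth) {
  overlap_dir <- function(a, b) {
    # for each row of a: any same-direction >=1bp overlap in b?
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] & b$direction == a$direction[i] &
            b$start <= a$end[i] & b$end >= a$start[i])
    }, logical(1))
  }
  recovered <- if (nrow(truth) > 0) overlap_dir(truth, called) else logical(0)
  correct <- if (nrow(called) > 0) overlap_dir(called, truth) else logical(0)
  list(
    sensitivity = if (nrow(truth) > 0) mean(recovered) else NA_real_,
    precision = if (nrow(called) > 0) mean(correct) else NA_real_,
    tp = sum(correct), fp = sum(!correct), fn = sum(!recovered)
  )
}
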