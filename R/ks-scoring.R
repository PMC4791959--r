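# Sliding-window Kolmogorov-Smirnov scoring of probe log2-ratio tracks.
# Each probe's window (default 750 bp, centred on the probe midpoint, broken
# at inter-probe gaps > 500 bp) is compared against the whole-sample
# background distribution; the score is sign(median shift) * -log10(p).

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_t |ECDF_window(t) - ECDF_background(t)|`, handling ties exactly.
#'
#' @param window_values Numeric vector (non-empty).
#' @param background_values Numeric vector (non-empty).
#' @return D in `[0, 1]`.
#' @export
ks_statistic <- function(window_values, background_values) {
  if (length(window_values) < 1 || length(background_values) < 1) {
    stop_validation("ks_statistic needs non-empty samples")
  }
  sbg <- sort(background_values)
  .ks_stat_sorted(window_values, sbg)
}

# Core: background already sorted. The sup over t of |Fw - Fb| is attained
# either at a distinct window value v (right limits) or just below one
# (left limits, which also covers every background jump between window
# values and the region below the smallest window value).
.ks_stat_sorted <- function(window_values, sorted_bg) {
  k <- length(window_values)
  nb <- length(sorted_bg)
  v <- sort(unique(window_values))
  cum <- cumsum(tabulate(match(sort(window_values), v), nbins = length(v)))
  fw_at <- cum / k                      # Fw(v_i)
  fw_before <- c(0, cum[-length(cum)]) / k  # Fw(v_i-)
  fb_at <- findInterval(v, sorted_bg) / nb
  fb_before <- findInterval(v, sorted_bg, left.open = TRUE) / nb
  d <- max(abs(fw_at - fb_at), abs(fw_before - fb_before), 1 - fb_at[length(v)])
  min(1, d)
}

#' Asymptotic two-sample KS p-value
#'
#' Kolmogorov distribution tail `Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1)
#' exp(-2 k^2 lambda^2)` evaluated at `lambda = sqrt(n_eff) * D` with
#' effective size `n_eff = n_w * n_b / (n_w + n_b)`. Values of lambda below
#' 0.27 return 1 (series regime where p is 1 to double precision); the
#' result is floored at 1e-300.
#'
#' @param d KS statistic in `[0, 1]`.
#' @param n_window,n_background Sample sizes.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
ks_pvalue <- function(d, n_window, n_background) {
  n_eff <- n_window * n_background / (n_window + n_background)
  lambda <- sqrt(n_eff) * d
  if (lambda < 0.27) return(1)
  kk <- 1:100
  p <- 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lambda^2))
  min(1, max(p, 1e-300))
}

#' Score one sample's probe track with sliding-window KS scores
#'
#' For each probe, collects the log2 ratios of probes whose midpoints lie
#' within `window_bp / 2` of its own midpoint, restricted to the contiguous
#' run of probes around it with inter-probe gaps (next start minus previous
#' end, minus 1) of at most `max_gap_bp` — windows never bridge untiled
#' gaps. The window is compared against the whole-sample background by
#' [ks_statistic()]; the score is
#' `sign(median(window) - median(background)) * -log10(p)` with the
#' asymptotic p-value of [ks_pvalue()].
#'
#' @param track Probe data frame with log2_ratio (one sample's rows, or pass
#'   `sample` to subset a multi-sample track).
#' @param sample Optional sample label to subset.
#' @param window_bp Window width in bp (default 750).
#' @param max_gap_bp Maximum untiled gap bridged within a window and, by
#'   convention, by DMR runs (default 500).
#' @return A `ks_track` data frame: probe_id, chrom, position (probe
#'   midpoint), sample, ks_score, n_window_probes, sorted by (chrom,
#'   position).
#' @export
score_track <- function(track, sample = NULL, window_bp = 750,
                        max_gap_bp = 500) {
  if (window_bp <= 0) stop_validation("window_bp must be > 0")
  if (!is.null(sample)) track <- track[track$sample == sample, , drop = FALSE]
  if (is.null(track$log2_ratio)) stop_validation("track lacks log2_ratio; normalize first")
  if (length(unique(track$sample)) > 1) {
    stop_validation("score_track handles one sample at a time")
  }
  if (!is_genomically_sorted(track$chrom, track$start)) {
    stop_validation("track must be sorted by (chrom, start)")
  }
  n <- nrow(track)
  mid <- (track$start + track$end) / 2
  # segment breaks at chromosome changes or gaps > max_gap_bp
  gap <- c(Inf, track$start[-1] - track$end[-n] - 1)
  new_chrom <- c(TRUE, track$chrom[-1] != track$chrom[-n])
  seg <- cumsum(new_chrom | gap > max_gap_bp)
  bg <- sort(track$log2_ratio)
  bg_median <- stats::median(track$log2_ratio)
  half <- window_bp / 2
  score <- numeric(n)
  n_win <- integer(n)
  for (s in unique(seg)) {
    idx <- which(seg == s)           # contiguous, one chromosome, mid sorted
    m <- mid[idx]
    vals <- track$log2_ratio[idx]
    lo <- findInterval(m - half, m, left.open = TRUE) + 1L
    hi <- findInterval(m + half, m)
    for (r in seq_along(idx)) {
      w <- vals[lo[r]:hi[r]]
      d <- .ks_stat_sorted(w, bg)
      p <- ks_pvalue(d, length(w), n)
      shift <- stats::median(w) - bg_median
      i <- idx[r]
      score[i] <- sign(shift) * (-log10(p))
      n_win[i] <- hi[r] - lo[r] + 1L
    }
  }
  out <- data.frame(
    probe_id = track$probe_id, chrom = track$chrom, position = mid,
    sample = track$sample, ks_score = score, n_window_probes = n_win,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ks_track", "data.frame")
  out
}
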