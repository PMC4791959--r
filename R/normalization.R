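# Per-channel background correction and quantile normalization, followed by
# biweight-centred log2 IP/input ratios.

#' Background-correct an intensity matrix
#'
#' Subtracts a per-sample background estimate (by default the 5th percentile
#' of that sample's raw intensities, lower order statistic) and clamps the
#' result at `floor` so downstream log2 transforms are defined. Monotone
#' within each sample, so rank order is preserved up to ties created by the
#' clamp.
#'
#' @param signals Numeric matrix, probes x samples.
#' @param floor Minimum retained intensity (> 0, default 1).
#' @param bg_quantile Quantile of each column used as its background
#'   estimate (default 0.05).
#' @return Matrix of the same shape.
#' @export
background_correct <- function(signals, floor = 1, bg_quantile = 0.05) {
  signals <- as.matrix(signals)
  if (!all(is.finite(signals))) stop_validation("signals must be finite")
  if (floor <= 0) stop_validation("floor must be > 0")
  bg <- apply(signals, 2, stats::quantile, probs = bg_quantile, type = 1,
              names = FALSE)
  out <- sweep(signals, 2, bg, "-")
  out[out < floor] <- floor
  out
}

#' Quantile-normalize the columns of a matrix
#'
#' Forces every column to share the same empirical distribution: the
#' across-column mean of order statistics. Ties within a column receive the
#' mean of the reference values at their (average) rank positions.
#'
#' @param mat Numeric matrix, probes x samples; no missing values.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 1) stop_validation("need at least one column")
  if (any(!is.finite(mat))) stop_validation("matrix must be finite")
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

#' One-step Tukey biweight location estimate
#'
#' Starting from the median with MAD scale (consistency constant 1.4826),
#' weights each value by `(1 - u^2)^2` for `|u| < 1` where
#' `u = (x - median) / (c * MAD * 1.4826)`, zero otherwise, and returns the
#' weighted mean. If the MAD is zero the median is returned.
#'
#' @param values Numeric vector (>= 1 value, finite).
#' @param tuning_c Tuning constant c (default 5).
#' @return Scalar location estimate, within `range(values)`.
#' @export
biweight_location <- function(values, tuning_c = 5) {
  if (length(values) < 1) stop_validation("biweight_location needs >= 1 value")
  if (any(!is.finite(values))) stop_validation("values must be finite")
  med <- stats::median(values)
  s <- stats::mad(values, center = med)  # includes the 1.4826 constant
  if (s == 0) return(med)
  u <- (values - med) / (tuning_c * s)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * values) / sum(w)
}

#' Compute biweight-centred log2 IP/input ratios for a probe track
#'
#' For each sample, `log2(ip/input)` per probe minus the one-step biweight
#' location of that sample's ratios, so the per-sample biweight location of
#' the output is zero. Channels must already be background-corrected (floor
#' > 0 guarantees nonzero input).
#'
#' @param track Long probe data frame with columns probe_id, chrom, start,
#'   end, sample, ip_signal, input_signal.
#' @param tuning_c Biweight tuning constant (default 5).
#' @return `track` with a `log2_ratio` column added.
#' @export
compute_log2_ratios <- function(track, tuning_c = 5) {
  need <- c("probe_id", "chrom", "start", "end", "sample",
            "ip_signal", "input_signal")
  if (!all(need %in% names(track))) {
    stop_validation("track must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(track$input_signal <= 0) || any(track$ip_signal <= 0)) {
    stop_validation("channel intensities must be > 0 (background-correct first)")
  }
  raw <- log2(track$ip_signal / track$input_signal)
  track$log2_ratio <- raw
  for (s in unique(track$sample)) {
    idx <- track$sample == s
    track$log2_ratio[idx] <- raw[idx] - biweight_location(raw[idx], tuning_c)
  }
  track
}

#' Run the full two-channel normalization for a probe track
#'
#' Background-corrects and quantile-normalizes each channel separately
#' across samples, then computes biweight-centred log2 IP/input ratios.
#'
#' @param track Long probe data frame (probe_id, chrom, start, end, sample,
#'   ip_signal, input_signal); every sample must cover the same probes.
#' @param floor,bg_quantile Passed to [background_correct()].
#' @param tuning_c Passed to [compute_log2_ratios()].
#' @return The track, sorted by (chrom, start, sample), with normalized
#'   channel intensities and a `log2_ratio` column.
#' @export
normalize_probe_track <- function(track, floor = 1, bg_quantile = 0.05,
                                  tuning_c = 5) {
  samples <- unique(track$sample)
  ids <- unique(track$probe_id)
  wide <- function(col) {
    m <- matrix(NA_real_, length(ids), length(samples),
                dimnames = list(ids, samples))
    m[cbind(match(track$probe_id, ids), match(track$sample, samples))] <-
      track[[col]]
    if (any(is.na(m))) stop_validation("samples do not share a common probe set")
    m
  }
  ip <- quantile_normalize(background_correct(wide("ip_signal"),
                                              floor, bg_quantile))
  input <- quantile_normalize(background_correct(wide("input_signal"),
                                                 floor, bg_quantile))
  i <- match(track$probe_id, ids)
  j <- match(track$sample, samples)
  track$ip_signal <- ip[cbind(i, j)]
  track$input_signal <- input[cbind(i, j)]
  track <- compute_log2_ratios(track, tuning_c)
  track[order(as.character(track$chrom), track$start, match(track$sample, samples)), ,
        drop = FALSE]
}
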