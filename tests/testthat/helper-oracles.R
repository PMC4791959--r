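# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results by enumeration / brute force, separately
# from the package's own code paths.

# exhaustive ECDF-difference enumeration at all jump points and left limits
brute_ks <- function(w, b) {
  ts <- sort(unique(c(w, b)))
  fw_at <- rowMeans(outer(ts, w, ">="))
  fb_at <- rowMeans(outer(ts, b, ">="))
  fw_lt <- rowMeans(outer(ts, w, ">"))
  fb_lt <- rowMeans(outer(ts, b, ">"))
  max(abs(fw_at - fb_at), abs(fw_lt - fb_lt))
}

# per-probe collect-window-then-KS recomputation, growing outward from each
# probe and stopping at gaps > max_gap_bp; ks_stat_fn lets large tracks use
# stats::ks.test's D as the independent statistic oracle
naive_score_track <- function(track, window_bp = 750, max_gap_bp = 500,
                              ks_stat_fn = brute_ks) {
  n <- nrow(track)
  mid <- (track$start + track$end) / 2
  half <- window_bp / 2
  bg <- track$log2_ratio
  med_bg <- median(bg)
  vapply(seq_len(n), function(i) {
    lo <- i
    while (lo > 1 &&
           track$chrom[lo - 1] == track$chrom[i] &&
           track$start[lo] - track$end[lo - 1] - 1 <= max_gap_bp &&
           mid[i] - mid[lo - 1] <= half) lo <- lo - 1
    hi <- i
    while (hi < n &&
           track$chrom[hi + 1] == track$chrom[i] &&
           track$start[hi + 1] - track$end[hi] - 1 <= max_gap_bp &&
           mid[hi + 1] - mid[i] <= half) hi <- hi + 1
    w <- bg[lo:hi]
    p <- ks_pvalue(ks_stat_fn(w, bg), length(w), n)
    sign(median(w) - med_bg) * (-log10(p))
  }, numeric(1))
}

# exhaustive enumeration of all maximal qualifying runs
brute_call_dmrs <- function(deltas, min_probes = 3L, min_fold = 2,
                            min_delta_ks = 1, max_gap_bp = 500) {
  n <- nrow(deltas)
  lfc <- log2(min_fold)
  linked <- c(FALSE, deltas$chrom[-1] == deltas$chrom[-n] &
                deltas$start[-1] - deltas$end[-n] - 1 <= max_gap_bp)
  out <- list()
  for (dir in c("gain", "loss")) {
    pass <- if (dir == "gain") {
      deltas$delta_log2 >= lfc & deltas$delta_ks >= min_delta_ks
    } else {
      deltas$delta_log2 <= -lfc & deltas$delta_ks <= -min_delta_ks
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1 < min_probes) next
        span <- i:j
        if (!all(pass[span])) break
        if (j > i && !all(linked[(i + 1):j])) next
        ext_left <- i > 1 && linked[i] && pass[i - 1]
        ext_right <- j < n && linked[j + 1] && pass[j + 1]
        if (!ext_left && !ext_right) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = deltas$chrom[i], start = deltas$start[i],
            end = deltas$end[j], n_probes = j - i + 1L, direction = dir,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random per-probe delta tracks with occasional planted runs, for oracle
# equivalence testing
random_deltas <- function(n, two_chroms = TRUE) {
  spacing <- sample(c(100, 100, 100, 100, 900), n, replace = TRUE)
  start <- cumsum(spacing)
  chrom <- if (two_chroms && n >= 4) {
    c(rep("chrA", n %/% 2), rep("chrB", n - n %/% 2))
  } else rep("chrA", n)
  dl <- rnorm(n, 0, 0.8)
  dk <- rnorm(n, 0, 0.8)
  for (k in seq_len(max(1, n %/% 30))) {
    i <- sample.int(max(1, n - 5), 1)
    len <- sample(2:6, 1)
    span <- i:min(n, i + len - 1)
    s <- sample(c(-1, 1), 1)
    dl[span] <- dl[span] + s * 1.5
    dk[span] <- dk[span] + s * 1.5
  }
  data.frame(
    probe_id = sprintf("p%05d", seq_len(n)), chrom = chrom,
    start = start, end = start + 49,
    delta_log2 = dl, delta_ks = dk, contrast = "a:b",
    stringsAsFactors = FALSE
  )
}

# single-sample probe track with log2 ratios, irregular tiling
random_ratio_track <- function(n, sample = "s1") {
  spacing <- sample(c(100, 100, 100, 2000), n, replace = TRUE)
  start <- cumsum(spacing)
  half <- n %/% 2
  chrom <- c(rep("chrA", half), rep("chrB", n - half))
  start[(half + 1):n] <- cumsum(spacing[(half + 1):n])
  df <- data.frame(
    probe_id = sprintf("p%05d", seq_len(n)), chrom = chrom,
    start = start, end = start + 49, sample = sample,
    log2_ratio = rnorm(n, 0, 0.5), stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start), ]
}

# hand-enumerated genome-classification fixture (also stored as
# inst/extdata/classification_fixture.tsv); two transcripts on chrF plus a
# gene-body CpG island, an orphan intergenic island, and 12 DMRs placed at
# category boundaries on both strands
classification_fixture <- function() {
  transcripts <- data.frame(
    transcript_id = c("TPLUS", "TMINUS"),
    gene_symbol = c("GenePlus", "GeneMinus"),
    chrom = "chrF", strand = c("+", "-"),
    tss = c(100000, 300000),
    tx_start = c(100000, 290000), tx_end = c(110000, 300000),
    stringsAsFactors = FALSE
  )
  cpg_islands <- data.frame(
    island_id = c("CGI_BODY", "CGI_ORPHAN"),
    chrom = "chrF",
    start = c(104000, 500000), end = c(105000, 501000),
    stringsAsFactors = FALSE
  )
  mk <- function(id, mid) {
    data.frame(dmr_id = id, chrom = "chrF", start = mid - 5, end = mid + 5,
               n_probes = 3L, direction = "gain", contrast = "d1:d7",
               mean_delta_log2 = 1.5, mean_delta_ks = 1.5, size_bp = 11,
               stringsAsFactors = FALSE)
  }
  # midpoints chosen around the +5000 / +500 / -100 boundaries
  dmrs <- rbind(
    mk("D01_plus_d500", 99500),     # d = +500  -> proximal (boundary in)
    mk("D02_plus_d501", 99499),     # d = +501  -> distal
    mk("D03_plus_dm100", 100100),   # d = -100  -> proximal (boundary in)
    mk("D04_plus_dm101", 100101),   # d = -101  -> distal (flagged strip)
    mk("D05_plus_d5000", 95000),    # d = +5000 -> distal (boundary in)
    mk("D06_plus_d5001", 94999),    # d = +5001 -> unmapped
    mk("D07_intragenic", 104500),   # overlaps CGI_BODY inside TPLUS
    mk("D08_minus_d500", 300500),   # minus strand, d = +500 -> proximal
    mk("D09_minus_d501", 300501),   # minus strand, d = +501 -> distal
    mk("D10_minus_dm100", 299900),  # minus strand, d = -100 -> proximal
    mk("D11_minus_d5000", 305000),  # minus strand, d = +5000 -> distal
    mk("D12_intergenic", 500500)    # overlaps CGI_ORPHAN only
  )
  expected <- data.frame(
    dmr_id = dmrs$dmr_id,
    category = c("proximal", "distal", "proximal", "distal", "distal", NA,
                 "intragenic", "proximal", "distal", "proximal", "distal",
                 "intergenic"),
    flagged = c(FALSE, FALSE, FALSE, TRUE, FALSE, NA, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  list(annotation = gene_annotation(transcripts, cpg_islands),
       dmrs = dmrs, expected = expected)
}
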