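make_deltas <- function(delta_log2, delta_ks, start = NULL, chrom = "chr1") {
  n <- length(delta_log2)
  if (is.null(start)) start <- seq_len(n) * 100
  data.frame(probe_id = sprintf("p%03d", seq_len(n)), chrom = chrom,
             start = start, end = start + 49,
             delta_log2 = delta_log2, delta_ks = delta_ks,
             contrast = "d1:d7", stringsAsFactors = FALSE)
}

test_that("probe_deltas is elementwise subtraction with alignment checks", {
  tr <- random_ratio_track(50, sample = "a")
  tr$ks_score <- rnorm(50)
  trb <- tr
  trb$sample <- "b"
  # identical samples: zero deltas
  d0 <- probe_deltas(tr, trb)
  expect_equal(d0$delta_log2, rep(0, 50))
  expect_equal(d0$delta_ks, rep(0, 50))
  # constant shift
  trb$log2_ratio <- tr$log2_ratio + 1
  expect_equal(probe_deltas(tr, trb)$delta_log2, rep(1, 50))
  # random pair matches direct subtraction
  trb$log2_ratio <- rnorm(50); trb$ks_score <- rnorm(50)
  d <- probe_deltas(tr, trb)
  expect_equal(d$delta_log2, trb$log2_ratio - tr$log2_ratio)
  expect_equal(d$delta_ks, trb$ks_score - tr$ks_score)
  expect_error(probe_deltas(tr, trb[c(2:50, 1), ]), "identical probe sets")
})

test_that("call_dmrs reproduces the worked example", {
  deltas <- make_deltas(c(0.2, 1.2, 1.5, 1.1, 0.3),
                        c(0.5, 1.3, 2.0, 1.4, 0.2))
  dmrs <- call_dmrs(deltas)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$direction, "gain")
  expect_equal(dmrs$n_probes, 3L)
  expect_equal(dmrs$start, deltas$start[2])
  expect_equal(dmrs$end, deltas$end[4])
  expect_equal(dmrs$mean_delta_log2, mean(c(1.2, 1.5, 1.1)))
})

test_that("call_dmrs boundary and degenerate cases", {
  # only two consecutive passing probes: nothing called
  expect_equal(nrow(call_dmrs(make_deltas(c(1.5, 1.5, 0), c(2, 2, 0)))), 0L)
  # all-zero deltas: empty
  expect_equal(nrow(call_dmrs(make_deltas(rep(0, 10), rep(0, 10)))), 0L)
  # probes exactly at threshold pass ("not less than")
  at <- call_dmrs(make_deltas(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(at$n_probes, 3L)
  expect_equal(at$direction, "gain")
  # mirrored loss thresholds
  lo <- call_dmrs(make_deltas(c(-1, -1.2, -1), c(-1, -2, -1.5)))
  expect_equal(lo$direction, "loss")
  # a qualifying run split by a > 500 bp gap is not called
  gap <- make_deltas(rep(1.5, 4), rep(2, 4), start = c(100, 200, 1500, 1600))
  expect_equal(nrow(call_dmrs(gap)), 0L)
  # runs never span chromosomes
  two <- rbind(make_deltas(rep(1.5, 2), rep(2, 2), chrom = "chr1"),
               make_deltas(rep(1.5, 2), rep(2, 2), chrom = "chr2"))
  expect_equal(nrow(call_dmrs(two)), 0L)
  expect_error(call_dmrs(make_deltas(1, 1), min_fold = -1), "thresholds")
})

test_that("call_dmrs equals exhaustive maximal-run enumeration", {
  set.seed(41)
  for (rep in 1:60) {
    deltas <- random_deltas(sample(10:200, 1))
    got <- call_dmrs(deltas)
    want <- brute_call_dmrs(deltas)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      got_o <- got[order(got$chrom, got$start, got$direction),
                   c("chrom", "start", "end", "n_probes", "direction")]
      rownames(got_o) <- NULL
      expect_equal(got_o, want)
    }
  }
})

test_that("every called probe passes and flanks fail (per-probe + maximality)", {
  set.seed(43)
  for (rep in 1:20) {
    deltas <- random_deltas(150, two_chroms = FALSE)
    dmrs <- call_dmrs(deltas)
    for (k in seq_len(nrow(dmrs))) {
      idx <- which(deltas$start >= dmrs$start[k] & deltas$end <= dmrs$end[k])
      sgn <- if (dmrs$direction[k] == "gain") 1 else -1
      expect_true(all(sgn * deltas$delta_log2[idx] >= 1 &
                        sgn * deltas$delta_ks[idx] >= 1))
      expect_gte(length(idx), 3L)
      # maximality: adjacent in-gap flanks fail at least one threshold
      l <- min(idx) - 1
      if (l >= 1 && deltas$chrom[l] == dmrs$chrom[k] &&
          deltas$start[l + 1] - deltas$end[l] - 1 <= 500) {
        expect_false(sgn * deltas$delta_log2[l] >= 1 &
                       sgn * deltas$delta_ks[l] >= 1)
      }
      r <- max(idx) + 1
      if (r <= nrow(deltas) && deltas$chrom[r] == dmrs$chrom[k] &&
          deltas$start[r] - deltas$end[r - 1] - 1 <= 500) {
        expect_false(sgn * deltas$delta_log2[r] >= 1 &
                       sgn * deltas$delta_ks[r] >= 1)
      }
    }
  }
})

test_that("summarize_dmrs counts directions and bins sizes", {
  s0 <- summarize_dmrs(call_dmrs(make_deltas(rep(0, 5), rep(0, 5))))
  expect_equal(sum(s0$size_histogram), 0L)
  expect_equal(nrow(s0$counts), 0L)

  dmrs <- data.frame(
    dmr_id = sprintf("d%d", 1:4), chrom = "chr1",
    start = c(1, 1000, 2000, 4000), end = c(450, 1550, 2900, 5200),
    n_probes = 3L, direction = c("gain", "gain", "gain", "loss"),
    contrast = "d1:d7", mean_delta_log2 = 1, mean_delta_ks = 1,
    size_bp = c(450, 551, 901, 1201), stringsAsFactors = FALSE
  )
  s <- summarize_dmrs(dmrs)
  expect_equal(s$counts$gains, 3L)
  expect_equal(s$counts$losses, 1L)
  expect_equal(unname(s$size_histogram), c(1L, 1L, 1L, 1L))
  # boundary sizes: 500 falls in the 500-750 bin, 750 in 750-1000
  s2 <- summarize_dmrs(transform(dmrs, size_bp = c(499, 500, 750, 1000)))
  expect_equal(unname(s2$size_histogram), c(1L, 1L, 1L, 1L))
})

test_that("evaluate_dmr_recovery scores overlap and direction", {
  truth <- data.frame(chrom = "chr1", start = c(100, 1000), end = c(400, 1300),
                      direction = c("gain", "loss"), stringsAsFactors = FALSE)
  called <- data.frame(chrom = "chr1", start = c(350, 1000, 5000),
                       end = c(600, 1300, 5300),
                       direction = c("gain", "gain", "loss"),
                       stringsAsFactors = FALSE)
  r <- evaluate_dmr_recovery(called, truth)
  expect_equal(r$sensitivity, 0.5)   # loss truth matched only by a gain call
  expect_equal(r$precision, 1 / 3)
  expect_equal(r$tp, 1L)
})
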