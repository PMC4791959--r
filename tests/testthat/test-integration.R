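make_mappings <- function(n, categories = c("distal", "proximal", "intragenic"),
                          contrast = "d1:d7") {
  if (n == 0) {
    return(make_mappings(1, categories, contrast)[0, , drop = FALSE])
  }
  data.frame(
    dmr_id = sprintf("D%03d", seq_len(n)),
    transcript_id = sprintf("TX%03d", seq_len(n)),
    gene_symbol = sprintf("G%03d", seq_len(n)),
    category = sample(categories, n, replace = TRUE),
    signed_tss_distance = 0, flagged = FALSE,
    direction = sample(c("gain", "loss"), n, replace = TRUE),
    mean_delta_ks = rnorm(n), contrast = contrast, stringsAsFactors = FALSE
  )
}

make_de <- function(transcript_ids, lfc, contrast = "d1:d7") {
  data.frame(transcript_id = transcript_ids, gene_symbol = transcript_ids,
             log2_fold_change = lfc,
             direction = ifelse(lfc >= 0, "up", "down"),
             contrast = rep(contrast, length(transcript_ids)),
             stringsAsFactors = FALSE)
}

test_that("pairing joins DMR mappings with qualifying expression changes", {
  ann <- make_mappings(3)
  ann$direction <- c("gain", "gain", "loss")
  ann$category <- c("proximal", "intergenic", "distal")
  de <- make_de(c("TX001", "TX003"), c(0.8, -1.0))
  pairs <- pair_dmrs_with_expression(ann, de)
  # intergenic mapping TX002 never pairs; TX001 gain+up, TX003 loss+down
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$quadrant[pairs$transcript_id == "TX001"],
               "meth_up_expr_up")
  expect_equal(pairs$quadrant[pairs$transcript_id == "TX003"],
               "meth_down_expr_down")
  # a transcript absent from the DE call list (sub-threshold change) never pairs
  de_only1 <- make_de("TX001", 0.8)
  expect_equal(nrow(pair_dmrs_with_expression(ann, de_only1)), 1L)
  # contrast mismatch is an error
  expect_error(
    pair_dmrs_with_expression(ann, make_de("TX001", 1, contrast = "d1:w2")),
    "contrast mismatch"
  )
})

test_that("quadrant accounting and correlation sets partition the pairs", {
  expect_equal(sum(quadrant_counts(
    pair_dmrs_with_expression(make_mappings(0), make_de(character(0),
                                                        numeric(0))))$total), 0)
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(1:60, 1)
    ann <- make_mappings(n)
    de <- make_de(ann$transcript_id[sample.int(n, max(1, n %/% 2))],
                  lfc = runif(max(1, n %/% 2), -2, 2) + 0.6)
    pairs <- pair_dmrs_with_expression(ann, de)
    qc <- quadrant_counts(pairs)
    expect_equal(sum(qc$total), nrow(pairs))
    expect_equal(qc$total, qc$distal + qc$proximal + qc$intragenic)
    sets <- correlation_gene_sets(pairs)
    expect_length(intersect(sets$positive, sets$inverse), 0)
    expect_setequal(c(sets$positive, sets$inverse), unique(pairs$gene_symbol))
    expect_equal(nrow(sets$dotplot), nrow(pairs))
    # quadrant consistency with the signs
    up <- pairs$log2_fold_change >= 0
    gain <- ann$direction[match(pairs$dmr_id, ann$dmr_id)] == "gain"
    expect_equal(pairs$quadrant,
                 paste0("meth_", ifelse(gain, "up", "down"),
                        "_expr_", ifelse(up, "up", "down")))
  }
})

test_that("mirror-image pair sets swap the correlation lists", {
  set.seed(62)
  ann <- make_mappings(20)
  de <- make_de(ann$transcript_id, runif(20, 0.7, 2) * sample(c(-1, 1), 20, TRUE))
  pairs <- pair_dmrs_with_expression(ann, de)
  mirrored <- pairs
  mirrored$quadrant <- c(meth_up_expr_up = "meth_up_expr_down",
                         meth_up_expr_down = "meth_up_expr_up",
                         meth_down_expr_up = "meth_down_expr_down",
                         meth_down_expr_down = "meth_down_expr_up")[pairs$quadrant]
  a <- correlation_gene_sets(pairs)
  b <- correlation_gene_sets(mirrored)
  expect_setequal(a$positive, b$inverse)
  expect_setequal(a$inverse, b$positive)
})

test_that("retained_changes keeps same-direction overlaps across all contrasts", {
  d7 <- data.frame(dmr_id = c("a", "b", "c"), chrom = "chr1",
                   start = c(100, 1000, 2000), end = c(400, 1400, 2400),
                   direction = c("gain", "loss", "gain"),
                   stringsAsFactors = FALSE)
  # a: present everywhere; b: direction flips in w8; c: absent from w2
  w2 <- data.frame(chrom = "chr1", start = c(350, 1200), end = c(600, 1500),
                   direction = c("gain", "loss"), stringsAsFactors = FALSE)
  w8 <- data.frame(chrom = "chr1", start = c(100, 1000, 2000),
                   end = c(400, 1400, 2400),
                   direction = c("gain", "gain", "gain"),
                   stringsAsFactors = FALSE)
  kept <- retained_changes(d7, w2, w8)
  expect_equal(kept$dmr_id, "a")
  # identical lists everywhere: everything retained
  expect_equal(retained_changes(d7, d7, d7)$dmr_id, d7$dmr_id)
  # an empty later contrast empties the result
  expect_equal(nrow(retained_changes(d7, d7[0, ], d7)), 0L)
})

test_that("retained_changes matches a brute-force interval check", {
  set.seed(63)
  rand_dmrs <- function(n) {
    start <- sort(sample.int(5000, n)) * 10
    data.frame(dmr_id = sprintf("r%03d", seq_len(n)),
               chrom = sample(c("c1", "c2"), n, TRUE),
               start = start, end = start + sample(200:600, n, TRUE),
               direction = sample(c("gain", "loss"), n, TRUE),
               stringsAsFactors = FALSE)
  }
  for (rep in 1:10) {
    a <- rand_dmrs(30); b <- rand_dmrs(25); c <- rand_dmrs(25)
    got <- retained_changes(a, b, c)$dmr_id
    want <- a$dmr_id[vapply(seq_len(nrow(a)), function(i) {
      hit <- function(x) any(x$chrom == a$chrom[i] &
                               x$direction == a$direction[i] &
                               x$start <= a$end[i] & x$end >= a$start[i])
      hit(b) && hit(c)
    }, logical(1))]
    expect_equal(got, want)
  }
})
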