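test_that("simulate_annotation honours the spec and is deterministic", {
  spec <- synthetic_genome_spec(n_genes = 10L, seed = 42L)
  ann <- simulate_annotation(spec)
  expect_equal(nrow(ann$transcripts), 10L)
  expect_true(all(ann$transcripts$tss >= ann$transcripts$tx_start &
                    ann$transcripts$tss <= ann$transcripts$tx_end))

  no_isl <- simulate_annotation(synthetic_genome_spec(n_genes = 10L,
                                                      cpg_island_fraction = 0))
  expect_equal(nrow(no_isl$cpg_islands), 0L)

  a1 <- simulate_annotation(synthetic_genome_spec(n_genes = 200L, seed = 7L))
  a2 <- simulate_annotation(synthetic_genome_spec(n_genes = 200L, seed = 7L))
  expect_identical(a1, a2)

  expect_error(
    simulate_annotation(synthetic_genome_spec(n_genes = 500L,
                                              chrom_length = 20000)),
    "too short"
  )
})

test_that("spec invariants are validated", {
  expect_error(synthetic_genome_spec(n_genes = 0), "n_genes")
  expect_error(synthetic_genome_spec(tile_upstream = 100,
                                     tile_downstream = 200), "tile_upstream")
  expect_error(synthetic_genome_spec(probe_spacing = 0), "probe_spacing")
})

test_that("every probe lies in a TSS tiling window (coverage invariant)", {
  spec <- synthetic_genome_spec(n_genes = 40L, seed = 3L)
  ann <- simulate_annotation(spec)
  probes <- tile_promoter_probes(ann)
  tx <- ann$transcripts
  mid <- (probes$start + probes$end) / 2
  i <- match(probes$transcript_id, tx$transcript_id)
  d <- signed_tss_distance(mid, tx$tss[i], tx$strand[i])
  expect_true(all(d <= spec$tile_upstream & d >= -spec$tile_downstream))
})

test_that("zero-noise methylation arrays carry exactly the planted effect", {
  spec <- synthetic_genome_spec(n_genes = 20L, seed = 11L)
  ann <- simulate_annotation(spec)
  layout <- tile_promoter_probes(ann)
  planted <- plant_dmrs(ann, layout, n = 1L, n_probes = 4L, effect_size = 1.5,
                        prop_gain = 1, seed = 5L)
  sim <- simulate_methylation_arrays(ann, planted, noise_sd = 0, seed = 9L)
  ratio <- function(s) {
    d <- sim$probes[sim$probes$sample == s, ]
    log2(d$ip_signal / d$input_signal)[order(d$probe_id)]
  }
  diff <- ratio("d7") - ratio("d1")
  d <- sim$probes[sim$probes$sample == "d1", ]
  d <- d[order(d$probe_id), ]
  in_region <- d$chrom == planted$chrom & d$start <= planted$end &
    d$end >= planted$start
  expect_equal(sum(in_region), 4L)
  expect_equal(diff[in_region], rep(1.5, 4))
  expect_equal(diff[!in_region], rep(0, sum(!in_region)))

  # no planted DMRs, zero noise: all contrast differences are 0
  sim0 <- simulate_methylation_arrays(ann, NULL, noise_sd = 0, seed = 9L)
  r <- function(s) {
    d <- sim0$probes[sim0$probes$sample == s, ]
    log2(d$ip_signal / d$input_signal)[order(d$probe_id)]
  }
  expect_equal(r("d7") - r("d1"), rep(0, nrow(layout)))
})

test_that("null contrast differences satisfy the CLT bound at noise_sd 0.3", {
  spec <- synthetic_genome_spec(n_genes = 200L, seed = 21L)
  ann <- simulate_annotation(spec)
  sim <- simulate_methylation_arrays(ann, NULL, noise_sd = 0.3, seed = 22L)
  d1 <- sim$probes[sim$probes$sample == "d1", ]
  d7 <- sim$probes[sim$probes$sample == "d7", ]
  stopifnot(identical(d1$probe_id, d7$probe_id))
  diff <- log2(d7$ip_signal / d7$input_signal) -
    log2(d1$ip_signal / d1$input_signal)
  n <- length(diff)
  expect_gte(n, 10000)
  expect_lt(abs(mean(diff)), 3 * (0.3 * sqrt(2)) / sqrt(n))
  # and the contrast-difference sd itself is noise_sd * sqrt(2)
  expect_lt(abs(sd(diff) - 0.3 * sqrt(2)), 0.02)
})

test_that("planted regions must overlap tiled probes", {
  spec <- synthetic_genome_spec(n_genes = 5L, seed = 1L)
  ann <- simulate_annotation(spec)
  bad <- data.frame(gene_id = "TX0001", chrom = "chr9", start = 10,
                    end = 400, direction = "gain", effect_size = 1.5,
                    n_probes = 4L, contrast = "d1:d7",
                    stringsAsFactors = FALSE)
  expect_error(simulate_methylation_arrays(ann, bad, noise_sd = 0),
               "overlaps no tiled probe")
})

test_that("zero-noise expression probes recover the planted fold change", {
  spec <- synthetic_genome_spec(n_genes = 8L, seed = 2L)
  ann <- simulate_annotation(spec)
  tid <- ann$transcripts$transcript_id[1]
  planted <- data.frame(transcript_id = tid, log2_fold_change = 1.0,
                        contrast = "d1:d7", stringsAsFactors = FALSE)
  sim <- simulate_expression(ann, planted, noise_sd = 0,
                             n_probes_per_transcript = 3L, seed = 4L)
  m <- with(sim$probes[sim$probes$transcript_id == tid, ],
            tapply(log2(signal), list(probe_id, sample), mean))
  expr <- rma_summarize(m)
  expect_equal(unname(expr["d7"] - expr["d1"]), 1.0)

  empty <- simulate_expression(ann, NULL, noise_sd = 0, seed = 4L)
  m2 <- with(empty$probes, tapply(log2(signal), list(probe_id, sample), mean))
  expect_equal(unname(m2[, "d7"] - m2[, "d1"]), rep(0, nrow(m2)))

  expect_error(
    simulate_expression(ann, data.frame(transcript_id = "NOPE",
                                        log2_fold_change = 1,
                                        contrast = "d1:d7")),
    "not in annotation"
  )
})

test_that("generators are bit-identical under a fixed seed", {
  spec <- synthetic_genome_spec(n_genes = 15L, seed = 6L)
  ann <- simulate_annotation(spec)
  layout <- tile_promoter_probes(ann)
  planted <- plant_dmrs(ann, layout, n = 3L, seed = 8L)
  m1 <- simulate_methylation_arrays(ann, planted, noise_sd = 0.3, seed = 10L)
  m2 <- simulate_methylation_arrays(ann, planted, noise_sd = 0.3, seed = 10L)
  expect_identical(m1, m2)
  e1 <- simulate_expression(ann, NULL, seed = 10L)
  e2 <- simulate_expression(ann, NULL, seed = 10L)
  expect_identical(e1, e2)
  q1 <- simulate_qpcr_cq(data.frame(gene = "g", timepoint = "d1",
                                    methylation = 0.6), seed = 3L)
  q2 <- simulate_qpcr_cq(data.frame(gene = "g", timepoint = "d1",
                                    methylation = 0.6), seed = 3L)
  expect_identical(q1, q2)
})

test_that("zero-noise planted probes clear the fold threshold (truth-consistency)", {
  # every planted probe's zero-noise log2-ratio contrast difference equals
  # the planted effect, so it meets the downstream delta-log2 >= 1 rule
  # whenever effect_size >= 1 (KS scores are not testable on degenerate
  # noise-free tracks; see the vignette)
  prof <- simulate_default_profile(seed = 3L, noise_sd = 0, n_dmrs = 8L,
                                   effect_size = 1.0, n_genes = 60L)
  raw <- prof$meth$probes
  ratio <- function(s) {
    d <- raw[raw$sample == s, ]
    d <- d[order(d$probe_id), ]
    cbind(d[, c("chrom", "start", "end")],
          r = log2(d$ip_signal / d$input_signal))
  }
  base <- ratio("d1")
  for (later in c("d7", "w2", "w8")) {
    diff <- ratio(later)$r - base$r
    truth <- prof$planted_dmrs[prof$planted_dmrs$contrast ==
                                 paste0("d1:", later), ]
    for (k in seq_len(nrow(truth))) {
      idx <- base$chrom == truth$chrom[k] & base$start <= truth$end[k] &
        base$end >= truth$start[k]
      sgn <- if (truth$direction[k] == "gain") 1 else -1
      expect_equal(sgn * diff[idx], rep(truth$effect_size[k], sum(idx)))
      expect_true(all(sgn * diff[idx] >= 1))
    }
  }
})
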