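# Synthetic-data generator: promoter-centric tiling-array and expression-array
# simulator with planted methylation / expression changes, providing ground
# truth for every downstream stage.

#' Describe a synthetic genome for the simulator
#'
#' Parameters of the simulated promoter array world: gene count, chromosome
#' geometry, and the promoter tiling window. Probes are laid out only around
#' transcription start sites (TSSs), from `tile_upstream` bp upstream to
#' `tile_downstream` bp downstream, mirroring CpG-island-plus-promoter tiling
#' designs.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of transcripts to place.
#' @param cpg_island_fraction Fraction of genes that carry a promoter CpG
#'   island.
#' @param probe_spacing Distance in bp between consecutive probe starts
#'   (default 100).
#' @param tile_upstream Tiled bp upstream of each TSS (default 5000).
#' @param tile_downstream Tiled bp downstream of each TSS (default 500).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 4L,
                                  chrom_length = 2e6,
                                  n_genes = 200L,
                                  cpg_island_fraction = 0.7,
                                  probe_spacing = 100L,
                                  tile_upstream = 5000L,
                                  tile_downstream = 500L,
                                  seed = 42L) {
  if (n_genes < 1) stop_validation("n_genes must be >= 1")
  if (probe_spacing < 1) stop_validation("probe_spacing must be >= 1")
  if (!(tile_upstream > tile_downstream && tile_downstream >= 0)) {
    stop_validation("need tile_upstream > tile_downstream >= 0")
  }
  if (cpg_island_fraction < 0 || cpg_island_fraction > 1) {
    stop_validation("cpg_island_fraction must be in [0, 1]")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.numeric(chrom_length),
      n_genes = as.integer(n_genes),
      cpg_island_fraction = cpg_island_fraction,
      probe_spacing = as.integer(probe_spacing),
      tile_upstream = as.integer(tile_upstream),
      tile_downstream = as.integer(tile_downstream),
      seed = as.integer(seed)
    ),
    class = "synthetic_genome_spec"
  )
}

#' Simulate a gene and CpG-island annotation
#'
#' Places `n_genes` transcripts on the synthetic chromosomes so that their
#' promoter tiling windows never overlap (one gene per chromosome "slot").
#' A `cpg_island_fraction` of genes receives a promoter CpG island spanning
#' 500 bp upstream to 1000 bp downstream of the TSS (strand-aware).
#'
#' @param spec A [synthetic_genome_spec()].
#' @return An object of class `gene_annotation`: a list with data frames
#'   `transcripts` (transcript_id, gene_symbol, chrom, strand, tss,
#'   tx_start, tx_end) and `cpg_islands` (island_id, chrom, start, end),
#'   carrying `spec` as an attribute.
#' @export
simulate_annotation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  genes_per_chrom <- ceiling(spec$n_genes / spec$n_chromosomes)
  slot <- floor(spec$chrom_length / genes_per_chrom)
  footprint <- spec$tile_upstream + spec$tile_downstream + 2L * spec$probe_spacing
  if (slot <= footprint) {
    stop_validation(
      "chromosomes too short: slot width %d bp cannot hold a %d bp tiling window",
      slot, footprint
    )
  }
  with_seed(spec$seed, {
    chrom <- sprintf("chr%d", 1L + (seq_len(spec$n_genes) - 1L) %/% genes_per_chrom)
    slot_idx <- (seq_len(spec$n_genes) - 1L) %% genes_per_chrom
    slot_start <- slot_idx * slot + 1
    # TSS placed so the full tiling window sits inside the slot
    lo <- slot_start + spec$tile_upstream
    hi <- slot_start + slot - 1 - spec$tile_upstream
    tss <- floor(lo + runif(spec$n_genes) * pmax(1, hi - lo))
    strand <- ifelse(runif(spec$n_genes) < 0.5, "+", "-")
    tx_len <- floor(runif(spec$n_genes, 2000, 15000))
    tx_start <- ifelse(strand == "+", tss, pmax(1, tss - tx_len))
    tx_end <- ifelse(strand == "+", pmin(spec$chrom_length, tss + tx_len), tss)
    transcripts <- data.frame(
      transcript_id = sprintf("TX%04d", seq_len(spec$n_genes)),
      gene_symbol = sprintf("Gene%04d", seq_len(spec$n_genes)),
      chrom = chrom, strand = strand,
      tss = as.numeric(tss),
      tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end),
      stringsAsFactors = FALSE
    )
    n_isl <- round(spec$cpg_island_fraction * spec$n_genes)
    has_island <- sort(sample.int(spec$n_genes, n_isl))
    if (n_isl > 0) {
      up <- 500; down <- 1000
      isl_start <- ifelse(strand[has_island] == "+",
                          tss[has_island] - up, tss[has_island] - down)
      isl_end <- ifelse(strand[has_island] == "+",
                        tss[has_island] + down, tss[has_island] + up)
      cpg_islands <- data.frame(
        island_id = sprintf("CGI%04d", seq_len(n_isl)),
        chrom = chrom[has_island],
        start = pmax(1, isl_start), end = pmin(spec$chrom_length, isl_end),
        stringsAsFactors = FALSE
      )
    } else {
      cpg_islands <- data.frame(
        island_id = character(0), chrom = character(0),
        start = numeric(0), end = numeric(0), stringsAsFactors = FALSE
      )
    }
    ord <- genomic_order(transcripts$chrom, transcripts$tss)
    transcripts <- transcripts[ord, , drop = FALSE]
    rownames(transcripts) <- NULL
    gene_annotation(transcripts, cpg_islands, spec = spec)
  })
}

#' Construct a gene_annotation object
#'
#' @param transcripts Data frame with columns transcript_id, gene_symbol,
#'   chrom, strand, tss, tx_start, tx_end.
#' @param cpg_islands Data frame with columns chrom, start, end (island_id
#'   optional).
#' @param spec Optional [synthetic_genome_spec()] recording tiling geometry.
#' @return A `gene_annotation` list.
#' @export
gene_annotation <- function(transcripts, cpg_islands, spec = NULL) {
  need <- c("transcript_id", "gene_symbol", "chrom", "strand", "tss",
            "tx_start", "tx_end")
  if (!all(need %in% names(transcripts))) {
    stop_validation("transcripts must have columns: %s", paste(need, collapse = ", "))
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop_validation("strand must be '+' or '-'")
  }
  if (any(transcripts$tss < transcripts$tx_start | transcripts$tss > transcripts$tx_end)) {
    stop_validation("tss must lie within the transcript span")
  }
  if (!("island_id" %in% names(cpg_islands)) && nrow(cpg_islands) > 0) {
    cpg_islands$island_id <- sprintf("CGI%04d", seq_len(nrow(cpg_islands)))
  }
  structure(list(transcripts = transcripts, cpg_islands = cpg_islands),
            class = "gene_annotation", spec = spec)
}

#' Lay out tiling probes around every TSS
#'
#' Probes of fixed 50 bp length are placed every `probe_spacing` bp across
#' the window from `tile_upstream` bp upstream to `tile_downstream` bp
#' downstream of each TSS, strand-aware.
#'
#' @param annotation A `gene_annotation` whose `spec` attribute (or the
#'   explicit arguments) define the tiling geometry.
#' @param probe_spacing,tile_upstream,tile_downstream Override the spec.
#' @param probe_length Probe length in bp (default 50).
#' @return Data frame: probe_id, chrom, start, end, transcript_id, sorted by
#'   (chrom, start).
#' @export
tile_promoter_probes <- function(annotation, probe_spacing = NULL,
                                 tile_upstream = NULL, tile_downstream = NULL,
                                 probe_length = 50L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  spec <- attr(annotation, "spec")
  probe_spacing <- probe_spacing %||% spec$probe_spacing %||% 100L
  tile_upstream <- tile_upstream %||% spec$tile_upstream %||% 5000L
  tile_downstream <- tile_downstream %||% spec$tile_downstream %||% 500L
  tx <- annotation$transcripts
  pieces <- lapply(seq_len(nrow(tx)), function(i) {
    if (tx$strand[i] == "+") {
      lo <- tx$tss[i] - tile_upstream
      hi <- tx$tss[i] + tile_downstream
    } else {
      lo <- tx$tss[i] - tile_downstream
      hi <- tx$tss[i] + tile_upstream
    }
    starts <- seq(lo, hi - probe_length + 1, by = probe_spacing)
    data.frame(
      chrom = tx$chrom[i], start = starts, end = starts + probe_length - 1,
      transcript_id = tx$transcript_id[i], stringsAsFactors = FALSE
    )
  })
  probes <- do.call(rbind, pieces)
  probes <- probes[genomic_order(probes$chrom, probes$start), , drop = FALSE]
  probes$probe_id <- sprintf("P%06d", seq_len(nrow(probes)))
  rownames(probes) <- NULL
  probes[, c("probe_id", "chrom", "start", "end", "transcript_id")]
}

#' Plant differentially methylated regions in a synthetic annotation
#'
#' Chooses `n` distinct genes and, within each gene's tiling window, a run of
#' `n_probes` consecutive probes; the spanned interval becomes a planted DMR
#' with the given direction and effect size for the stated contrast.
#'
#' @param annotation A `gene_annotation`.
#' @param probes Probe layout from [tile_promoter_probes()].
#' @param n Number of DMRs to plant.
#' @param n_probes Probes per planted region (>= 3).
#' @param effect_size Added log2 IP/input enrichment (> 0).
#' @param contrast Ordered sample pair, e.g. `c("d1", "d7")`; the effect is
#'   applied to the later sample.
#' @param prop_gain Fraction of planted regions that are gains.
#' @param seed Integer seed.
#' @return Data frame of planted DMRs: gene_id, chrom, start, end, direction,
#'   effect_size, n_probes, contrast (as "A:B").
#' @export
plant_dmrs <- function(annotation, probes, n = 50L, n_probes = 4L,
                       effect_size = 1.5, contrast = c("d1", "d7"),
                       prop_gain = 0.5, seed = 1L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (n_probes < 3) stop_validation("planted DMRs need n_probes >= 3")
  if (effect_size <= 0) stop_validation("effect_size must be > 0")
  tx_ids <- unique(probes$transcript_id)
  if (n > length(tx_ids)) stop_validation("cannot plant %d DMRs on %d genes", n, length(tx_ids))
  if (n == 0) {
    return(data.frame(
      gene_id = character(0), chrom = character(0), start = numeric(0),
      end = numeric(0), direction = character(0), effect_size = numeric(0),
      n_probes = integer(0), contrast = character(0), stringsAsFactors = FALSE
    ))
  }
  with_seed(seed, {
    genes <- sample(tx_ids, n)
    rows <- lapply(genes, function(g) {
      p <- probes[probes$transcript_id == g, , drop = FALSE]
      if (nrow(p) < n_probes) stop_validation("gene %s has too few probes", g)
      i0 <- sample.int(nrow(p) - n_probes + 1L, 1L)
      run <- p[i0:(i0 + n_probes - 1L), , drop = FALSE]
      data.frame(
        gene_id = g, chrom = run$chrom[1],
        start = min(run$start), end = max(run$end),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$direction <- ifelse(seq_len(n) <= round(prop_gain * n), "gain", "loss")
    out$effect_size <- effect_size
    out$n_probes <- as.integer(n_probes)
    out$contrast <- paste(contrast, collapse = ":")
    rownames(out) <- NULL
    out
  })
}

#' Simulate two-channel MeDIP tiling-array intensities
#'
#' Generates log-normal IP and input channel intensities for each probe and
#' sample. Each probe carries a shared affinity term; the IP channel of the
#' later sample of a planted contrast additionally carries the planted
#' effect (+ for gains, - for losses) on all probes overlapping the region.
#' Channel noise is scaled so that the per-probe log2(IP/input) ratio has
#' standard deviation `noise_sd` within a sample (each channel receives
#' independent Gaussian noise of sd `noise_sd / sqrt(2)` on the log2 scale),
#' so a contrast difference of ratios has sd `noise_sd * sqrt(2)`.
#'
#' A `dim_probe_fraction` of probes (never inside planted regions) is
#' rendered as near-background features at `dim_log2` mean intensity in both
#' channels, emulating the empty/failed/unenriched spots that percentile
#' background estimators rely on: the 5th-percentile background correction
#' removes these features while leaving functional probes essentially
#' untouched.
#'
#' @param annotation A `gene_annotation` (tiling geometry read from its spec).
#' @param planted Data frame of planted DMRs from [plant_dmrs()] (may be
#'   empty or NULL).
#' @param noise_sd Standard deviation of the per-sample log2 ratio noise.
#' @param samples Ordered sample labels (default d1, d7, w2, w8).
#' @param seed Integer seed.
#' @param baseline_log2 Mean log2 intensity of the input channel.
#' @param affinity_sd Probe-to-probe sd of the shared affinity term.
#' @param dim_probe_fraction Fraction of probes rendered as near-background
#'   features (default 0.05).
#' @param dim_log2 Mean log2 intensity of dim features (default 5).
#' @return List with `probes` (long data frame: probe_id, chrom, start, end,
#'   sample, ip_signal, input_signal) and `truth` (the planted table).
#' @export
simulate_methylation_arrays <- function(annotation, planted = NULL,
                                        noise_sd = 0.3,
                                        samples = c("d1", "d7", "w2", "w8"),
                                        seed = 1L,
                                        baseline_log2 = 10,
                                        affinity_sd = 1,
                                        dim_probe_fraction = 0.05,
                                        dim_log2 = 5) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  probes <- tile_promoter_probes(annotation)
  if (is.null(planted)) {
    planted <- data.frame(
      gene_id = character(0), chrom = character(0), start = numeric(0),
      end = numeric(0), direction = character(0), effect_size = numeric(0),
      n_probes = integer(0), contrast = character(0), stringsAsFactors = FALSE
    )
  }
  n <- nrow(probes)
  # effect matrix: probes x samples, on the log2 IP scale
  eff <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
  if (nrow(planted) > 0) {
    for (k in seq_len(nrow(planted))) {
      hit <- probes$chrom == planted$chrom[k] &
        probes$start <= planted$end[k] & probes$end >= planted$start[k]
      if (!any(hit)) {
        stop_validation("planted region %s:%d-%d overlaps no tiled probe",
                        planted$chrom[k], planted$start[k], planted$end[k])
      }
      later <- strsplit(planted$contrast[k], ":", fixed = TRUE)[[1]][2]
      if (!later %in% samples) {
        stop_validation("contrast sample '%s' not among samples", later)
      }
      sgn <- if (planted$direction[k] == "gain") 1 else -1
      eff[hit, later] <- eff[hit, later] + sgn * planted$effect_size[k]
    }
  }
  with_seed(seed, {
    affinity <- baseline_log2 + rnorm(n, 0, affinity_sd)
    if (dim_probe_fraction > 0) {
      in_planted <- rowSums(abs(eff)) > 0
      candidates <- which(!in_planted)
      n_dim <- round(dim_probe_fraction * n)
      dim_idx <- candidates[sample.int(length(candidates), min(n_dim, length(candidates)))]
      affinity[dim_idx] <- dim_log2
    }
    ch_sd <- noise_sd / sqrt(2)
    long <- vector("list", length(samples))
    for (j in seq_along(samples)) {
      ip <- affinity + eff[, j] + rnorm(n, 0, ch_sd)
      input <- affinity + rnorm(n, 0, ch_sd)
      long[[j]] <- data.frame(
        probe_id = probes$probe_id, chrom = probes$chrom,
        start = probes$start, end = probes$end,
        sample = samples[j],
        ip_signal = 2^ip, input_signal = 2^input,
        stringsAsFactors = FALSE
      )
    }
    list(probes = do.call(rbind, long), truth = planted, layout = probes)
  })
}

#' Simulate expression-array probe intensities
#'
#' Each transcript gets `n_probes_per_transcript` probes with transcript
#' baselines, probe affinities, planted log2 fold changes (applied to the
#' later sample of each planted contrast), and Gaussian log2 noise.
#'
#' @param annotation A `gene_annotation`.
#' @param planted Data frame with columns transcript_id, log2_fold_change,
#'   contrast ("A:B"); may be NULL/empty.
#' @param noise_sd Per-probe log2 noise sd.
#' @param samples Ordered sample labels.
#' @param n_probes_per_transcript Probes per probe set (>= 1).
#' @param seed Integer seed.
#' @param low_quality_fraction Fraction of transcripts given se_metric 0.5
#'   (below the default 0.8 retention threshold); all others get 1.0.
#' @return List with `probes` (probe_id, transcript_id, sample, signal),
#'   `se_metric` (transcript_id, se_metric) and `truth` (the planted table).
#' @export
simulate_expression <- function(annotation, planted = NULL, noise_sd = 0.25,
                                samples = c("d1", "d7", "w2", "w8"),
                                n_probes_per_transcript = 3L, seed = 1L,
                                low_quality_fraction = 0) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (n_probes_per_transcript < 1) stop_validation("need >= 1 probe per transcript")
  tx <- annotation$transcripts
  if (is.null(planted)) {
    planted <- data.frame(transcript_id = character(0),
                          log2_fold_change = numeric(0),
                          contrast = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(planted) > 0 && !all(planted$transcript_id %in% tx$transcript_id)) {
    bad <- setdiff(planted$transcript_id, tx$transcript_id)
    stop_validation("planted transcript(s) not in annotation: %s",
                    paste(bad, collapse = ", "))
  }
  nt <- nrow(tx)
  eff <- matrix(0, nt, length(samples), dimnames = list(tx$transcript_id, samples))
  if (nrow(planted) > 0) {
    for (k in seq_len(nrow(planted))) {
      later <- strsplit(planted$contrast[k], ":", fixed = TRUE)[[1]][2]
      if (!later %in% samples) stop_validation("contrast sample '%s' unknown", later)
      eff[planted$transcript_id[k], later] <-
        eff[planted$transcript_id[k], later] + planted$log2_fold_change[k]
    }
  }
  with_seed(seed, {
    base <- rnorm(nt, 8, 1)
    k <- n_probes_per_transcript
    affinity <- rnorm(nt * k, 0, 0.5)
    probe_id <- sprintf("EP%06d", seq_len(nt * k))
    tx_of_probe <- rep(tx$transcript_id, each = k)
    long <- vector("list", length(samples))
    for (j in seq_along(samples)) {
      mu <- rep(base + eff[, j], each = k) + affinity
      long[[j]] <- data.frame(
        probe_id = probe_id, transcript_id = tx_of_probe,
        sample = samples[j],
        signal = 2^(mu + rnorm(nt * k, 0, noise_sd)),
        stringsAsFactors = FALSE
      )
    }
    se <- rep(1.0, nt)
    if (low_quality_fraction > 0) {
      n_low <- round(low_quality_fraction * nt)
      se[sample.int(nt, n_low)] <- 0.5
    }
    list(
      probes = do.call(rbind, long),
      se_metric = data.frame(transcript_id = tx$transcript_id, se_metric = se,
                             stringsAsFactors = FALSE),
      truth = planted
    )
  })
}

#' Simulate qPCR Cq tables for methylation and expression assays
#'
#' Cq values are generated so that the planted methylation level and
#' expression ratio are recovered exactly by [methylation_level()] and
#' [relative_expression()] in expectation.
#'
#' @param levels Data frame with columns gene, timepoint, and either
#'   `methylation` (in `[0, 1)`) or `expression_ratio` (> 0).
#' @param mode "methylation" (assays mcrbc/input) or "expression"
#'   (assays target/reference).
#' @param n_individuals Biological replicates per timepoint.
#' @param n_replicates Technical qPCR replicates per well group.
#' @param noise_cq Sd of Gaussian Cq noise, cycles.
#' @param efficiency Amplification efficiency, fold per cycle.
#' @param seed Integer seed.
#' @return Long Cq table: sample_id, timepoint, gene, assay, replicate, cq.
#' @export
simulate_qpcr_cq <- function(levels, mode = c("methylation", "expression"),
                             n_individuals = 3L, n_replicates = 3L,
                             noise_cq = 0.15, efficiency = 2,
                             seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(levels))) {
      for (ind in seq_len(n_individuals)) {
        base <- rnorm(1, if (mode == "methylation") 22 else 20, 0.5)
        if (mode == "methylation") {
          dcq <- -log(1 - levels$methylation[i]) / log(efficiency)
          assays <- c(input = base, mcrbc = base + dcq)
        } else {
          dcq <- -log(levels$expression_ratio[i]) / log(efficiency)
          assays <- c(reference = base, target = base + dcq)
        }
        for (a in names(assays)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%s_ind%d", levels$gene[i],
                                levels$timepoint[i], ind),
            timepoint = levels$timepoint[i], gene = levels$gene[i],
            assay = a, replicate = seq_len(n_replicates),
            cq = assays[[a]] + rnorm(n_replicates, 0, noise_cq),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Build the default synthetic study profile
#'
#' The stated simulation world used throughout the tests: 200 genes on four
#' 2 Mb chromosomes, 50 planted DMRs for the d1:d7 contrast (half gains,
#' half losses; effect 1.5 log2 units across 4 consecutive probes), of which
#' the first 10 are re-planted identically in w2 and w8 (retained changes),
#' ratio noise sd 0.3, and one planted expression change of |log2FC| = 1 on
#' every DMR gene with random sign.
#'
#' @param seed Master seed (default 42).
#' @param noise_sd Methylation log2-ratio noise sd (default 0.3).
#' @param n_dmrs Number of planted DMRs (default 50).
#' @param effect_size Planted methylation effect (default 1.5).
#' @param dmr_probes Probes per planted DMR (default 4).
#' @param n_genes Number of genes (default 200).
#' @return List: spec, annotation, planted_dmrs, meth (probes/truth),
#'   planted_expr, expr (probes/se_metric/truth), samples.
#' @export
simulate_default_profile <- function(seed = 42L, noise_sd = 0.3,
                                     n_dmrs = 50L, effect_size = 1.5,
                                     dmr_probes = 4L, n_genes = 200L) {
  samples <- c("d1", "d7", "w2", "w8")
  spec <- synthetic_genome_spec(n_genes = n_genes, seed = derive_seed(seed, 1))
  annotation <- simulate_annotation(spec)
  layout <- tile_promoter_probes(annotation)
  planted <- plant_dmrs(annotation, layout, n = n_dmrs, n_probes = dmr_probes,
                        effect_size = effect_size, contrast = c("d1", "d7"),
                        seed = derive_seed(seed, 2))
  retained <- planted[seq_len(min(10L, nrow(planted))), , drop = FALSE]
  all_planted <- rbind(
    planted,
    transform(retained, contrast = "d1:w2"),
    transform(retained, contrast = "d1:w8")
  )
  meth <- simulate_methylation_arrays(annotation, all_planted,
                                      noise_sd = noise_sd, samples = samples,
                                      seed = derive_seed(seed, 3))
  with_seed(derive_seed(seed, 4), {
    sgn <- ifelse(runif(nrow(planted)) < 0.5, 1, -1)
  })
  planted_expr <- do.call(rbind, lapply(c("d1:d7", "d1:w2", "d1:w8"), function(ct) {
    data.frame(transcript_id = planted$gene_id,
               log2_fold_change = sgn * 1.0,
               contrast = rep(ct, nrow(planted)), stringsAsFactors = FALSE)
  }))
  expr <- simulate_expression(annotation, planted_expr, noise_sd = 0.25,
                              samples = samples,
                              seed = derive_seed(seed, 5))
  list(spec = spec, annotation = annotation, planted_dmrs = all_planted,
       meth = meth, planted_expr = planted_expr, expr = expr,
       samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
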