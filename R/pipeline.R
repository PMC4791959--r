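# End-to-end orchestration: simulate -> normalize -> score -> call DMRs ->
# annotate -> expression -> integrate, under one flat configuration.

#' Build a pipeline configuration
#'
#' All stage parameters in one flat list. Defaults are the published
#' analysis parameters: 750 bp KS window with a 500 bp maximum inter-probe
#' gap, DMRs from at least 3 consecutive probes at a minimum two-fold
#' change and delta-KS of at least 1.0, expression calls at two-fold,
#' methylation-expression pairing at 1.5-fold, quality-metric retention
#' threshold 0.8, and qPCR efficiency 2.
#'
#' @param ... Overrides of any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window_bp = 750, max_gap_bp = 500,
    min_probes = 3L, min_fold_meth = 2.0, min_delta_ks = 1.0,
    min_fold_expr_de = 2.0, min_fold_expr_pair = 1.5,
    se_threshold = 0.8, qpcr_efficiency = 2.0,
    floor = 1, bg_quantile = 0.05, biweight_c = 5,
    seed = 42L,
    samples = c("d1", "d7", "w2", "w8"),
    contrasts = list(c("d1", "d7"), c("d1", "w2"), c("d1", "w8")),
    # synthetic profile
    n_genes = 200L, n_dmrs = 50L, effect_size = 1.5, dmr_probes = 4L,
    noise_sd = 0.3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop_validation("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  num <- c("window_bp", "max_gap_bp", "min_probes", "min_fold_meth",
           "min_delta_ks", "min_fold_expr_de", "min_fold_expr_pair",
           "se_threshold", "qpcr_efficiency")
  if (any(unlist(cfg[num]) <= 0)) stop_validation("all thresholds must be > 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration file
#'
#' Flat `key = value` text; `samples` is a comma list and `contrasts` a
#' comma list of `A:B` pairs.
#'
#' @param path File path.
#' @param config A `pipeline_config`.
#' @return A `pipeline_config` (read); the path, invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$", lines))
  args <- list()
  for (m in kv) {
    if (length(m) != 3) next
    key <- m[2]; val <- m[3]
    args[[key]] <- switch(
      key,
      samples = strsplit(val, ",", fixed = TRUE)[[1]],
      contrasts = lapply(strsplit(val, ",", fixed = TRUE)[[1]],
                         function(x) strsplit(x, ":", fixed = TRUE)[[1]]),
      {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) val else num
      }
    )
  }
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  fmt <- function(key) {
    v <- config[[key]]
    if (key == "samples") return(paste(v, collapse = ","))
    if (key == "contrasts") {
      return(paste(vapply(v, paste, "", collapse = ":"), collapse = ","))
    }
    as.character(v)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(names(config), fmt, "")), path)
  invisible(path)
}

#' Run the full pipeline on the synthetic profile
#'
#' Simulates the configured synthetic study, normalizes both channels,
#' scores every sample track, calls and classifies DMRs for every contrast,
#' summarizes expression with the quality filter, pairs methylation with
#' expression changes, and collects the retained (early-established,
#' adult-persistent) DMRs. Deterministic under `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, all stage outputs and a
#'   JSON report are written there.
#' @return A report list: per-contrast DMR counts, size histogram, location
#'   distribution, quadrant tables, pair/DE counts, retained DMR ids, and
#'   recovery metrics against the planted truth.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  prof <- simulate_default_profile(
    seed = config$seed, noise_sd = config$noise_sd, n_dmrs = config$n_dmrs,
    effect_size = config$effect_size, dmr_probes = config$dmr_probes,
    n_genes = config$n_genes
  )
  norm <- normalize_probe_track(prof$meth$probes, floor = config$floor,
                                bg_quantile = config$bg_quantile,
                                tuning_c = config$biweight_c)
  tracks <- lapply(stats::setNames(nm = config$samples), function(s) {
    tr <- norm[norm$sample == s, , drop = FALSE]
    ks <- score_track(tr, window_bp = config$window_bp,
                      max_gap_bp = config$max_gap_bp)
    combine_track_scores(tr, ks)
  })
  expr <- summarize_expression(prof$expr$probes, prof$expr$se_metric,
                               prof$annotation, floor = config$floor,
                               bg_quantile = config$bg_quantile)
  expr <- suppressMessages(se_filter(expr, config$se_threshold))

  contrast_reports <- list()
  dmrs_by_contrast <- list()
  for (ct in config$contrasts) {
    label <- paste(ct, collapse = ":")
    deltas <- probe_deltas(tracks[[ct[1]]], tracks[[ct[2]]], contrast = label)
    dmrs <- call_dmrs(deltas, min_probes = config$min_probes,
                      min_fold = config$min_fold_meth,
                      min_delta_ks = config$min_delta_ks,
                      max_gap_bp = config$max_gap_bp)
    classified <- classify_dmrs(dmrs, prof$annotation)
    de <- call_differential(expr, ct, min_fold = config$min_fold_expr_de)
    de_pair <- call_differential(expr, ct, min_fold = config$min_fold_expr_pair)
    pairs <- pair_dmrs_with_expression(classified$mappings, de_pair)
    truth_ct <- prof$planted_dmrs[prof$planted_dmrs$contrast == label, ,
                                  drop = FALSE]
    dmrs_by_contrast[[label]] <- dmrs
    contrast_reports[[label]] <- list(
      dmrs = dmrs, classified = classified, pairs = pairs, de = de,
      summary = summarize_dmrs(dmrs),
      location = location_distribution(classified),
      quadrants = quadrant_counts(pairs),
      recovery = evaluate_dmr_recovery(dmrs, truth_ct)
    )
  }
  first <- paste(config$contrasts[[1]], collapse = ":")
  laters <- dmrs_by_contrast[-1]
  retained <- do.call(retained_changes,
                      c(list(dmrs_by_contrast[[first]]), unname(laters)))

  report <- list(
    n_probes = nrow(prof$meth$layout),
    n_transcripts = nrow(prof$annotation$transcripts),
    contrasts = lapply(contrast_reports, function(cr) {
      list(
        n_dmrs = nrow(cr$dmrs),
        gains = sum(cr$dmrs$direction == "gain"),
        losses = sum(cr$dmrs$direction == "loss"),
        size_histogram = as.list(cr$summary$size_histogram),
        location_distribution = as.list(cr$location),
        n_de = nrow(cr$de), n_pairs = nrow(cr$pairs),
        quadrants = cr$quadrants,
        recovery = cr$recovery
      )
    }),
    retained = list(n = nrow(retained), dmr_id = retained$dmr_id)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(outdir, ...)
    write_probe_table(norm, fp("probes_normalized.tsv"))
    write_annotation_bed(prof$annotation, fp("transcripts.bed"),
                         fp("cpg_islands.bed"))
    write_tsv(prof$planted_dmrs, fp("planted_dmrs.tsv"))
    write_tsv(prof$expr$truth, fp("planted_expression.tsv"))
    write_tsv(expr, fp("expression_table.tsv"))
    for (label in names(contrast_reports)) {
      tag <- gsub(":", "_", label, fixed = TRUE)
      cr <- contrast_reports[[label]]
      write_dmr_bed(cr$dmrs, fp(sprintf("dmrs_%s.bed", tag)))
      write_tsv(cr$classified$mappings, fp(sprintf("dmr_annotation_%s.tsv", tag)))
      write_tsv(cr$pairs, fp(sprintf("pairs_%s.tsv", tag)))
      write_tsv(cr$quadrants, fp(sprintf("quadrants_%s.tsv", tag)))
    }
    write_tsv(retained, fp("retained_dmrs.tsv"))
    jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  c(report, list(details = contrast_reports, retained_dmrs = retained,
                 profile = prof, expression = expr))
}
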