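pipeline_defaults <- function() {
  list(min_anchor = 6L, edge_trim = 10L, pseudocount = 0.5,
       min_fpkm = 1, min_ref_junction_reads = 10L,
       z_threshold = 2, min_metrics = 2L, cv_max = 0.5, sd_floor = 1e-6,
       case_aggregation = "mean", two_sided = FALSE,
       min_support = 3L, window = 100L)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full splicing-deficiency pipeline
#'
#' Orchestrates simulate (optional) -> annotation -> quantify -> score ->
#' cohort ranking -> event detection, writing every stage's TSV, a JSON
#' run manifest (package version, parameters, seed, input checksums,
#' per-stage row counts) and a human-readable report to the output
#' directory. Stages fail fast with stage-named errors.
#'
#' @param config a list or YAML file path. Fields: \code{outdir}
#'   (required); either \code{simulate} (a list of
#'   \code{\link{simulation_config}} arguments) or \code{inputs} (a list
#'   with \code{gtf}, \code{intron_types}, \code{genome}, \code{samples}
#'   and \code{sam} -- a named list/vector sample_id -> SAM path);
#'   \code{params} overriding any of the documented defaults (min_anchor
#'   6, edge_trim 10, pseudocount 0.5, min_fpkm 1,
#'   min_ref_junction_reads 10, z_threshold 2, min_metrics 2, cv_max 0.5,
#'   sd_floor 1e-6, case_aggregation "mean", two_sided FALSE,
#'   min_support 3, window 100).
#' @return list with the per-stage objects (\code{models},
#'   \code{ref_pairs}, \code{quants}, \code{scores}, \code{detection},
#'   \code{cv_filter}, \code{zscores}, \code{ranked}, \code{events}) and
#'   \code{paths} of the written files.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("[stage config] config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$outdir)) stop("[stage config] outdir is required")
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    sim_cfg <- run_stage("config", do.call(simulation_config, config$simulate))
    sim_out <- run_stage("simulate", simulate_cohort(sim_cfg, file.path(outdir, "sim")))
    inputs <- list(gtf = sim_out$paths$gtf, intron_types = sim_out$paths$intron_types,
                   genome = sim_out$paths$genome, samples = sim_out$paths$samples,
                   sam = sim_out$paths[sim_out$samples$sample_id])
    seed <- sim_cfg$seed
  } else {
    inputs <- config$inputs
    sim_out <- NULL
    seed <- config$seed %||% NA_integer_
    run_stage("config", {
      for (f in c(inputs$gtf, inputs$intron_types, inputs$genome, inputs$samples,
                  unlist(inputs$sam)))
        if (!file.exists(f)) stop("input file not found: ", f)
    })
  }

  samples <- run_stage("config", {
    s <- utils::read.delim(inputs$samples, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "condition") %in% names(s)))
      stop("samples table needs columns sample_id, condition")
    if (!all(s$condition %in% c("case", "control")))
      stop("condition must be 'case' or 'control'")
    s
  })
  sam_files <- unlist(inputs$sam)
  if (is.null(names(sam_files)) || any(!nzchar(names(sam_files))))
    names(sam_files) <- samples$sample_id
  missing_sam <- setdiff(samples$sample_id, names(sam_files))
  if (length(missing_sam))
    stop("[stage config] no SAM file for sample(s): ", paste(missing_sam, collapse = ", "))

  models <- run_stage("annotation", {
    m <- read_gene_models(inputs$gtf, genome = inputs$genome)
    read_intron_types(inputs$intron_types, m)
  })
  rp <- run_stage("annotation", reference_pairs(models))

  gaps_by_sample <- list()
  quants <- run_stage("quantify", {
    qs <- lapply(samples$sample_id, function(sid) {
      gal <- read_alignments(sam_files[[sid]])
      gaps <- splice_gaps(gal)
      gaps_by_sample[[sid]] <<- gaps
      quantify_sample(gal, models, rp, sample_id = sid,
                      min_anchor = params$min_anchor, edge_trim = params$edge_trim,
                      gaps = gaps)
    })
    do.call(rbind, qs)
  })

  scores <- run_stage("score", compute_scores(quants, pseudocount = params$pseudocount))
  detection <- run_stage("score", detection_filter(quants,
    min_fpkm = params$min_fpkm, min_ref_junction_reads = params$min_ref_junction_reads))

  cohort_cfg <- cohort_config(z_threshold = params$z_threshold,
    min_metrics = params$min_metrics, cv_max = params$cv_max,
    sd_floor = params$sd_floor, case_aggregation = params$case_aggregation,
    two_sided = params$two_sided)
  cv_filter <- NULL
  zscores <- NULL
  ranked <- run_stage("cohort", {
    sc <- scores[scores$gene_id %in% detection$detected, , drop = FALSE]
    cv_filter <- filter_variable_genes(sc, samples, cv_max = params$cv_max,
                                       sd_floor = params$sd_floor)
    sc <- sc[sc$gene_id %in% cv_filter$retained, , drop = FALSE]
    if (!nrow(sc)) stop("no genes remain after detection and variability filters")
    zscores <- compute_zscores(sc, samples, cohort_cfg)
    rank_genes(zscores, cohort_cfg)
  })

  events <- run_stage("events", detect_events(gaps_by_sample, models, samples,
    quants, min_anchor = params$min_anchor, min_support = params$min_support,
    window = params$window))

  wt <- function(d, f) {
    p <- file.path(outdir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(
    quant = wt(quants, "quant.tsv"),
    scores = wt(scores, "scores.tsv"),
    ranked = wt(ranked, "ranked.tsv"),
    events = wt(events$per_sample, "events.tsv"),
    events_pooled = wt(events$pooled, "events_pooled.tsv"))

  in_files <- unlist(inputs, use.names = FALSE)
  manifest <- list(
    package = "u12splice",
    version = as.character(utils::packageVersion("u12splice")),
    seed = seed,
    parameters = params,
    simulation = if (!is.null(config$simulate)) config$simulate else NULL,
    input_checksums = as.list(tools::md5sum(in_files[file.exists(in_files)])),
    row_counts = list(quant = nrow(quants), scores = nrow(scores),
                      ranked = nrow(ranked), events = nrow(events$per_sample),
                      detected_genes = length(detection$detected),
                      cv_discarded = sum(!unique(scores$gene_id) %in% cv_filter$retained &
                                         unique(scores$gene_id) %in% detection$detected)))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  results <- list(models = models, ref_pairs = rp, samples = samples,
                  quants = quants, scores = scores, detection = detection,
                  cv_filter = cv_filter, zscores = zscores, ranked = ranked,
                  events = events, sim = sim_out, params = params, paths = paths)
  paths$report <- file.path(outdir, "report.md")
  writeLines(make_report(results), paths$report)
  results$paths <- paths
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Human-readable run summary
#'
#' Summarises a \code{\link{run_all}} result as markdown: detected-gene
#' fraction, variability-filter discards, flagged genes with their
#' per-metric z-scores, and the top aberrant events with fractions.
#'
#' @param results the list returned by \code{\link{run_all}}.
#' @param top_events number of events to list (default 10).
#' @return character vector of markdown lines.
#' @export
make_report <- function(results, top_events = 10L) {
  need <- c("quants", "detection", "cv_filter", "ranked", "events")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing component(s): ", paste(miss, collapse = ", "))
  for (comp in c("quants", "ranked")) {
    d <- results[[comp]]
    if (!"gene_id" %in% names(d))
      stop("malformed ", comp, " table: missing column gene_id")
  }
  n_quant <- length(unique(results$quants$gene_id))
  n_det <- length(results$detection$detected)
  n_disc <- sum(!unique(results$detection$detected) %in% results$cv_filter$retained)
  ranked <- results$ranked
  flagged <- ranked[ranked$flagged, , drop = FALSE]
  lines <- c(
    "# U12 splicing-deficiency run report", "",
    sprintf("- Quantifiable genes (U12 intron with two U2 references): %d", n_quant),
    sprintf("- Detected at sufficient levels in all samples: %d (%.1f%%)",
            n_det, if (n_quant) 100 * n_det / n_quant else 0),
    sprintf("- Discarded for high control variability: %d", n_disc),
    sprintf("- Genes ranked: %d; flagged (>= %s metrics beyond threshold): %d",
            nrow(ranked), "min_metrics", nrow(flagged)), "")
  if (nrow(flagged)) {
    lines <- c(lines, "## Flagged genes", "",
      "| gene | z(U12/U2) | z(U12/FPKM) | z(IR/U2) | z(IR/FPKM) | metrics | rank score |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %.2f | %.2f | %.2f | %.2f | %d | %.2f |",
              flagged$gene_id, flagged$z_r_u12_u2, flagged$z_r_u12_fpkm,
              flagged$z_ir_u2, flagged$z_ir_fpkm, flagged$n_flagged_metrics,
              flagged$rank_score), "")
  } else {
    lines <- c(lines, "No genes were flagged.", "")
  }
  pooled <- results$events$pooled
  pooled_case <- pooled[pooled$condition == "case" & pooled$support_reads > 0, , drop = FALSE]
  if (nrow(pooled_case)) {
    pooled_case <- pooled_case[order(-pooled_case$fraction), , drop = FALSE]
    top <- utils::head(pooled_case, top_events)
    lines <- c(lines, "## Top aberrant events (pooled over case samples)", "",
      "| gene | junction | class | support | canonical | fraction |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %s:%d-%d | %s | %d | %d | %.3f |",
              top$gene_id, top$chrom, top$start, top$end, top$event_class,
              top$support_reads, top$canonical_reads, top$fraction), "")
  } else {
    lines <- c(lines, "No aberrant events detected in case samples.", "")
  }
  lines
}
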