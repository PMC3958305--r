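#' Cohort comparison configuration
#'
#' @param z_threshold z-score threshold flagging a metric (default 2).
#' @param min_metrics metrics beyond threshold needed to flag a gene
#'   (default 2).
#' @param cv_max maximal control coefficient of variation; genes above it
#'   on any metric are discarded (default 0.5).
#' @param sd_floor floor applied to control SD (and mean, for CV) to keep
#'   z-scores finite (default 1e-6).
#' @param case_aggregation "mean" compares the mean over case samples;
#'   "all" requires every case sample to exceed the threshold (the
#'   minimum-|z| case sample is reported).
#' @param two_sided flag metrics on either tail instead of the
#'   deficiency direction only (default FALSE).
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(z_threshold = 2, min_metrics = 2L, cv_max = 0.5,
                          sd_floor = 1e-6, case_aggregation = c("mean", "all"),
                          two_sided = FALSE) {
  case_aggregation <- match.arg(case_aggregation)
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  if (min_metrics < 1L || min_metrics > 4L) stop("min_metrics must be in 1..4")
  if (cv_max <= 0) stop("cv_max must be > 0")
  structure(list(z_threshold = z_threshold, min_metrics = as.integer(min_metrics),
                 cv_max = cv_max, sd_floor = sd_floor,
                 case_aggregation = case_aggregation, two_sided = two_sided),
            class = "cohort_config")
}

# scores rows restricted to the given condition's samples
condition_scores <- function(scores, samples, cond) {
  ids <- samples$sample_id[samples$condition == cond]
  scores[scores$sample_id %in% ids, , drop = FALSE]
}

#' Discard genes with high control variability
#'
#' For each metric, the coefficient of variation (sample SD over mean,
#' mean floored) is computed across control samples; a gene is discarded
#' when its CV exceeds \code{cv_max} on any metric.
#'
#' @param scores metric table from \code{\link{compute_scores}}.
#' @param samples sample table (sample_id, condition).
#' @param cv_max CV threshold (default 0.5).
#' @param sd_floor floor for the mean in the CV denominator.
#' @return list with \code{retained} (gene ids) and \code{report}
#'   (per-gene per-metric CV with the discard decision).
#' @export
filter_variable_genes <- function(scores, samples, cv_max = 0.5, sd_floor = 1e-6) {
  ctrl <- condition_scores(scores, samples, "control")
  if (length(unique(ctrl$sample_id)) < 2L)
    stop("control variability undefined: need at least 2 control samples")
  dt <- data.table::as.data.table(ctrl)
  long <- data.table::melt(dt, id.vars = c("gene_id", "sample_id"),
    measure.vars = METRIC_COLS, variable.name = "metric", value.name = "value")
  cv <- long[, .(cv = stats::sd(value) / max(mean(value), sd_floor)), by = .(gene_id, metric)]
  cv[, discard := cv > cv_max]
  decision <- cv[, .(discard = any(discard), max_cv = max(cv)), by = gene_id]
  list(retained = sort(decision$gene_id[!decision$discard]),
       report = as.data.frame(cv))
}

#' Case-vs-control z-scores per gene and metric
#'
#' z = (case statistic - control mean) / max(control SD, sd_floor). The
#' case statistic is the mean over case samples
#' (\code{case_aggregation = "mean"}) or, in \code{"all"} mode, the case
#' sample with the smallest |z| (so that a flag requires every case to
#' exceed the threshold).
#'
#' @param scores metric table from \code{\link{compute_scores}}.
#' @param samples sample table (sample_id, condition).
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame: gene_id and z_<metric> for the four metrics.
#' @export
compute_zscores <- function(scores, samples, config = cohort_config()) {
  ctrl <- condition_scores(scores, samples, "control")
  case <- condition_scores(scores, samples, "case")
  if (length(unique(ctrl$sample_id)) < 2L) stop("need at least 2 control samples")
  if (length(unique(case$sample_id)) < 1L) stop("need at least 1 case sample")
  cdt <- data.table::as.data.table(ctrl)
  kdt <- data.table::as.data.table(case)
  longc <- data.table::melt(cdt, id.vars = c("gene_id", "sample_id"),
    measure.vars = METRIC_COLS, variable.name = "metric", value.name = "value")
  stat <- longc[, .(ctrl_mean = mean(value),
                    ctrl_sd = stats::sd(value)), by = .(gene_id, metric)]
  longk <- data.table::melt(kdt, id.vars = c("gene_id", "sample_id"),
    measure.vars = METRIC_COLS, variable.name = "metric", value.name = "value")
  m <- merge(longk, stat, by = c("gene_id", "metric"))
  m[, z := (value - ctrl_mean) / pmax(ctrl_sd, config$sd_floor)]
  zz <- if (config$case_aggregation == "mean") {
    m[, .(z = (mean(value) - ctrl_mean[1L]) /
            pmax(ctrl_sd[1L], config$sd_floor)), by = .(gene_id, metric)]
  } else {
    m[, .(z = z[which.min(abs(z))]), by = .(gene_id, metric)]
  }
  wide <- data.table::dcast(zz, gene_id ~ metric, value.var = "z")
  data.table::setnames(wide, METRIC_COLS, paste0("z_", METRIC_COLS))
  data.table::setorder(wide, gene_id)
  as.data.frame(wide)
}

#' Rank genes by case/control deviation
#'
#' A metric is flagged when its z-score exceeds the threshold in the
#' deficiency direction: decreased splicing efficiency (z below minus the
#' threshold for \code{r_u12_u2}, \code{r_u12_fpkm}) or increased
#' retention (z above the threshold for \code{ir_u2}, \code{ir_fpkm});
#' with \code{two_sided = TRUE} either tail counts. A gene is flagged when
#' at least \code{min_metrics} metrics are flagged. Output is sorted by
#' rank score (largest |z| among flagged metrics, 0 when none) descending,
#' ties broken by gene id.
#'
#' @param zscores output of \code{\link{compute_zscores}}.
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame: gene_id, the four z columns, n_flagged_metrics,
#'   flagged, rank_score, rank.
#' @export
rank_genes <- function(zscores, config = cohort_config()) {
  z <- as.data.frame(zscores)
  eff <- c("z_r_u12_u2", "z_r_u12_fpkm")
  ret <- c("z_ir_u2", "z_ir_fpkm")
  thr <- config$z_threshold
  hit <- sapply(c(eff, ret), function(col) {
    if (config$two_sided) abs(z[[col]]) >= thr
    else if (col %in% eff) z[[col]] <= -thr
    else z[[col]] >= thr
  })
  if (nrow(z) == 1L) hit <- matrix(hit, nrow = 1L, dimnames = list(NULL, c(eff, ret)))
  n_flagged <- rowSums(hit)
  flagged <- n_flagged >= config$min_metrics
  absz <- abs(as.matrix(z[, c(eff, ret)]))
  rank_score <- vapply(seq_len(nrow(z)), function(i) {
    if (n_flagged[i] == 0L) 0 else max(absz[i, hit[i, ]])
  }, numeric(1))
  out <- data.frame(z[, c("gene_id", eff, ret)],
                    n_flagged_metrics = as.integer(n_flagged),
                    flagged = flagged, rank_score = rank_score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank_score, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
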