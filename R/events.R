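#' Enumerate novel (unannotated) splice junctions per gene
#'
#' Collects every N-operation span lying within a gene's genomic extent
#' that matches no annotated intron of any transcript, applying the same
#' anchor rule as canonical junction counting, and keeps junctions with at
#' least \code{min_support} supporting reads.
#'
#' @param x a \code{GAlignments} object or \code{\link{splice_gaps}} table.
#' @param models a \code{GeneModelSet}.
#' @param min_anchor minimal flanking aligned length in bp (default 6).
#' @param min_support minimal supporting reads (default 3).
#' @return data.frame: gene_id, chrom, start, end, support_reads.
#' @export
enumerate_novel_junctions <- function(x, models, min_anchor = 6L, min_support = 3L) {
  if (min_support < 1L) stop("min_support must be >= 1")
  gaps <- if (inherits(x, "GAlignments")) splice_gaps(x) else data.table::as.data.table(x)
  empty <- data.frame(gene_id = character(), chrom = character(),
    start = integer(), end = integer(), support_reads = integer(),
    stringsAsFactors = FALSE)
  g <- gaps[gaps$left_anchor >= min_anchor & gaps$right_anchor >= min_anchor]
  if (!nrow(g)) return(empty)
  agg <- g[, .(support_reads = .N), by = .(chrom, start, end)]
  ann <- unique(models$introns[, c("chrom", "start", "end")])
  agg <- agg[!paste(chrom, start, end) %in% paste(ann$chrom, ann$start, ann$end)]
  agg <- agg[support_reads >= min_support]
  if (!nrow(agg)) return(empty)
  ex <- data.table::as.data.table(models$exons)
  ext <- ex[, .(gstart = min(start), gend = max(end)), by = .(gene_id, chrom)]
  jgr <- GenomicRanges::GRanges(agg$chrom, IRanges::IRanges(agg$start, agg$end))
  egr <- GenomicRanges::GRanges(ext$chrom, IRanges::IRanges(ext$gstart, ext$gend))
  hits <- GenomicRanges::findOverlaps(jgr, egr, type = "within")
  out <- data.frame(gene_id = ext$gene_id[S4Vectors::subjectHits(hits)],
                    agg[S4Vectors::queryHits(hits),
                        c("chrom", "start", "end", "support_reads")],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a novel junction at a U12-type intron
#'
#' Classification relative to the gene's U12-type intron, strand-aware:
#' a junction sharing the U12 donor whose acceptor lies within
#' \code{window} bp of the U12 acceptor is a cryptic-acceptor event
#' (\code{cryptic_3p}); the mirror case is \code{cryptic_5p}; a junction
#' running from an annotated donor to a non-adjacent annotated acceptor
#' across the U12 intron is \code{exon_skip}; anything else is
#' \code{other}.
#'
#' @param junction list/one-row data.frame with chrom, start, end (1-based
#'   inclusive genomic span of the skip).
#' @param introns the gene's canonical-transcript introns (data.frame with
#'   start, end, sorted by start).
#' @param u12 the U12-type intron (list with start, end).
#' @param strand gene strand ("+" or "-").
#' @param window cryptic-site search window in bp (default 100).
#' @return one of "cryptic_5p", "cryptic_3p", "exon_skip", "other".
#' @export
classify_event <- function(junction, introns, u12, strand, window = 100L) {
  js <- junction$start; je <- junction$end
  us <- u12$start; ue <- u12$end
  if (strand == "+") {
    shares_donor <- js == us; shares_acceptor <- je == ue
    other_site_near <- if (js == us) abs(je - ue) <= window else abs(js - us) <= window
  } else {
    shares_donor <- je == ue; shares_acceptor <- js == us
    other_site_near <- if (je == ue) abs(js - us) <= window else abs(je - ue) <= window
  }
  if (shares_donor && !shares_acceptor && other_site_near) return("cryptic_3p")
  if (shares_acceptor && !shares_donor && other_site_near) return("cryptic_5p")
  ia <- match(js, introns$start)
  ib <- match(je, introns$end)
  if (!is.na(ia) && !is.na(ib) && ib > ia && js <= us && je >= ue)
    return("exon_skip")
  "other"
}

# Vectorised classification of the novel-junction table.
annotate_events <- function(novel, models, ref_pairs = NULL, window = 100L) {
  if (!nrow(novel)) {
    novel$event_class <- character(0)
    return(novel)
  }
  if (is.null(ref_pairs)) ref_pairs <- reference_pairs(models)
  introns <- data.table::as.data.table(models$introns)
  canon <- introns[transcript_id %in% models$genes$canonical_transcript_id]
  data.table::setorder(canon, gene_id, start)
  strands <- setNames(models$genes$strand, models$genes$gene_id)
  cls <- character(nrow(novel))
  for (i in seq_len(nrow(novel))) {
    gid <- novel$gene_id[i]
    gint <- canon[gene_id == gid]
    u12s <- gint[splice_type == "U12"]
    cls[i] <- "other"
    for (k in seq_len(nrow(u12s))) {
      c_k <- classify_event(novel[i, ], gint, u12s[k, ], strands[[gid]], window)
      if (c_k != "other") { cls[i] <- c_k; break }
    }
  }
  novel$event_class <- cls
  novel
}

#' Event abundance relative to canonical splicing
#'
#' For each aberrant junction, the fraction of junction-spanning reads it
#' captures relative to the canonical U12 junction of the same gene:
#' support / (support + canonical), reported per sample and pooled by
#' condition. Events whose pooled control fraction is below 1% while the
#' pooled case fraction exceeds 5% are flagged \code{case_exclusive}.
#'
#' @param events per-sample classified events (gene_id, sample_id, chrom,
#'   start, end, event_class, support_reads).
#' @param quants per-intron quantification over all samples (provides the
#'   canonical U12 junction counts).
#' @param samples sample table (sample_id, condition).
#' @return list with \code{per_sample} (events with canonical_reads,
#'   fraction, case_exclusive) and \code{pooled} (per condition).
#' @export
event_fractions <- function(events, quants, samples) {
  q <- data.table::as.data.table(quants)
  canon <- q[, .(canonical_reads = sum(J_u12)), by = .(gene_id, sample_id)]
  ev <- data.table::as.data.table(events)
  if (!nrow(ev)) {
    ev[, `:=`(canonical_reads = integer(0), fraction = numeric(0),
              case_exclusive = logical(0))]
    return(list(per_sample = as.data.frame(ev),
                pooled = data.frame(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), event_class = character(),
                  condition = character(), support_reads = integer(),
                  canonical_reads = integer(), fraction = numeric())))
  }
  ev <- merge(ev, canon, by = c("gene_id", "sample_id"), all.x = TRUE)
  ev[is.na(canonical_reads), canonical_reads := 0L]
  ev[, fraction := ifelse(support_reads + canonical_reads > 0,
                          support_reads / (support_reads + canonical_reads), NA_real_)]
  ev <- merge(ev, data.table::as.data.table(samples), by = "sample_id")

  # pooled by condition: canonical denominators from all samples of the
  # condition, support summed over samples where the event was seen
  cond_canon <- merge(canon, data.table::as.data.table(samples), by = "sample_id")
  cond_canon <- cond_canon[, .(canonical_reads = sum(canonical_reads)),
                           by = .(gene_id, condition)]
  jkey <- c("gene_id", "chrom", "start", "end", "event_class")
  sup <- ev[, .(support_reads = sum(support_reads)), by = c(jkey, "condition")]
  grid <- data.table::CJ(jid = seq_len(nrow(unique(sup[, ..jkey]))),
                         condition = unique(samples$condition))
  uj <- unique(sup[, ..jkey])[grid$jid]
  uj[, condition := grid$condition]
  pooled <- merge(uj, sup, by = c(jkey, "condition"), all.x = TRUE)
  pooled[is.na(support_reads), support_reads := 0L]
  pooled <- merge(pooled, cond_canon, by = c("gene_id", "condition"), all.x = TRUE)
  pooled[is.na(canonical_reads), canonical_reads := 0L]
  pooled[, fraction := ifelse(support_reads + canonical_reads > 0,
                              support_reads / (support_reads + canonical_reads), NA_real_)]
  widef <- data.table::dcast(pooled, gene_id + chrom + start + end + event_class ~ condition,
                             value.var = "fraction")
  if (!"case" %in% names(widef)) widef[, case := NA_real_]
  if (!"control" %in% names(widef)) widef[, control := NA_real_]
  widef[, case_exclusive := !is.na(case) & case > 0.05 &
          (is.na(control) | control < 0.01)]
  ev <- merge(ev, widef[, c(jkey, "case_exclusive"), with = FALSE], by = jkey, all.x = TRUE)
  data.table::setorder(ev, gene_id, sample_id, start)
  data.table::setcolorder(ev, c("gene_id", "sample_id", "chrom", "start", "end",
                                "event_class", "support_reads", "canonical_reads",
                                "fraction", "condition", "case_exclusive"))
  data.table::setorder(pooled, gene_id, condition, start)
  list(per_sample = as.data.frame(ev), pooled = as.data.frame(pooled))
}

#' Detect and quantify aberrant processing events across a cohort
#'
#' Per sample: enumerate unannotated junctions, classify them against the
#' gene's U12-type intron, and relate their abundance to canonical U12
#' splicing (\code{\link{event_fractions}}).
#'
#' @param gaps_by_sample named list of \code{\link{splice_gaps}} tables
#'   (or \code{GAlignments}), one per sample.
#' @param models a labeled \code{GeneModelSet}.
#' @param samples sample table (sample_id, condition).
#' @param quants per-intron quantification over all samples.
#' @param min_anchor,min_support,window see
#'   \code{\link{enumerate_novel_junctions}} and
#'   \code{\link{classify_event}}.
#' @return list as from \code{\link{event_fractions}}.
#' @export
detect_events <- function(gaps_by_sample, models, samples, quants,
                          min_anchor = 6L, min_support = 3L, window = 100L) {
  rp <- reference_pairs(models)
  evs <- lapply(names(gaps_by_sample), function(sid) {
    nv <- enumerate_novel_junctions(gaps_by_sample[[sid]], models,
                                    min_anchor = min_anchor, min_support = min_support)
    nv <- annotate_events(nv, models, ref_pairs = rp, window = window)
    if (nrow(nv)) nv$sample_id <- sid
    nv
  })
  events <- data.table::rbindlist(evs, fill = TRUE)
  if (!nrow(events))
    events <- data.frame(gene_id = character(), sample_id = character(),
      chrom = character(), start = integer(), end = integer(),
      event_class = character(), support_reads = integer(),
      stringsAsFactors = FALSE)
  event_fractions(events, quants, samples)
}
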