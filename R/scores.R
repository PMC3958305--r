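#' Per-gene splicing-efficiency and retention metrics
#'
#' Converts raw per-intron quantifications into the four per-gene,
#' per-sample metrics: \code{r_u12_u2} (U12 junction reads over the mean
#' of the two U2 reference junction counts), \code{r_u12_fpkm} (U12
#' junction reads over FPKM), \code{ir_u2} (U12 intron-body depth over the
#' mean of the two reference intron depths), \code{ir_fpkm} (U12
#' intron-body depth over FPKM). A pseudocount is added to every
#' denominator so all metrics are finite; numerator zeros are kept as
#' meaningful zeros. Genes with several U12-type introns are averaged
#' arithmetically across introns.
#'
#' @param quants per-intron quantification table (rows from
#'   \code{\link{quantify_sample}}, possibly several samples bound
#'   together).
#' @param pseudocount added to denominators (default 0.5).
#' @return data.frame: sample_id, gene_id, the four metrics,
#'   n_u12_introns_averaged.
#' @export
compute_scores <- function(quants, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  q <- data.table::as.data.table(quants)
  q[, `:=`(
    r_u12_u2 = J_u12 / ((J_u2a + J_u2b) / 2 + pseudocount),
    r_u12_fpkm = J_u12 / (fpkm + pseudocount),
    ir_u2 = D_u12 / ((D_u2a + D_u2b) / 2 + pseudocount),
    ir_fpkm = D_u12 / (fpkm + pseudocount))]
  out <- q[, .(r_u12_u2 = mean(r_u12_u2), r_u12_fpkm = mean(r_u12_fpkm),
               ir_u2 = mean(ir_u2), ir_fpkm = mean(ir_fpkm),
               n_u12_introns_averaged = .N),
           by = .(sample_id, gene_id)]
  data.table::setorder(out, sample_id, gene_id)
  as.data.frame(out)
}

#' Filter genes detected at sufficient levels in every sample
#'
#' A gene is detected when, in every sample, its FPKM reaches
#' \code{min_fpkm} and each of its U12 introns' two reference junctions
#' together carry at least \code{min_ref_junction_reads} split reads.
#' Genes failing anywhere are excluded from the case/control comparison.
#'
#' @param quants per-intron quantification table over all samples.
#' @param min_fpkm minimal FPKM in every sample (default 1).
#' @param min_ref_junction_reads minimal J_u2a + J_u2b in every sample
#'   (default 10).
#' @return list with \code{detected} (character vector of gene ids) and
#'   \code{report} (per gene/sample failure reasons).
#' @export
detection_filter <- function(quants, min_fpkm = 1, min_ref_junction_reads = 10L) {
  q <- data.table::as.data.table(quants)
  q[, `:=`(fpkm_ok = fpkm >= min_fpkm,
           ref_ok = (J_u2a + J_u2b) >= min_ref_junction_reads)]
  per <- q[, .(fpkm_ok = all(fpkm_ok), ref_ok = all(ref_ok)),
           by = .(gene_id, sample_id)]
  gene <- per[, .(detected = all(fpkm_ok & ref_ok)), by = gene_id]
  fails <- per[!(fpkm_ok & ref_ok)]
  fails[, reason := ifelse(!fpkm_ok & !ref_ok, "low_fpkm;low_ref_junctions",
                    ifelse(!fpkm_ok, "low_fpkm", "low_ref_junctions"))]
  list(detected = sort(gene$gene_id[gene$detected]),
       report = as.data.frame(fails[, .(gene_id, sample_id, reason)]))
}
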