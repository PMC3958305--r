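#' Read aligned spliced reads from a SAM (or BAM) file
#'
#' SAM input is converted to BAM internally; mapped records are returned
#' with their CIGAR strings. Chromosome lengths come from the \code{@SQ}
#' header.
#'
#' @param path SAM or BAM file.
#' @return A \code{GAlignments} object (mapped records only).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- if (grepl("\\.bam$", path)) path else {
    dest <- tempfile(fileext = "")
    tryCatch(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("SAM parse failure for ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  GenomicAlignments::readGAlignments(bam)
}

#' Table of splice gaps (N operations) with anchor lengths
#'
#' Expands every read's CIGAR into its skipped-region (N) spans on the
#' reference, with the lengths of the aligned (M) segments immediately
#' flanking each span. One row per N operation; the span coordinates are
#' the 1-based inclusive intron coordinates the split read supports.
#'
#' @param gal a \code{GAlignments} object.
#' @return data.table: read (index into \code{gal}), chrom, start, end,
#'   left_anchor, right_anchor.
#' @export
splice_gaps <- function(gal) {
  empty <- data.table::data.table(read = integer(), chrom = character(),
    start = integer(), end = integer(), left_anchor = integer(),
    right_anchor = integer())
  if (!length(gal)) return(empty)
  cig <- GenomicAlignments::cigar(gal)
  has_n <- grepl("N", cig, fixed = TRUE)
  if (!any(has_n)) return(empty)
  idx <- which(has_n)
  ops <- GenomicAlignments::explodeCigarOps(cig[idx])
  lens <- GenomicAlignments::explodeCigarOpLengths(cig[idx])
  nop <- lengths(ops)
  rid <- rep(idx, nop)
  op <- unlist(ops, use.names = FALSE)
  len <- unlist(lens, use.names = FALSE)
  n <- length(op)
  rc <- len * (op %in% c("M", "D", "N", "=", "X"))
  # reference offset of each op within its read, without grouped scans:
  # global cumsum minus its value at the read's first op
  cs0 <- c(0L, cumsum(rc)[-n])
  first_row <- cumsum(c(1L, nop[-length(nop)]))
  off <- cs0 - rep(cs0[first_row], nop)
  prev_ok <- c(FALSE, op[-n] %in% c("M", "=", "X")) & c(FALSE, rid[-n] == rid[-1L])
  next_ok <- c(op[-1L] %in% c("M", "=", "X"), FALSE) & c(rid[-n] == rid[-1L], FALSE)
  left <- ifelse(prev_ok, c(0L, len[-n]), 0L)
  right <- ifelse(next_ok, c(len[-1L], 0L), 0L)
  g <- which(op == "N")
  grid <- rid[g]
  pos <- BiocGenerics::start(gal)
  chrom <- S4Vectors::decode(GenomicAlignments::seqnames(gal))
  data.table::data.table(
    read = grid,
    chrom = as.character(chrom[grid]),
    start = pos[grid] + off[g],
    end = pos[grid] + off[g] + len[g] - 1L,
    left_anchor = left[g],
    right_anchor = right[g])
}

#' Count split reads supporting one splice junction
#'
#' A read supports a junction when one of its N operations skips exactly
#' the junction's intron span and carries at least \code{min_anchor}
#' aligned bases immediately on each side of the skip.
#'
#' @param x a \code{GAlignments} object or a \code{\link{splice_gaps}} table.
#' @param junction list/data.frame with chrom, start, end (1-based
#'   inclusive intron coordinates).
#' @param min_anchor minimal flanking aligned length in bp (default 6).
#' @return integer count.
#' @export
count_junction_reads <- function(x, junction, min_anchor = 6L) {
  gaps <- if (inherits(x, "GAlignments")) splice_gaps(x) else data.table::as.data.table(x)
  sum(gaps$chrom == junction$chrom & gaps$start == junction$start &
      gaps$end == junction$end & gaps$left_anchor >= min_anchor &
      gaps$right_anchor >= min_anchor)
}

# Aggregate split-read counts for a set of junctions.
# junctions: data.frame with chrom, start, end. Returns integer vector.
junction_counts <- function(gaps, junctions, min_anchor = 6L) {
  if (!nrow(junctions)) return(integer(0))
  g <- gaps[gaps$left_anchor >= min_anchor & gaps$right_anchor >= min_anchor]
  if (!nrow(g)) return(rep(0L, nrow(junctions)))
  agg <- g[, .N, by = .(chrom, start, end)]
  key <- paste(junctions$chrom, junctions$start, junctions$end)
  m <- match(key, paste(agg$chrom, agg$start, agg$end))
  ifelse(is.na(m), 0L, agg$N[m])
}

#' Mean read depth over an intron body
#'
#' Mean per-base coverage by aligned (M) segments over the intron body
#' trimmed by \code{edge_trim} bp at each end; skipped (N) regions of
#' spliced reads contribute nothing.
#'
#' @param x a \code{GAlignments} object or an \code{RleList} coverage.
#' @param intron list/data.frame with chrom, start, end (1-based inclusive).
#' @param edge_trim bp trimmed from each intron end (default 10).
#' @return mean depth (numeric), or \code{NA} with attribute
#'   \code{"reason"} = \code{"intron_too_short"} when nothing remains
#'   after trimming.
#' @export
intron_depth <- function(x, intron, edge_trim = 10L) {
  cov <- if (inherits(x, "GAlignments")) GenomicAlignments::coverage(x) else x
  s <- intron$start + edge_trim
  e <- intron$end - edge_trim
  if (e < s) {
    out <- NA_real_
    attr(out, "reason") <- "intron_too_short"
    return(out)
  }
  if (!intron$chrom %in% names(cov)) return(0)
  rle <- cov[[intron$chrom]]
  e2 <- min(e, length(rle))
  if (e2 < s) return(0)
  as.numeric(sum(S4Vectors::runValue(IRanges::Views(rle, s, e2)) *
                 S4Vectors::runLength(IRanges::Views(rle, s, e2)))) / (e - s + 1)
}

# Vectorised trimmed-body mean depths for an intron table.
intron_depths <- function(cov, introns, edge_trim = 10L) {
  n <- nrow(introns)
  out <- numeric(n)
  s <- introns$start + edge_trim
  e <- introns$end - edge_trim
  bad <- e < s
  out[bad] <- NA_real_
  for (ch in unique(introns$chrom)) {
    sel <- which(introns$chrom == ch & !bad)
    if (!length(sel)) next
    if (!ch %in% names(cov)) { out[sel] <- 0; next }
    rle <- cov[[ch]]
    e2 <- pmin(e[sel], length(rle))
    ok <- e2 >= s[sel]
    if (any(ok)) {
      v <- IRanges::Views(rle, s[sel][ok], e2[ok])
      out[sel][ok] <- IRanges::viewSums(v) / (e[sel][ok] - s[sel][ok] + 1)
    }
    out[sel][!ok] <- 0
  }
  out
}

#' Per-gene FPKM from read start positions
#'
#' Fragments per kilobase of canonical exonic length per million mapped
#' fragments: reads whose leftmost aligned position falls within the
#' gene's canonical exon union, divided by exonic length (kb) and by
#' total mapped fragments (millions).
#'
#' @param gal a \code{GAlignments} object.
#' @param gene one row of \code{models$genes}, or a list with
#'   \code{gene_id} and \code{exonic_length}.
#' @param models the \code{GeneModelSet} (for the canonical exon union).
#' @param total_mapped library-wide mapped-read count (> 0).
#' @return numeric FPKM.
#' @export
gene_fpkm <- function(gal, gene, models, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  counts <- exonic_start_counts(gal, models, gene$gene_id)
  as.numeric(counts) / (gene$exonic_length / 1000) / (total_mapped / 1e6)
}

# Reads whose leftmost position falls in each gene's canonical exon union.
exonic_start_counts <- function(gal, models, gene_ids = NULL) {
  ex <- models$exons
  canon <- ex[ex$transcript_id %in% models$genes$canonical_transcript_id, , drop = FALSE]
  if (!is.null(gene_ids)) canon <- canon[canon$gene_id %in% gene_ids, , drop = FALSE]
  if (!nrow(canon)) return(setNames(integer(0), character(0)))
  gr <- GenomicRanges::GRanges(canon$chrom, IRanges::IRanges(canon$start, canon$end))
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, canon$gene_id))
  starts <- GenomicRanges::GRanges(GenomicAlignments::seqnames(gal),
    IRanges::IRanges(GenomicAlignments::start(gal), width = 1L))
  GenomicRanges::countOverlaps(grl, starts)
}

#' Quantify one sample: junction counts, intron depths, FPKM
#'
#' For every quantifiable U12-type intron (those with an "ok" reference
#' pair), counts split reads at the U12 junction and at both U2 reference
#' junctions, computes trimmed-body mean depths for the three introns, and
#' the gene's FPKM. \code{total_mapped} is the sample's mapped-record
#' count.
#'
#' @param x SAM/BAM path or a \code{GAlignments} object.
#' @param models a labeled \code{GeneModelSet}.
#' @param ref_pairs output of \code{\link{reference_pairs}} (computed from
#'   \code{models} when NULL).
#' @param sample_id sample name recorded in the output.
#' @param min_anchor minimal junction anchor in bp (default 6).
#' @param edge_trim intron-body edge trim in bp (default 10).
#' @param gaps optional precomputed \code{\link{splice_gaps}} table.
#' @return data.frame, one row per quantifiable (gene, U12 intron):
#'   J_u12, J_u2a, J_u2b, D_u12, D_u2a, D_u2b, fpkm, total_mapped. Genes
#'   excluded by reference selection are listed in the attached
#'   \code{"exclusions"} attribute.
#' @export
quantify_sample <- function(x, models, ref_pairs = NULL, sample_id = "sample",
                            min_anchor = 6L, edge_trim = 10L, gaps = NULL) {
  gal <- if (inherits(x, "GAlignments")) x else read_alignments(x)
  total_mapped <- length(gal)
  if (total_mapped == 0L)
    stop("sample '", sample_id, "' rejected: zero mapped reads")
  if (is.null(ref_pairs)) ref_pairs <- reference_pairs(models)
  excl <- ref_pairs[ref_pairs$status != "ok", , drop = FALSE]
  rp <- ref_pairs[ref_pairs$status == "ok", , drop = FALSE]
  if (is.null(gaps)) gaps <- splice_gaps(gal)

  j_u12 <- junction_counts(gaps, data.frame(chrom = rp$chrom, start = rp$u12_start,
                                            end = rp$u12_end), min_anchor)
  j_u2a <- junction_counts(gaps, data.frame(chrom = rp$chrom, start = rp$u2a_start,
                                            end = rp$u2a_end), min_anchor)
  j_u2b <- junction_counts(gaps, data.frame(chrom = rp$chrom, start = rp$u2b_start,
                                            end = rp$u2b_end), min_anchor)
  cov <- GenomicAlignments::coverage(gal)
  d_u12 <- intron_depths(cov, data.frame(chrom = rp$chrom, start = rp$u12_start,
                                         end = rp$u12_end), edge_trim)
  d_u2a <- intron_depths(cov, data.frame(chrom = rp$chrom, start = rp$u2a_start,
                                         end = rp$u2a_end), edge_trim)
  d_u2b <- intron_depths(cov, data.frame(chrom = rp$chrom, start = rp$u2b_start,
                                         end = rp$u2b_end), edge_trim)
  counts <- exonic_start_counts(gal, models, unique(rp$gene_id))
  gm <- models$genes[match(rp$gene_id, models$genes$gene_id), ]
  fpkm <- as.numeric(counts[rp$gene_id]) / (gm$exonic_length / 1000) /
    (total_mapped / 1e6)
  out <- data.frame(sample_id = sample_id, gene_id = rp$gene_id,
    chrom = rp$chrom, u12_index = rp$u12_index,
    u12_start = rp$u12_start, u12_end = rp$u12_end,
    J_u12 = j_u12, J_u2a = j_u2a, J_u2b = j_u2b,
    D_u12 = d_u12, D_u2a = d_u2a, D_u2b = d_u2b,
    fpkm = fpkm, total_mapped = total_mapped,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}
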