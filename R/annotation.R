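#' @import data.table
#' @importFrom stats median rbinom rnbinom rlnorm setNames
#' @importFrom utils head tail
NULL

METRIC_COLS <- c("r_u12_u2", "r_u12_fpkm", "ir_u2", "ir_fpkm")

#' Construct a gene model set from exon coordinates
#'
#' Builds the internal gene-model container used throughout the package:
#' exons grouped into transcripts and genes, introns derived as the gaps
#' between consecutive exons of each transcript, and a canonical transcript
#' chosen per gene (largest exonic length; ties broken by lexicographically
#' smallest transcript id). All coordinates are 1-based inclusive.
#'
#' @param exons data.frame with columns chrom, start, end, strand, gene_id,
#'   transcript_id (1-based inclusive coordinates).
#' @param genome optional data.frame with columns chrom, length. When NULL,
#'   chromosome lengths are inferred as the maximal exon end per chromosome.
#' @return An object of class \code{GeneModelSet}: a list with elements
#'   \code{genome}, \code{exons}, \code{introns}, \code{transcripts},
#'   \code{genes}. Derived introns carry \code{splice_type = "unknown"}
#'   until labeled via \code{\link{read_intron_types}}.
#' @export
gene_model_set <- function(exons, genome = NULL) {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("exon table missing columns: ", paste(miss, collapse = ", "))
  exons <- exons[need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons)) {
    if (any(exons$start < 1L | exons$end < exons$start))
      stop("invalid exon coordinates (require 1 <= start <= end)")
    if (!all(exons$strand %in% c("+", "-")))
      stop("exon strand must be '+' or '-'")
  }
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  ex <- data.table::as.data.table(exons)
  if (nrow(ex)) {
    # exons of one transcript must not overlap (abutting is also rejected:
    # a zero-length intron cannot exist)
    bad <- ex[, any(start[-1L] <= end[-.N] + 1L) && .N > 1L, by = transcript_id]
    if (any(bad$V1))
      stop("overlapping or abutting exons within transcript(s): ",
           paste(head(bad$transcript_id[bad$V1], 5L), collapse = ", "))
    one <- ex[, .(n_chrom = data.table::uniqueN(chrom),
                  n_strand = data.table::uniqueN(strand)), by = transcript_id]
    if (any(one$n_chrom > 1L | one$n_strand > 1L))
      stop("transcript spans multiple chromosomes or strands")
  }

  if (is.null(genome)) {
    genome <- if (nrow(ex)) {
      as.data.frame(ex[, .(length = max(end)), by = chrom][order(chrom)])
    } else data.frame(chrom = character(), length = integer())
  } else {
    genome <- as.data.frame(genome, stringsAsFactors = FALSE)[, c("chrom", "length")]
    genome$length <- as.integer(genome$length)
    if (anyDuplicated(genome$chrom)) stop("duplicate chromosome names in genome")
    if (nrow(genome) && any(genome$length <= 0L)) stop("chromosome lengths must be > 0")
    if (nrow(ex) && !all(ex$chrom %in% genome$chrom))
      stop("exon chromosome absent from genome")
  }

  if (nrow(ex)) {
    tx <- ex[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
                 exonic_length = sum(end - start + 1L), n_exons = .N),
             by = transcript_id]
    introns <- ex[, if (.N > 1L) .(
      chrom = chrom[1L],
      start = end[-.N] + 1L,
      end = start[-1L] - 1L,
      strand = strand[1L],
      gene_id = gene_id[1L]
    ) else NULL, by = transcript_id]
    if (nrow(introns)) {
      # intron_index is transcript order 5'->3'
      introns[, intron_index := if (strand[1L] == "+") seq_len(.N) else rev(seq_len(.N)),
              by = transcript_id]
      introns[, splice_type := "unknown"]
    } else {
      introns <- data.table::data.table(transcript_id = character(), chrom = character(),
        start = integer(), end = integer(), strand = character(), gene_id = character(),
        intron_index = integer(), splice_type = character())
    }
    data.table::setcolorder(introns, c("chrom", "start", "end", "strand",
                                       "gene_id", "transcript_id", "intron_index", "splice_type"))
    data.table::setorder(tx, gene_id, -exonic_length, transcript_id)
    genes <- tx[, .(chrom = chrom[1L], strand = strand[1L],
                    canonical_transcript_id = transcript_id[1L],
                    exonic_length = exonic_length[1L]), by = gene_id]
    data.table::setorder(genes, gene_id)
    data.table::setorder(tx, transcript_id)
    data.table::setorder(introns, gene_id, transcript_id, start)
  } else {
    tx <- data.table::data.table(transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), exonic_length = integer(), n_exons = integer())
    introns <- data.table::data.table(chrom = character(), start = integer(), end = integer(),
      strand = character(), gene_id = character(), transcript_id = character(),
      intron_index = integer(), splice_type = character())
    genes <- data.table::data.table(gene_id = character(), chrom = character(),
      strand = character(), canonical_transcript_id = character(), exonic_length = integer())
  }

  out <- list(genome = as.data.frame(genome),
              exons = as.data.frame(exons),
              introns = as.data.frame(introns),
              transcripts = as.data.frame(tx[, .(transcript_id, gene_id, chrom, strand,
                                                 exonic_length, n_exons)]),
              genes = as.data.frame(genes))
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  class(out) <- "GeneModelSet"
  out
}

#' @export
print.GeneModelSet <- function(x, ...) {
  n_u12 <- sum(x$introns$splice_type == "U12")
  cat(sprintf("GeneModelSet: %d genes, %d transcripts, %d exons, %d introns (%d U12-labeled), %d chromosomes\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$introns),
              n_u12, nrow(x$genome)))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses exon features (attributes \code{gene_id}, \code{transcript_id})
#' from a GTF2.2 file and derives transcripts, genes and introns. GTF
#' coordinates are 1-based inclusive and are kept as such internally.
#'
#' @param gtf_file path to a GTF file.
#' @param genome optional chromosome-length table (data.frame with chrom,
#'   length, or path to a two-column TSV with a header).
#' @return A \code{\link{gene_model_set}} object.
#' @export
read_gene_models <- function(gtf_file, genome = NULL) {
  if (!file.exists(gtf_file)) stop("GTF file not found: ", gtf_file)
  lines <- readLines(gtf_file)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d", i, length(f)))
    if (is.na(suppressWarnings(as.integer(f[4L]))) || is.na(suppressWarnings(as.integer(f[5L]))))
      stop(sprintf("malformed GTF line %d: non-numeric coordinates", i))
  }
  if (is.character(genome) && length(genome) == 1L)
    genome <- utils::read.delim(genome, stringsAsFactors = FALSE)
  if (!length(body))
    return(gene_model_set(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character(), transcript_id = character()),
      genome = genome))
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) && (any(is.na(gr$gene_id)) || any(is.na(gr$transcript_id))))
    stop("GTF exon feature lacks gene_id or transcript_id attribute")
  exons <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    stringsAsFactors = FALSE)
  gene_model_set(exons, genome = genome)
}

#' Write gene models to a GTF file
#'
#' Emits one \code{exon} feature per exon, 1-based inclusive, with quoted
#' \code{gene_id}/\code{transcript_id} attributes. The output is
#' deterministic (sorted by gene, transcript, start), so writing a model
#' set read back from its own output reproduces the file byte for byte.
#'
#' @param models a \code{GeneModelSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "GeneModelSet"))
  e <- models$exons
  e <- e[order(e$gene_id, e$transcript_id, e$start), , drop = FALSE]
  lines <- sprintf("%s\tu12splice\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
                   e$chrom, e$start, e$end, e$strand, e$gene_id, e$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Label derived introns with splicing type (U2/U12)
#'
#' Reads a U12DB-style annotation table (tab-delimited with header; columns
#' chrom, start, end, strand, gene_id, splice_type; 1-based inclusive
#' coordinates) and labels the matching derived introns. Rows that match no
#' derived intron are skipped with a warning and counted in the attached
#' report; conflicting duplicate labels for one intron are an error.
#' Unmatched introns keep the label \code{"unknown"} and are ineligible as
#' U2 reference introns.
#'
#' @param tsv_file path to the annotation table, or a data.frame.
#' @param models a \code{GeneModelSet}.
#' @return \code{models} with intron \code{splice_type} filled in; the
#'   matching report is attached as attribute \code{"report"} (a list with
#'   \code{n_rows}, \code{n_matched}, \code{n_unmatched},
#'   \code{unmatched}).
#' @export
read_intron_types <- function(tsv_file, models) {
  stopifnot(inherits(models, "GeneModelSet"))
  tab <- if (is.data.frame(tsv_file)) tsv_file else
    utils::read.delim(tsv_file, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "splice_type")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("intron-type table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) && !all(tab$splice_type %in% c("U2", "U12")))
    stop("splice_type must be 'U2' or 'U12'")
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand, d$gene_id, sep = "\r")
  if (nrow(tab)) {
    kt <- key(tab)
    conf <- tapply(tab$splice_type, kt, function(v) length(unique(v)) > 1L)
    if (any(conf)) stop("conflicting duplicate splice_type labels for intron(s): ",
                        paste(head(gsub("\r", ":", names(conf)[conf]), 3L), collapse = "; "))
    tab <- tab[!duplicated(kt), , drop = FALSE]
  }
  introns <- models$introns
  m <- match(key(introns), key(tab))
  matched_rows <- unique(m[!is.na(m)])
  unmatched <- setdiff(seq_len(nrow(tab)), matched_rows)
  if (length(unmatched))
    warning(sprintf("%d intron-type row(s) match no derived intron; skipped", length(unmatched)))
  introns$splice_type <- ifelse(is.na(m), "unknown", tab$splice_type[m])
  models$introns <- introns
  attr(models, "report") <- list(
    n_rows = nrow(tab), n_matched = length(matched_rows),
    n_unmatched = length(unmatched),
    unmatched = tab[unmatched, , drop = FALSE])
  models
}

#' Write an intron-type annotation table
#'
#' @param models a \code{GeneModelSet} whose introns carry splice-type
#'   labels, or a data.frame with columns chrom, start, end, strand,
#'   gene_id, splice_type.
#' @param path output TSV path.
#' @param drop_unknown drop introns still labeled "unknown" (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_intron_types <- function(models, path, drop_unknown = TRUE) {
  tab <- if (inherits(models, "GeneModelSet")) models$introns else models
  tab <- tab[, c("chrom", "start", "end", "strand", "gene_id", "splice_type")]
  if (drop_unknown) tab <- tab[tab$splice_type != "unknown", , drop = FALSE]
  tab <- unique(tab)
  tab <- tab[order(tab$gene_id, tab$start), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the two U2-type reference introns for a U12-type intron
#'
#' Given the intron chain of one transcript (ordered 5' to 3') and the
#' index of a U12-type intron, returns the U2-labeled introns immediately
#' upstream and downstream in transcript order. When the U12-type intron
#' has no U2 intron on one side, the two nearest U2 introns on the
#' available side are used. Introns of unknown type are ineligible.
#'
#' @param chain data.frame with columns \code{intron_index} and
#'   \code{splice_type} for one transcript.
#' @param u12_index the transcript-order index of the U12-type intron.
#' @return list with \code{a}, \code{b} (reference intron indices, a < b)
#'   and \code{status} ("ok" or "insufficient_U2_references").
#' @export
select_reference_u2_introns <- function(chain, u12_index) {
  cand <- sort(chain$intron_index[chain$splice_type == "U2"])
  cand <- setdiff(cand, u12_index)
  if (length(cand) < 2L)
    return(list(a = NA_integer_, b = NA_integer_, status = "insufficient_U2_references"))
  up <- cand[cand < u12_index]
  down <- cand[cand > u12_index]
  if (length(up) && length(down)) {
    sel <- c(max(up), min(down))
  } else if (length(down)) {
    sel <- down[1:2]
  } else {
    sel <- sort(tail(up, 2L))
  }
  list(a = sel[1L], b = sel[2L], status = "ok")
}

#' Reference-pair table for all U12-type introns
#'
#' For every U12-labeled intron of every gene's canonical transcript,
#' selects the two U2-type reference introns
#' (\code{\link{select_reference_u2_introns}}). Genes whose U12 intron
#' cannot obtain two U2 references are retained with a reason code in
#' \code{status} and excluded from quantification downstream.
#'
#' @param models a labeled \code{GeneModelSet}.
#' @return data.frame, one row per (gene, U12 intron): gene coordinates of
#'   the U12 intron and of both references, plus \code{status}.
#' @export
reference_pairs <- function(models) {
  stopifnot(inherits(models, "GeneModelSet"))
  introns <- data.table::as.data.table(models$introns)
  genes <- models$genes
  canon <- introns[transcript_id %in% genes$canonical_transcript_id]
  u12 <- canon[splice_type == "U12"]
  if (!nrow(u12)) {
    return(data.frame(gene_id = character(), chrom = character(), strand = character(),
      u12_index = integer(), u12_start = integer(), u12_end = integer(),
      u2a_index = integer(), u2a_start = integer(), u2a_end = integer(),
      u2b_index = integer(), u2b_start = integer(), u2b_end = integer(),
      status = character(), stringsAsFactors = FALSE))
  }
  data.table::setorder(u12, gene_id, intron_index)
  res <- vector("list", nrow(u12))
  for (i in seq_len(nrow(u12))) {
    g <- u12$gene_id[i]
    chain <- canon[gene_id == g]
    sel <- select_reference_u2_introns(chain[, .(intron_index, splice_type)], u12$intron_index[i])
    row <- data.frame(gene_id = g, chrom = u12$chrom[i], strand = u12$strand[i],
      u12_index = u12$intron_index[i], u12_start = u12$start[i], u12_end = u12$end[i],
      u2a_index = sel$a, u2a_start = NA_integer_, u2a_end = NA_integer_,
      u2b_index = sel$b, u2b_start = NA_integer_, u2b_end = NA_integer_,
      status = sel$status, stringsAsFactors = FALSE)
    if (sel$status == "ok") {
      ia <- chain[intron_index == sel$a]; ib <- chain[intron_index == sel$b]
      row$u2a_start <- ia$start; row$u2a_end <- ia$end
      row$u2b_start <- ib$start; row$u2b_end <- ib$end
    }
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
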