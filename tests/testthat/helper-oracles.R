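# Independent brute-force oracles. These parse CIGAR strings and count
# positions read by read, base by base, sharing no code with the package's
# vectorised implementations.

oracle_cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", parts)),
       op = sub("^\\d+", "", parts))
}

# split reads skipping exactly [start, end] with >= min_anchor aligned
# bases adjacent on both sides
oracle_junction_count <- function(records, chrom, start, end, min_anchor = 6L) {
  n <- 0L
  for (i in seq_len(nrow(records))) {
    if (records$chrom[i] != chrom) next
    ops <- oracle_cigar_ops(records$cigar[i])
    pos <- records$pos[i]
    for (j in seq_along(ops$op)) {
      w <- ops$len[j]
      if (ops$op[j] == "N") {
        if (pos == start && pos + w - 1L == end) {
          left <- if (j > 1L && ops$op[j - 1L] == "M") ops$len[j - 1L] else 0L
          right <- if (j < length(ops$op) && ops$op[j + 1L] == "M") ops$len[j + 1L] else 0L
          if (left >= min_anchor && right >= min_anchor) n <- n + 1L
        }
      }
      if (ops$op[j] %in% c("M", "D", "N")) pos <- pos + w
    }
  }
  n
}

# per-base M coverage over [from, to]
oracle_pileup <- function(records, chrom, from, to) {
  depth <- integer(to - from + 1L)
  for (i in seq_len(nrow(records))) {
    if (records$chrom[i] != chrom) next
    ops <- oracle_cigar_ops(records$cigar[i])
    pos <- records$pos[i]
    for (j in seq_along(ops$op)) {
      w <- ops$len[j]
      if (ops$op[j] == "M") {
        lo <- max(pos, from); hi <- min(pos + w - 1L, to)
        if (lo <= hi) depth[(lo - from + 1L):(hi - from + 1L)] <-
            depth[(lo - from + 1L):(hi - from + 1L)] + 1L
      }
      if (ops$op[j] %in% c("M", "D", "N")) pos <- pos + w
    }
  }
  depth
}

oracle_depth <- function(records, chrom, start, end, edge_trim = 10L) {
  mean(oracle_pileup(records, chrom, start + edge_trim, end - edge_trim))
}

# all distinct N spans with both anchors >= min_anchor, with counts
oracle_gap_table <- function(records, min_anchor = 6L) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    ops <- oracle_cigar_ops(records$cigar[i])
    pos <- records$pos[i]
    for (j in seq_along(ops$op)) {
      w <- ops$len[j]
      if (ops$op[j] == "N") {
        left <- if (j > 1L && ops$op[j - 1L] == "M") ops$len[j - 1L] else 0L
        right <- if (j < length(ops$op) && ops$op[j + 1L] == "M") ops$len[j + 1L] else 0L
        if (left >= min_anchor && right >= min_anchor)
          rows[[length(rows) + 1L]] <- data.frame(chrom = records$chrom[i],
            start = pos, end = pos + w - 1L, stringsAsFactors = FALSE)
      }
      if (ops$op[j] %in% c("M", "D", "N")) pos <- pos + w
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(), start = integer(),
                                       end = integer(), n = integer()))
  d <- do.call(rbind, rows)
  agg <- aggregate(list(n = rep(1L, nrow(d))), d[c("chrom", "start", "end")], sum)
  agg[order(agg$chrom, agg$start, agg$end), , drop = FALSE]
}

# tiny cohort configuration used across tests
small_config <- function(...) {
  args <- utils::modifyList(list(
    n_genes = 30L, n_case_samples = 1L, n_control_samples = 2L,
    mean_fragments_per_gene = 200, seed = 11L), list(...))
  do.call(simulation_config, args)
}
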