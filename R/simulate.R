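#' Simulation configuration
#'
#' Parameters of the spliced-read simulator. Defaults describe the study
#' conditions the analysis targets: genes carrying one U12-type intron among
#' U2-type introns, 100-bp single-end reads at the depth of a moderately
#' expressed gene in a ~30M-read library, low baseline U12 intron retention
#' in controls, and (for affected genes in case samples) elevated retention
#' plus aberrant U2-type splicing of up to ~30% of spliced transcripts.
#'
#' @param n_genes number of genes to simulate.
#' @param n_case_samples,n_control_samples cohort sizes (defaults 2 and 4).
#' @param read_length read length in bp (default 100).
#' @param mean_fragments_per_gene mean sequenced fragments per gene
#'   (default 2000, the per-gene depth of a moderately expressed gene in a
#'   ~30M-fragment library).
#' @param expression_dispersion negative-binomial size parameter for
#'   between-sample fragment-count variation (default 20, ~22% biological CV).
#' @param expression_spread log-normal sdlog of between-gene expression
#'   levels around \code{mean_fragments_per_gene} (default 0.5).
#' @param baseline_retention probability that a molecule retains a given
#'   intron under normal minor-spliceosome function (default 0.02); applies
#'   to U2-type introns in all samples and to U12-type introns in controls
#'   and unaffected genes.
#' @param baseline_cryptic probability of aberrant (cryptic/exon-skip)
#'   processing of a spliced molecule at the U12 intron under normal
#'   function (default 0).
#' @param affected_gene_fraction fraction of genes drawn (once per
#'   simulation, among U12-bearing genes) as splicing-deficient in cases
#'   (default 0.04).
#' @param case_retention U12-intron retention probability for affected
#'   genes in case samples (default 0.3).
#' @param case_cryptic probability that a spliced molecule of an affected
#'   gene in a case sample uses the gene's aberrant isoform (default 0.3,
#'   the upper end of the observed <5--30% range).
#' @param u12_gene_fraction fraction of genes carrying exactly one U12-type
#'   intron (default 0.9); the remainder are all-U2 negative controls.
#' @param seed master RNG seed; per-sample substreams are derived from it
#'   and the sample id.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 500L,
                              n_case_samples = 2L,
                              n_control_samples = 4L,
                              read_length = 100L,
                              mean_fragments_per_gene = 2000,
                              expression_dispersion = 20,
                              expression_spread = 0.5,
                              baseline_retention = 0.02,
                              baseline_cryptic = 0,
                              affected_gene_fraction = 0.04,
                              case_retention = 0.3,
                              case_cryptic = 0.3,
                              u12_gene_fraction = 0.9,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_case_samples = as.integer(n_case_samples),
              n_control_samples = as.integer(n_control_samples),
              read_length = as.integer(read_length),
              mean_fragments_per_gene = as.numeric(mean_fragments_per_gene),
              expression_dispersion = as.numeric(expression_dispersion),
              expression_spread = as.numeric(expression_spread),
              baseline_retention = as.numeric(baseline_retention),
              baseline_cryptic = as.numeric(baseline_cryptic),
              affected_gene_fraction = as.numeric(affected_gene_fraction),
              case_retention = as.numeric(case_retention),
              case_cryptic = as.numeric(case_cryptic),
              u12_gene_fraction = as.numeric(u12_gene_fraction),
              seed = as.integer(seed))
  if (is.na(cfg$n_genes) || cfg$n_genes <= 0L) stop("config error: n_genes must be > 0")
  if (cfg$read_length < 20L) stop("config error: read_length too short")
  if (cfg$mean_fragments_per_gene <= 0) stop("config error: mean_fragments_per_gene must be > 0")
  if (cfg$expression_dispersion <= 0) stop("config error: expression_dispersion must be > 0")
  probs <- c("baseline_retention", "baseline_cryptic", "affected_gene_fraction",
             "case_retention", "case_cryptic", "u12_gene_fraction")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("config error: ", p, " must be in [0,1]")
  class(cfg) <- "simulation_config"
  cfg
}

# sample() without the length-one surprise
pick <- function(v, n = 1L) v[sample.int(length(v), n, replace = n > length(v))]

# Deterministic per-sample RNG substream seed (< 2^31).
sample_seed <- function(seed, sample_id) {
  h <- sum(utf8ToInt(sample_id) * seq_along(utf8ToInt(sample_id))) %% 1000003L
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

# Merge sorted genomic intervals, joining abutting/overlapping ones.
merge_blocks <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  keep_s <- start[1L]; keep_e <- end[1L]
  if (length(start) > 1L) {
    out_s <- integer(0); out_e <- integer(0)
    for (i in 2:length(start)) {
      if (start[i] <= keep_e + 1L) {
        keep_e <- max(keep_e, end[i])
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
        keep_s <- start[i]; keep_e <- end[i]
      }
    }
    return(list(start = c(out_s, keep_s), end = c(out_e, keep_e)))
  }
  list(start = keep_s, end = keep_e)
}

#' Simulate a gene set with U12-type intron annotation
#'
#' Draws gene structures (4--8 exons of 80--300 bp separated by introns of
#' 200--2000 bp, placed non-overlapping on synthetic chromosomes, random
#' strand). A seeded fraction of genes carries exactly one U12-type intron
#' at an internal position; the rest are all-U2 negative controls. Each
#' U12-bearing gene is assigned, once, an aberrant-processing mode (cryptic
#' donor or acceptor 30--90 bp inside the U12 intron, or skipping of the
#' exon 5' of it) and a per-gene expression level; affected
#' (splicing-deficient) genes are pre-drawn once and shared by all case
#' samples.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list of class \code{u12_simulation} with elements \code{models}
#'   (labeled \code{GeneModelSet}), \code{gene_params} (per-gene truth:
#'   expression level, U12 intron, aberrant type and coordinates, affected
#'   flag) and \code{config}.
#' @export
simulate_gene_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes_per_chrom <- 25L
  gap <- 5000L

  exon_list <- vector("list", n)
  params <- vector("list", n)
  chrom_ends <- list()
  cursor <- 1000L
  chrom_i <- 1L
  for (g in seq_len(n)) {
    if ((g - 1L) %% genes_per_chrom == 0L && g > 1L) {
      chrom_ends[[paste0("chr", chrom_i)]] <- cursor + 1000L
      chrom_i <- chrom_i + 1L
      cursor <- 1000L
    }
    chrom <- paste0("chr", chrom_i)
    n_exons <- sample(4:8, 1L)
    exon_len <- sample(80:300, n_exons, replace = TRUE)
    intron_len <- sample(200:2000, n_exons - 1L, replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- cursor
    for (i in seq_len(n_exons)) {
      starts[i] <- pos
      ends[i] <- pos + exon_len[i] - 1L
      if (i < n_exons) pos <- ends[i] + intron_len[i] + 1L
    }
    cursor <- ends[n_exons] + gap

    gene_id <- sprintf("G%05d", g)
    n_introns <- n_exons - 1L
    has_u12 <- stats::runif(1) < config$u12_gene_fraction
    # transcript-order index, internal so that flanking U2 introns exist
    u12_tx_index <- if (has_u12) pick(2:(n_introns - 1L)) else NA_integer_
    u12_gx_index <- if (has_u12) {
      if (strand == "+") u12_tx_index else n_introns + 1L - u12_tx_index
    } else NA_integer_
    aberrant_type <- if (has_u12)
      sample(c("cryptic_5p", "cryptic_3p", "exon_skip"), 1L) else "none"
    cryptic_offset <- sample(30:90, 1L)
    base_expr <- stats::rlnorm(1, meanlog = log(config$mean_fragments_per_gene),
                               sdlog = config$expression_spread)
    exon_list[[g]] <- data.frame(chrom = chrom, start = starts, end = ends,
      strand = strand, gene_id = gene_id,
      transcript_id = paste0(gene_id, ".T1"), stringsAsFactors = FALSE)
    params[[g]] <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
      n_exons = n_exons, has_u12 = has_u12, u12_tx_index = u12_tx_index,
      u12_gx_index = u12_gx_index, aberrant_type = aberrant_type,
      cryptic_offset = cryptic_offset, base_expression = base_expr,
      stringsAsFactors = FALSE)
  }
  chrom_ends[[paste0("chr", chrom_i)]] <- cursor + 1000L
  genome <- data.frame(chrom = names(chrom_ends),
                       length = as.integer(unlist(chrom_ends)),
                       stringsAsFactors = FALSE)
  genome <- genome[order(genome$chrom), , drop = FALSE]
  rownames(genome) <- NULL

  exons <- do.call(rbind, exon_list)
  models <- gene_model_set(exons, genome = genome)
  gene_params <- do.call(rbind, params)

  # label introns: U12 at the drawn position, U2 elsewhere
  introns <- models$introns
  key <- paste(introns$gene_id, vapply(seq_len(nrow(introns)), function(i) {
    introns$intron_index[i]
  }, integer(1)))
  introns$splice_type <- "U2"
  u12g <- gene_params[gene_params$has_u12, , drop = FALSE]
  u12_keys <- paste(u12g$gene_id, u12g$u12_tx_index)
  introns$splice_type[key %in% u12_keys] <- "U12"
  models$introns <- introns

  # affected genes: drawn once, shared across case samples
  n_affected <- round(config$affected_gene_fraction * config$n_genes)
  pool <- u12g$gene_id
  if (n_affected > length(pool))
    stop("config error: affected_gene_fraction exceeds the U12-bearing gene pool")
  affected <- if (n_affected > 0L) sample(pool, n_affected) else character(0)
  gene_params$affected <- gene_params$gene_id %in% affected

  # genomic coordinates of the U12 intron and the gene's aberrant junction
  idt <- data.table::as.data.table(models$introns)
  gene_params$u12_start <- NA_integer_; gene_params$u12_end <- NA_integer_
  gene_params$aberrant_start <- NA_integer_; gene_params$aberrant_end <- NA_integer_
  for (g in which(gene_params$has_u12)) {
    gid <- gene_params$gene_id[g]
    gint <- idt[gene_id == gid][order(start)]
    gi <- gene_params$u12_gx_index[g]
    us <- gint$start[gi]; ue <- gint$end[gi]
    gene_params$u12_start[g] <- us; gene_params$u12_end[g] <- ue
    d <- gene_params$cryptic_offset[g]
    st <- gene_params$strand[g]
    ab <- switch(gene_params$aberrant_type[g],
      cryptic_3p = if (st == "+") c(us, ue - d) else c(us + d, ue),
      cryptic_5p = if (st == "+") c(us + d, ue) else c(us, ue - d),
      exon_skip = if (st == "+") c(gint$start[gi - 1L], gint$end[gi])
                  else c(gint$start[gi], gint$end[gi + 1L]))
    gene_params$aberrant_start[g] <- ab[1L]
    gene_params$aberrant_end[g] <- ab[2L]
  }
  rownames(gene_params) <- NULL
  structure(list(models = models, gene_params = gene_params, config = config),
            class = "u12_simulation")
}

# Isoform block structure (genomic order) for one molecule class of a gene.
# exn: data.frame start,end of the gene's exons (genomic order);
# intr: same for introns; p: the gene_params row; u2_keep: genomic indices
# of additionally retained U2 introns.
isoform_blocks <- function(exn, intr, p, class, u2_keep) {
  s <- exn$start; e <- exn$end
  gi <- p$u12_gx_index
  if (class == "retained") {
    s <- c(s, intr$start[gi]); e <- c(e, intr$end[gi])
  } else if (class %in% c("cryptic_5p", "cryptic_3p")) {
    # retained intronic piece = U12 intron minus the aberrant junction span
    us <- intr$start[gi]; ue <- intr$end[gi]
    if (p$aberrant_start > us) { s <- c(s, us); e <- c(e, p$aberrant_start - 1L) }
    if (p$aberrant_end < ue) { s <- c(s, p$aberrant_end + 1L); e <- c(e, ue) }
  } else if (class == "exon_skip") {
    drop_exon <- if (p$strand == "+") gi else gi + 1L
    s <- s[-drop_exon]; e <- e[-drop_exon]
  }
  if (length(u2_keep)) {
    s <- c(s, intr$start[u2_keep]); e <- c(e, intr$end[u2_keep])
  }
  merge_blocks(s, e)
}

# Vectorised read placement on one isoform: uniform start offsets, genomic
# M/N op encoding. Returns data.frame(pos, cigar).
place_reads <- function(blocks, n, read_length) {
  w <- blocks$end - blocks$start + 1L
  g <- blocks$start
  L <- read_length
  len <- sum(w)
  if (len < L)
    stop("isoform shorter than read length; increase exon sizes")
  b <- cumsum(c(0L, w))   # transcript-space block starts (genomic order)
  u <- sample.int(len - L + 1L, n, replace = TRUE) - 1L
  i1 <- findInterval(u, b)
  i2 <- findInterval(u + L - 1L, b)
  pos <- g[i1] + (u - b[i1])
  k <- i2 - i1 + 1L
  if (any(k > 3L)) stop("read spans more than three isoform blocks")
  cigar <- character(n)
  one <- k == 1L
  if (any(one)) cigar[one] <- sprintf("%dM", L)
  two <- k == 2L
  if (any(two)) {
    a <- b[i1[two] + 1L] - u[two]
    gap <- g[i1[two] + 1L] - (g[i1[two]] + w[i1[two]])
    cigar[two] <- sprintf("%dM%dN%dM", a, gap, L - a)
  }
  three <- k == 3L
  if (any(three)) {
    a <- b[i1[three] + 1L] - u[three]
    m2 <- w[i1[three] + 1L]
    gap1 <- g[i1[three] + 1L] - (g[i1[three]] + w[i1[three]])
    gap2 <- g[i1[three] + 2L] - (g[i1[three] + 1L] + m2)
    cigar[three] <- sprintf("%dM%dN%dM%dN%dM", a, gap1, m2, gap2, L - a - m2)
  }
  data.frame(pos = pos, cigar = cigar, stringsAsFactors = FALSE)
}

#' Simulate aligned spliced reads for one sample
#'
#' Per gene, the fragment count is negative-binomial around the gene's
#' expression level; each molecule is assigned an isoform class at the U12
#' intron hierarchically -- retained with the retention probability, else
#' aberrant (the gene's fixed cryptic/exon-skip mode) with the cryptic
#' probability, else canonically spliced -- so that the aberrant share is a
#' fraction of spliced molecules. U2-type introns are retained
#' independently at the baseline rate in every sample. One 100-bp read per
#' molecule is placed uniformly along the molecule's isoform and projected
#' to genomic match/skip (M/N) operations.
#'
#' @param sim output of \code{\link{simulate_gene_set}}.
#' @param sample_id sample name (also seeds this sample's RNG substream).
#' @param condition "case" or "control".
#' @return list with \code{records} (data.table: read_id, chrom, pos,
#'   strand, cigar, gene_id, truth_class, sorted by coordinate) and
#'   \code{truth} (per-gene molecule counts by class).
#' @export
simulate_sample <- function(sim, sample_id, condition = c("control", "case")) {
  stopifnot(inherits(sim, "u12_simulation"))
  condition <- match.arg(condition)
  config <- sim$config
  sseed <- sample_seed(config$seed, sample_id)

  exdt <- data.table::as.data.table(sim$models$exons)
  indt <- data.table::as.data.table(sim$models$introns)
  data.table::setorder(exdt, gene_id, start)
  data.table::setorder(indt, gene_id, start)
  ex_split <- split(exdt[, .(start, end)], exdt$gene_id)
  in_split <- split(indt[, .(start, end)], indt$gene_id)
  gp <- sim$gene_params

  rec_list <- vector("list", nrow(gp))
  truth_list <- vector("list", nrow(gp))
  for (g in seq_len(nrow(gp))) {
    p <- gp[g, ]
    # per-gene substream: matched simulations (same seed, one parameter
    # varied) stay matched gene by gene
    set.seed((sseed + 7919 * g) %% 2147483647)
    N <- stats::rnbinom(1L, size = config$expression_dispersion, mu = p$base_expression)
    truth_counts <- c(canonical = 0L, retained = 0L, cryptic_5p = 0L,
                      cryptic_3p = 0L, exon_skip = 0L)
    if (N == 0L) {
      truth_list[[g]] <- data.frame(sample_id = sample_id, condition = condition,
        gene_id = p$gene_id, n_molecules = 0L, t(truth_counts),
        retention_prob = NA_real_, cryptic_prob = NA_real_, stringsAsFactors = FALSE)
      next
    }
    affected_here <- condition == "case" && p$affected
    r <- if (!p$has_u12) 0 else if (affected_here) config$case_retention else config$baseline_retention
    cr <- if (!p$has_u12 || p$aberrant_type == "none") 0 else
      if (affected_here) config$case_cryptic else config$baseline_cryptic

    n_ret <- stats::rbinom(1L, N, r)
    n_ab <- stats::rbinom(1L, N - n_ret, cr)
    class <- rep(c("retained", p$aberrant_type, "canonical"),
                 c(n_ret, n_ab, N - n_ret - n_ab))
    if (!p$has_u12) class <- rep("canonical", N)

    exn <- as.data.frame(ex_split[[p$gene_id]])
    intr <- if (p$gene_id %in% names(in_split)) as.data.frame(in_split[[p$gene_id]]) else
      data.frame(start = integer(), end = integer())
    # independent baseline retention of U2-type introns in every molecule
    u2_idx <- setdiff(seq_len(nrow(intr)), if (p$has_u12) p$u12_gx_index else integer(0))
    u2pat <- character(N)
    for (j in u2_idx) {
      kj <- stats::rbinom(1L, N, config$baseline_retention)
      if (kj > 0L) {
        idx <- sample.int(N, kj)
        u2pat[idx] <- paste(u2pat[idx], j)
      }
    }
    grp <- paste(class, u2pat)
    ug <- unique(grp)
    gr_list <- vector("list", length(ug))
    for (q in seq_along(ug)) {
      sel <- which(grp == ug[q])
      cls <- class[sel[1L]]
      keep <- as.integer(strsplit(trimws(u2pat[sel[1L]]), " +")[[1]])
      keep <- keep[!is.na(keep)]
      blocks <- isoform_blocks(exn, intr, p, cls, keep)
      pr <- place_reads(blocks, length(sel), config$read_length)
      gr_list[[q]] <- data.table::data.table(chrom = p$chrom, pos = pr$pos,
        strand = p$strand, cigar = pr$cigar, gene_id = p$gene_id,
        truth_class = cls)
    }
    rec_list[[g]] <- data.table::rbindlist(gr_list)
    tc <- table(class)
    truth_counts[names(tc)] <- as.integer(tc)
    truth_list[[g]] <- data.frame(sample_id = sample_id, condition = condition,
      gene_id = p$gene_id, n_molecules = N, t(truth_counts),
      retention_prob = r, cryptic_prob = cr, stringsAsFactors = FALSE)
  }
  records <- data.table::rbindlist(rec_list)
  if (nrow(records)) {
    records[, read_id := sprintf("%s_r%08d", sample_id, seq_len(.N))]
    data.table::setorder(records, chrom, pos, read_id)
    data.table::setcolorder(records, c("read_id", "chrom", "pos", "strand",
                                       "cigar", "gene_id", "truth_class"))
  } else {
    records <- data.table::data.table(read_id = character(), chrom = character(),
      pos = integer(), strand = character(), cigar = character(),
      gene_id = character(), truth_class = character())
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Write simulated alignment records to a SAM file
#'
#' Emits a coordinate-sorted SAM with \code{@HD}/\code{@SQ} headers, FLAG
#' 0/16 by strand, MAPQ 60, the record's M/N CIGAR, deterministic seeded
#' bases as SEQ and a constant high-quality QUAL string. Identical records
#' always produce identical bytes.
#'
#' @param records data.frame/data.table with read_id, chrom, pos, strand,
#'   cigar (as from \code{\link{simulate_sample}}; extra columns ignored).
#' @param genome chromosome-length table (chrom, length).
#' @param path output SAM path.
#' @param read_length read length used for SEQ/QUAL strings.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(records, genome, path, read_length = 100L) {
  records <- data.table::as.data.table(records)
  if (nrow(records) && !all(records$chrom %in% genome$chrom))
    stop("record chromosome absent from genome")
  genome <- genome[order(genome$chrom), , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, genome$length))
  writeLines(header, path)
  if (!nrow(records)) return(invisible(path))
  data.table::setorder(records, chrom, pos, read_id)
  # deterministic seeded base pool; global RNG state untouched
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(104729L)
  pool <- paste(sample(c("A", "C", "G", "T"), 65536L, replace = TRUE), collapse = "")
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  off <- (records$pos %% (65536L - read_length)) + 1L
  seqs <- substring(pool, off, off + read_length - 1L)
  qual <- strrep("I", read_length)
  out <- data.table::data.table(
    qname = records$read_id,
    flag = ifelse(records$strand == "-", 16L, 0L),
    rname = records$chrom,
    pos = records$pos,
    mapq = 60L,
    cigar = records$cigar,
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = seqs, qual = qual)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     append = TRUE)
  invisible(path)
}

#' Simulate a full case/control cohort to disk
#'
#' Runs \code{\link{simulate_gene_set}} and \code{\link{simulate_sample}}
#' for every sample and writes: \code{genome.tsv}, \code{models.gtf},
#' \code{intron_types.tsv}, \code{samples.tsv} (sample_id, condition), one
#' coordinate-sorted SAM per sample, per-read truth sidecars
#' (\code{<sample>.truth_reads.tsv}), the per-gene molecule-class truth
#' table (\code{truth_molecules.tsv}) and the per-gene simulation truth
#' (\code{truth_genes.tsv}: expression, U12 intron, aberrant mode,
#' affected flag).
#'
#' @param config a \code{\link{simulation_config}}.
#' @param outdir output directory (created if needed).
#' @return list with \code{sim} (the in-memory simulation), \code{samples}
#'   (sample table) and \code{paths} (named file paths).
#' @export
simulate_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_gene_set(config)
  pth <- function(x) file.path(outdir, x)
  utils::write.table(sim$models$genome, pth("genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gtf(sim$models, pth("models.gtf"))
  write_intron_types(sim$models, pth("intron_types.tsv"))
  utils::write.table(sim$gene_params, pth("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  samples <- data.frame(
    sample_id = c(sprintf("case%02d", seq_len(config$n_case_samples)),
                  sprintf("ctrl%02d", seq_len(config$n_control_samples))),
    condition = c(rep("case", config$n_case_samples),
                  rep("control", config$n_control_samples)),
    stringsAsFactors = FALSE)
  utils::write.table(samples, pth("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_all <- vector("list", nrow(samples))
  sam_paths <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- simulate_sample(sim, samples$sample_id[i], samples$condition[i])
    sam_paths[i] <- pth(paste0(samples$sample_id[i], ".sam"))
    write_sam(s$records, sim$models$genome, sam_paths[i], config$read_length)
    data.table::fwrite(s$records[, c("read_id", "gene_id", "truth_class")],
                       pth(paste0(samples$sample_id[i], ".truth_reads.tsv")), sep = "\t")
    truth_all[[i]] <- s$truth
  }
  truth <- do.call(rbind, truth_all)
  utils::write.table(truth, pth("truth_molecules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  names(sam_paths) <- samples$sample_id
  list(sim = sim, samples = samples, truth = truth,
       paths = c(list(genome = pth("genome.tsv"), gtf = pth("models.gtf"),
                      intron_types = pth("intron_types.tsv"),
                      samples = pth("samples.tsv"),
                      truth_genes = pth("truth_genes.tsv"),
                      truth_molecules = pth("truth_molecules.tsv")),
                 as.list(sam_paths)))
}
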