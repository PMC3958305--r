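make_gal <- function(records, genome) {
  f <- tempfile(fileext = ".sam")
  write_sam(records, genome, f, read_length = 100L)
  read_alignments(f)
}

test_that("junction counting requires an exact span match and both anchors", {
  genome <- data.frame(chrom = "chr1", length = 10000L)
  rec <- function(pos, cigar, id) data.frame(read_id = id, chrom = "chr1",
    pos = pos, strand = "+", cigar = cigar, stringsAsFactors = FALSE)
  # junction skipping [1021, 1520]
  recs <- rbind(
    rec(1001L, "20M500N80M", "ok"),        # anchors 20/80 -> counted
    rec(1017L, "4M500N96M", "short"),      # left anchor 4 < 6 -> not counted
    rec(1001L, "20M501N80M", "off_by_one") # different span -> not counted
  )
  gal <- make_gal(recs, genome)
  j <- list(chrom = "chr1", start = 1021L, end = 1520L)
  expect_equal(count_junction_reads(gal, j, min_anchor = 6L), 1L)
  expect_equal(count_junction_reads(gal, j, min_anchor = 4L), 2L)
  expect_equal(count_junction_reads(gal, list(chrom = "chr2", start = 1021L, end = 1520L)), 0L)
})

test_that("intron depth is mean M coverage over the trimmed body; N contributes nothing", {
  genome <- data.frame(chrom = "chr1", length = 10000L)
  # ten 100-bp reads fully inside a body whose trimmed width is 1000
  recs <- data.frame(read_id = sprintf("r%d", 1:10), chrom = "chr1",
                     pos = seq(2011L, 2911L, by = 100L), strand = "+",
                     cigar = "100M", stringsAsFactors = FALSE)
  gal <- make_gal(recs, genome)
  intron <- list(chrom = "chr1", start = 2001L, end = 3020L)  # trimmed: 2011..3010
  expect_equal(intron_depth(gal, intron, edge_trim = 10L), 1.0)
  # spliced read skipping the body adds nothing
  recs2 <- rbind(recs, data.frame(read_id = "sp", chrom = "chr1", pos = 1951L,
                                  strand = "+", cigar = "50M1070N50M"))
  expect_equal(intron_depth(make_gal(recs2, genome), intron, edge_trim = 10L), 1.0)
  # no overlapping reads -> 0; too-short intron -> NA with reason
  expect_equal(intron_depth(gal, list(chrom = "chr1", start = 8000L, end = 9000L)), 0)
  short <- intron_depth(gal, list(chrom = "chr1", start = 100L, end = 115L), edge_trim = 10L)
  expect_true(is.na(short))
  expect_equal(attr(short, "reason"), "intron_too_short")
})

test_that("FPKM follows the fragments / kb / million definition", {
  ex <- data.frame(chrom = "chr1", start = c(1001L, 3001L), end = c(2000L, 4000L),
                   strand = "+", gene_id = "gA", transcript_id = "gA.t1")
  m <- gene_model_set(ex, genome = data.frame(chrom = "chr1", length = 100000L))
  recs <- data.frame(read_id = sprintf("r%d", 1:200), chrom = "chr1",
                     pos = rep(c(1101L, 3101L), 100), strand = "+",
                     cigar = "100M", stringsAsFactors = FALSE)
  gal <- make_gal(recs, m$genome)
  gene <- m$genes[1, ]
  expect_equal(gene_fpkm(gal, gene, m, total_mapped = 1e7), 200 / 2 / 10)
  expect_equal(gene_fpkm(gal[0], gene, m, total_mapped = 1e7), 0)
  expect_error(gene_fpkm(gal, gene, m, total_mapped = 0), "total_mapped")
})

test_that("sample quantification equals brute-force oracle counting", {
  cfg <- small_config(n_genes = 15L, mean_fragments_per_gene = 150, seed = 61L)
  sim <- simulate_gene_set(cfg)
  s <- simulate_sample(sim, "case01", "case")
  f <- tempfile(fileext = ".sam")
  write_sam(s$records, sim$models$genome, f, cfg$read_length)
  q <- quantify_sample(f, sim$models, sample_id = "case01")
  recs <- as.data.frame(s$records)
  expect_equal(unique(q$total_mapped), nrow(recs))
  for (i in seq_len(nrow(q))) {
    expect_equal(q$J_u12[i], oracle_junction_count(recs, q$chrom[i],
                                                   q$u12_start[i], q$u12_end[i]),
                 label = paste("J_u12", q$gene_id[i]))
    expect_equal(q$D_u12[i], oracle_depth(recs, q$chrom[i], q$u12_start[i], q$u12_end[i]),
                 label = paste("D_u12", q$gene_id[i]))
  }
  rp <- reference_pairs(sim$models)
  rp <- rp[match(q$gene_id, rp$gene_id), ]
  i <- 1L
  expect_equal(q$J_u2a[i], oracle_junction_count(recs, q$chrom[i], rp$u2a_start[i], rp$u2a_end[i]))
  expect_equal(q$J_u2b[i], oracle_junction_count(recs, q$chrom[i], rp$u2b_start[i], rp$u2b_end[i]))
  expect_equal(q$D_u2a[i], oracle_depth(recs, q$chrom[i], rp$u2a_start[i], rp$u2a_end[i]))
})

test_that("quantification is independent of SAM record order", {
  cfg <- small_config(n_genes = 8L, seed = 67L)
  sim <- simulate_gene_set(cfg)
  s <- simulate_sample(sim, "ctrl01", "control")
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(s$records, sim$models$genome, f1, cfg$read_length)
  set.seed(1)
  shuf <- s$records[sample(nrow(s$records)), ]
  # write shuffled records manually (write_sam re-sorts; bypass the sort)
  hdr <- readLines(f1, n = 1L + nrow(sim$models$genome))
  body <- setdiff(readLines(f1), hdr)
  writeLines(c(hdr, sample(body)), f2)
  q1 <- quantify_sample(f1, sim$models, sample_id = "s")
  q2 <- quantify_sample(f2, sim$models, sample_id = "s")
  expect_equal(q1, q2, ignore_attr = TRUE)
})

test_that("higher simulated retention raises intron depth and lowers junction counts", {
  qs <- lapply(c(0, 0.1, 0.3), function(r) {
    cfg <- simulation_config(n_genes = 5L, n_case_samples = 1L, n_control_samples = 1L,
                             mean_fragments_per_gene = 3000, expression_spread = 0.01,
                             affected_gene_fraction = 1, case_retention = r,
                             case_cryptic = 0, u12_gene_fraction = 1, seed = 71L)
    sim <- simulate_gene_set(cfg)
    s <- simulate_sample(sim, "case01", "case")
    f <- tempfile(fileext = ".sam")
    write_sam(s$records, sim$models$genome, f, cfg$read_length)
    quantify_sample(f, sim$models, sample_id = "case01")
  })
  # same seed => same gene structures and molecule counts; matched per gene
  for (g in seq_len(nrow(qs[[1]]))) {
    d <- vapply(qs, function(q) q$D_u12[g], numeric(1))
    expect_true(all(diff(d) > 0))
  }
  # junction counts drop as retention diverts molecules from splicing
  j_tot <- vapply(qs, function(q) sum(q$J_u12), numeric(1))
  expect_true(all(diff(j_tot) < 0))
})

test_that("FPKM recovers the simulated expression ranking", {
  cfg <- simulation_config(n_genes = 120L, n_case_samples = 1L, n_control_samples = 1L,
                           mean_fragments_per_gene = 300, expression_spread = 1.5,
                           u12_gene_fraction = 1, seed = 73L)
  sim <- simulate_gene_set(cfg)
  s <- simulate_sample(sim, "ctrl01", "control")
  f <- tempfile(fileext = ".sam")
  write_sam(s$records, sim$models$genome, f, cfg$read_length)
  q <- quantify_sample(f, sim$models, sample_id = "ctrl01")
  truth <- sim$gene_params$base_expression[match(q$gene_id, sim$gene_params$gene_id)]
  expect_gte(cor(q$fpkm, truth, method = "spearman"), 0.95)
})

test_that("a sample with zero mapped reads is rejected with a clear message", {
  genome <- data.frame(chrom = "chr1", length = 1000L)
  f <- tempfile(fileext = ".sam")
  write_sam(data.frame(read_id = character(), chrom = character(), pos = integer(),
                       strand = character(), cigar = character()), genome, f)
  ex <- data.frame(chrom = "chr1", start = c(1L, 201L), end = c(100L, 300L),
                   strand = "+", gene_id = "g", transcript_id = "g.t")
  m <- gene_model_set(ex, genome)
  expect_error(quantify_sample(f, m, sample_id = "empty"), "zero mapped reads")
})
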