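# shared cohort with strong aberrant splicing in the case sample
aberrant_cohort <- function(seed = 103L, case_cryptic = 0.3, n_genes = 12L,
                            mean_fragments = 3000) {
  cfg <- simulation_config(n_genes = n_genes, n_case_samples = 1L,
                           n_control_samples = 2L, mean_fragments_per_gene = mean_fragments,
                           expression_spread = 0.01, affected_gene_fraction = 1,
                           case_cryptic = case_cryptic, u12_gene_fraction = 1, seed = seed)
  simulate_cohort(cfg, tempfile())
}

test_that("event classification follows the donor/acceptor sharing rules on both strands", {
  introns <- data.frame(start = c(1000L, 3000L, 5000L), end = c(1999L, 3999L, 5999L))
  u12 <- list(start = 3000L, end = 3999L)
  cls <- function(js, je, strand = "+")
    classify_event(list(chrom = "c", start = js, end = je), introns, u12, strand)
  # plus strand: donor = start side
  expect_equal(cls(3000L, 3939L), "cryptic_3p")   # shared donor, acceptor -60
  expect_equal(cls(3060L, 3999L), "cryptic_5p")   # shared acceptor, donor +60
  expect_equal(cls(1000L, 3999L), "exon_skip")    # intron1 donor -> intron2 acceptor
  expect_equal(cls(3000L, 5999L), "exon_skip")
  expect_equal(cls(1000L, 5999L), "exon_skip")    # double skip crossing the U12 intron
  expect_equal(cls(3000L, 3500L), "other")        # shared donor, acceptor 499 bp away
  expect_equal(cls(1234L, 4321L), "other")        # shares nothing
  expect_equal(cls(1000L, 1999L, "+"), "other")   # annotated U2 span, no donor/acceptor logic
  # minus strand mirror: donor = end side
  expect_equal(cls(3060L, 3999L, "-"), "cryptic_3p")
  expect_equal(cls(3000L, 3939L, "-"), "cryptic_5p")
  expect_equal(cls(1000L, 3999L, "-"), "exon_skip")
})

test_that("a purely canonical sample yields no novel junctions", {
  cfg <- simulation_config(n_genes = 8L, n_case_samples = 1L, n_control_samples = 1L,
                           mean_fragments_per_gene = 1000, baseline_retention = 0,
                           affected_gene_fraction = 0, u12_gene_fraction = 1, seed = 107L)
  sim <- simulate_gene_set(cfg)
  s <- simulate_sample(sim, "ctrl01", "control")
  f <- tempfile(fileext = ".sam")
  write_sam(s$records, sim$models$genome, f, cfg$read_length)
  nv <- enumerate_novel_junctions(read_alignments(f), sim$models)
  expect_equal(nrow(nv), 0L)
})

test_that("novel junctions match the truth sidecar and the min_support floor applies", {
  co <- aberrant_cohort()
  sim <- co$sim
  gal <- read_alignments(co$paths$case01)
  gaps <- splice_gaps(gal)
  nv <- enumerate_novel_junctions(gaps, sim$models, min_support = 3L)
  gp <- sim$gene_params
  recs <- data.table::fread(co$paths$case01, skip = length(unique(gp$chrom)) + 1L,
                            header = FALSE,
                            col.names = c("read_id", "flag", "chrom", "pos", "mapq",
                                          "cigar", "rn", "pn", "tl", "seq", "qual"))
  oracle <- oracle_gap_table(as.data.frame(recs), min_anchor = 6L)
  ann <- unique(sim$models$introns[, c("chrom", "start", "end")])
  okey <- paste(oracle$chrom, oracle$start, oracle$end)
  oracle_novel <- oracle[!okey %in% paste(ann$chrom, ann$start, ann$end) & oracle$n >= 3L, ]
  expect_equal(nrow(nv), nrow(oracle_novel))
  expect_equal(paste(nv$chrom, nv$start, nv$end),
               paste(oracle_novel$chrom, oracle_novel$start, oracle_novel$end))
  expect_equal(nv$support_reads, oracle_novel$n)
  # every aberrant junction sits at the gene's pre-drawn aberrant site
  m <- match(nv$gene_id, gp$gene_id)
  expect_equal(nv$start, gp$aberrant_start[m])
  expect_equal(nv$end, gp$aberrant_end[m])
  # raising min_support can only shrink the list
  nv10 <- enumerate_novel_junctions(gaps, sim$models, min_support = 200L)
  expect_lt(nrow(nv10), nrow(nv))
})

test_that("junction reads partition into annotated plus novel under one anchor rule", {
  co <- aberrant_cohort(seed = 109L, n_genes = 8L)
  gal <- read_alignments(co$paths$case01)
  gaps <- splice_gaps(gal)
  keep <- gaps[gaps$left_anchor >= 6L & gaps$right_anchor >= 6L, ]
  ann <- unique(co$sim$models$introns[, c("chrom", "start", "end")])
  is_ann <- paste(keep$chrom, keep$start, keep$end) %in% paste(ann$chrom, ann$start, ann$end)
  nv <- enumerate_novel_junctions(gaps, co$sim$models, min_support = 1L)
  expect_equal(sum(!is_ann), sum(nv$support_reads))
  expect_equal(sum(is_ann) + sum(!is_ann), nrow(keep))
})

test_that("event fractions recover the configured aberrant share and flag case exclusivity", {
  co <- aberrant_cohort(seed = 113L, n_genes = 12L, mean_fragments = 5000)
  m <- co$sim$models
  rp <- reference_pairs(m)
  gaps <- lapply(setNames(co$samples$sample_id, co$samples$sample_id), function(sid)
    splice_gaps(read_alignments(co$paths[[sid]])))
  quants <- do.call(rbind, lapply(co$samples$sample_id, function(sid)
    quantify_sample(read_alignments(co$paths[[sid]]), m, rp, sample_id = sid,
                    gaps = gaps[[sid]])))
  ev <- detect_events(gaps, m, co$samples, quants)
  gp <- co$sim$gene_params
  # classified class equals the gene's configured aberrant mode
  m2 <- match(ev$per_sample$gene_id, gp$gene_id)
  expect_equal(ev$per_sample$event_class, gp$aberrant_type[m2])
  # pooled case fraction near 0.3 for cryptic-site genes (binomial band)
  pooled <- ev$pooled[ev$pooled$condition == "case" & ev$pooled$support_reads > 0, ]
  pooled <- pooled[pooled$event_class %in% c("cryptic_5p", "cryptic_3p"), ]
  expect_gt(nrow(pooled), 0L)
  n <- pooled$support_reads + pooled$canonical_reads
  expect_true(all(abs(pooled$fraction - 0.3) < 3 * sqrt(0.3 * 0.7 / n)))
  # aberrant events absent from controls are flagged case-exclusive
  expect_true(all(ev$per_sample$case_exclusive[ev$per_sample$condition == "case" &
                                               ev$per_sample$fraction > 0.05]))
})

test_that("fraction arithmetic: support 30 canonical 70 gives 0.30", {
  events <- data.frame(gene_id = "g1", sample_id = "s1", chrom = "c", start = 10L,
                       end = 20L, event_class = "cryptic_3p", support_reads = 30L)
  quants <- data.frame(gene_id = "g1", sample_id = "s1", J_u12 = 70L)
  samples <- data.frame(sample_id = "s1", condition = "case")
  ef <- event_fractions(events, quants, samples)
  expect_equal(ef$per_sample$fraction, 0.30)
  expect_equal(ef$pooled$fraction[ef$pooled$condition == "case"], 0.30)
})

test_that("baseline simulations produce no events in almost all genes", {
  cfg <- simulation_config(n_genes = 40L, n_case_samples = 1L, n_control_samples = 1L,
                           mean_fragments_per_gene = 1000, affected_gene_fraction = 0,
                           u12_gene_fraction = 1, seed = 127L)
  sim <- simulate_gene_set(cfg)
  s <- simulate_sample(sim, "ctrl01", "control")
  f <- tempfile(fileext = ".sam")
  write_sam(s$records, sim$models$genome, f, cfg$read_length)
  nv <- enumerate_novel_junctions(read_alignments(f), sim$models, min_support = 3L)
  expect_lte(length(unique(nv$gene_id)), 2L)  # >= 95% of 40 genes clean
})
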