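# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", "..jkey", "transcript_id", "gene_id", "chrom", "start", "end",
  "strand", "intron_index", "splice_type", "exonic_length", "n_exons",
  "read_id", "rid", "op", "len", "rc", "off", "prev_op", "prev_len",
  "next_op", "next_len", "prev_rid", "next_rid", "left_anchor",
  "right_anchor", "J_u12", "J_u2a", "J_u2b", "D_u12", "D_u2a", "D_u2b",
  "fpkm", "r_u12_u2", "r_u12_fpkm", "ir_u2", "ir_fpkm", "sample_id",
  "fpkm_ok", "ref_ok", "reason", "detected", "value", "metric", "cv",
  "discard", "z", "ctrl_mean", "ctrl_sd", "support_reads",
  "canonical_reads", "fraction", "condition", "case_exclusive", "gstart",
  "gend", "event_class", "truth_class", "jid", "case", "control",
  "canonical", "n_molecules"))
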