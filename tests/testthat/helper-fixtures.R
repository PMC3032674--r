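# Shared fixtures, built in code.

# A tiny hand-made locus: primer GGAT, then body with two CpGs, a CpH
# cytosine and a TTTT homopolymer.
#   GGAT  CGTACA  CGA  TTTT  CAG
# 0-based CpG positions: 4 and 10.
toy_locus <- function(name = "toy") {
  locus(name, "GGATCGTACACGATTTTCAG", c(4L, 10L), primer_len = 4L)
}

# expected fully converted, fully unmethylated read body for toy_locus
# (alignable region, all C -> T)
toy_body_unmeth <- function() gsub("C", "T", "CGTACACGATTTTCAG")

# a small deterministic error-free run over two loci and two samples
toy_run <- function(reads_per_bin = 10L, seed = 11L,
                    error = error_model(0, 0, 0, 0),
                    p_full = 0.2, p_none = 0.3) {
  l1 <- build_locus("L1", 140, 5, 0.5, seed = 101)
  l2 <- build_locus("L2", 180, 6, 0.55, seed = 102)
  models <- list(
    "S1|L1" = epiallele_model(p_full, p_none, rep(0.5, 5)),
    "S1|L2" = epiallele_model(p_full, p_none, rep(0.3, 6)),
    "S2|L1" = epiallele_model(p_full, p_none, rep(0.7, 5)),
    "S2|L2" = epiallele_model(p_full, p_none, rep(0.4, 6)))
  simulate_run(list(l1, l2), c("S1", "S2"), models, reads_per_bin,
               error, seed = seed)
}

# align every demultiplexed bin of a run; returns rbind-ed metrics table
align_run <- function(run, demux, identity_mode = "filtered") {
  crefs <- lapply(run$loci, convert_reference)
  a <- demux$assignments
  do.call(rbind, lapply(split(a, paste(a$sample_id, a$locus)),
    function(bin) {
      seqs <- bin$sequence
      names(seqs) <- bin$read_id
      align_bin(seqs, crefs[[bin$locus[1]]],
                identity_mode = identity_mode,
                sample = bin$sample_id[1], locus = bin$locus[1])
    }))
}

# manual bs_alignment constructor for metric unit tests
fake_alignment <- function(read_gapped, labels, ordinals = NULL,
                           n_cpg = sum(labels == 5L)) {
  if (is.null(ordinals)) {
    ordinals <- integer(length(labels))
    ordinals[labels == 5L] <- seq_len(sum(labels == 5L))
  }
  structure(list(read_id = "fake", score = NA_real_,
                 read_gapped = read_gapped, labels_gapped = labels,
                 ordinals_gapped = ordinals, n_cpg = n_cpg,
                 identity_pct = NA_real_, conversion_pct = NA_real_,
                 cpg_calls = NULL),
            class = "bs_alignment")
}
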