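test_that("build_locus is deterministic, honours invariants, rejects impossible placements", {
  loc <- build_locus("L1", 200, 8, 0.6, seed = 7)
  expect_s3_class(loc, "bs_locus")
  expect_identical(loc, build_locus("L1", 200, 8, 0.6, seed = 7))
  expect_false(identical(loc$sequence,
                         build_locus("L1", 200, 8, 0.6, seed = 8)$sequence))
  ch <- strsplit(loc$sequence, "", fixed = TRUE)[[1]]
  expect_length(loc$cpg_positions, 8)
  expect_true(all(ch[loc$cpg_positions + 1] == "C"))
  expect_true(all(ch[loc$cpg_positions + 2] == "G"))
  expect_true(all(diff(loc$cpg_positions) >= 2))
  expect_true(all(loc$cpg_positions >= loc$primer_len))
  expect_true(all(loc$cpg_positions <= nchar(loc$sequence) - 2))
  # no accidental CpG outside the annotated set
  all_cg <- gregexpr("(?=CG)", loc$sequence, perl = TRUE)[[1]] - 1L
  expect_setequal(all_cg, loc$cpg_positions)
  # guaranteed homopolymer run of length >= 4
  expect_true(max(rle(ch)$lengths) >= 4)
  expect_error(build_locus("X", 120, 9, 0.5, seed = 1, primer_len = 100),
               "impossible placement")
  expect_error(build_locus("X", 90, 3, 0.5, seed = 1), "between 100 and 350")
})

test_that("generated loci hit the requested GC fraction on average", {
  gc <- vapply(1:1000, function(i) {
    s <- build_locus("g", 150, 3, 0.5, seed = 5000 + i)$sequence
    mean(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  }, 0)
  expect_lt(abs(mean(gc) - 0.5), 0.03)
})

test_that("epiallele sampling reproduces the analytic mixture probabilities", {
  k <- 6L
  m <- epiallele_model(0.3, 0.3, rep(0.5, k))
  mat <- sample_epialleles(m, 10000, seed = 42)
  expect_identical(dim(mat), c(10000L, k))
  # P(fully methylated row) = p_full + (1 - p_full - p_none) * prod(site)
  p <- 0.3 + 0.4 * 0.5^k
  obs <- mean(rowSums(mat) == k)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 10000))
  # degenerate mixtures
  expect_true(all(sample_epialleles(
    epiallele_model(1, 0, rep(0.2, 3)), 50, seed = 1) == 1L))
  expect_true(all(sample_epialleles(
    epiallele_model(0, 0, rep(0, 3)), 50, seed = 1) == 0L))
  expect_error(epiallele_model(0.7, 0.5, rep(0.5, 3)), "<= 1")
  expect_error(epiallele_model(-0.1, 0, rep(0.5, 3)), "\\[0, 1\\]")
  expect_identical(sample_epialleles(m, 100, seed = 9),
                   sample_epialleles(m, 100, seed = 9))
})

test_that("bisulfite conversion respects methylation state and failure rate", {
  loc <- build_locus("L", 150, 5, 0.5, seed = 3)
  em0 <- error_model(0, 0, 0, 0)
  s0 <- bisulfite_convert_molecule(loc, rep(0L, 5), em0, seed = 1)
  expect_false(grepl("C", s0))
  s1 <- bisulfite_convert_molecule(loc, rep(1L, 5), em0, seed = 1)
  ch <- strsplit(s1, "", fixed = TRUE)[[1]]
  expect_identical(which(ch == "C") - 1L, loc$cpg_positions)
  expect_identical(nchar(s1), nchar(loc$sequence))
  expect_error(bisulfite_convert_molecule(loc, c(0L, 1L), em0), "pattern length")
  # unconverted-CpH counts follow Binomial(n_CpH, f)
  f <- 0.01
  em <- error_model(conversion_failure_rate = f, substitution_rate = 0,
                    hp_indel_base_rate = 0, deletion_bias = 0)
  gch <- strsplit(loc$sequence, "", fixed = TRUE)[[1]]
  cph_pos <- setdiff(which(gch == "C"), loc$cpg_positions + 1L)
  n_cph <- length(cph_pos)
  n_mol <- 4000
  tot <- sum(vapply(seq_len(n_mol), function(i) {
    s <- bisulfite_convert_molecule(loc, rep(0L, 5), em, seed = 100 + i)
    sum(strsplit(s, "", fixed = TRUE)[[1]][cph_pos] == "C")
  }, 0))
  mu <- n_mol * n_cph * f
  expect_lt(abs(tot - mu), 3 * sqrt(n_mol * n_cph * f * (1 - f)))
})

test_that("read errors: identity at zero rates, forced homopolymer deletion, binomial substitutions", {
  em0 <- error_model(0, 0, 0, 0)
  expect_identical(apply_read_errors("ACGTACGT", em0, seed = 1), "ACGTACGT")
  # forced deletion: every homopolymer run of length >= 2 loses one base
  emd <- error_model(0, 0, hp_indel_base_rate = 1, deletion_bias = 1)
  expect_identical(apply_read_errors("AATTTTG", emd, seed = 1), "ATTTG")
  # forced insertion
  emi <- error_model(0, 0, hp_indel_base_rate = 1, deletion_bias = 0)
  expect_identical(apply_read_errors("AATTTTG", emi, seed = 1), "AAATTTTTG")
  # substitution counts ~ Binomial(n, rate)
  n <- 1000000L; rate <- 0.004
  base <- paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = "")
  ems <- error_model(0, substitution_rate = rate, hp_indel_base_rate = 0,
                     deletion_bias = 0)
  out <- apply_read_errors(base, ems, seed = 77)
  expect_identical(nchar(out), n)
  d <- sum(strsplit(base, "", fixed = TRUE)[[1]] !=
           strsplit(out, "", fixed = TRUE)[[1]])
  expect_lt(abs(d - n * rate), 3 * sqrt(n * rate * (1 - rate)))
})

test_that("simulated runs are deterministic, correctly sized, and self-consistent", {
  run <- toy_run(reads_per_bin = 10L, seed = 11)
  expect_length(run$reads, 40L)             # 2 loci x 2 samples x 10
  run2 <- toy_run(reads_per_bin = 10L, seed = 11)
  expect_identical(run$reads, run2$reads)
  d <- withr::local_tempdir()
  write_run(run, file.path(d, "a")); write_run(run2, file.path(d, "b"))
  expect_identical(unname(tools::md5sum(file.path(d, "a", "reads.fasta"))),
                   unname(tools::md5sum(file.path(d, "b", "reads.fasta"))))
  # truth levels are the column means of the emitted pattern matrix
  for (key in unique(paste(run$truth_patterns$sample,
                           run$truth_patterns$locus))) {
    tp <- run$truth_patterns[paste(run$truth_patterns$sample,
                                   run$truth_patterns$locus) == key, ]
    tl <- run$truth_levels[paste(run$truth_levels$sample,
                                 run$truth_levels$locus) == key, ]
    mat <- do.call(rbind, lapply(strsplit(tp$pattern, ""), as.integer))
    expect_equal(tl$true_level_pct, 100 * colMeans(mat))
  }
  expect_error(simulate_run(run$loci, c("S1", "S2"),
                            epiallele_model(0, 0, rep(0.5, 5)), 5L,
                            tags = c("ACGAGTGCGT", "ACGAGTGCGT")),
               "duplicate tags")
})

test_that("pyro simulation adds clipped Gaussian noise of the stated spread", {
  tl <- data.frame(sample = "S1", locus = "L1", cpg_index = 1:10000,
                   true_level_pct = rep(50, 10000))
  expect_identical(simulate_pyro(tl, 0, seed = 1)$level_pct,
                   tl$true_level_pct)
  lv <- simulate_pyro(tl, 3, seed = 2)$level_pct
  expect_lt(abs(sd(lv) - 3) / 3, 0.05)
  tl0 <- transform(tl, true_level_pct = 0)
  expect_true(all(simulate_pyro(tl0, 3, seed = 3)$level_pct >= 0))
  expect_error(simulate_pyro(tl, -1), "noise_sd")
})
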