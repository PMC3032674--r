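test_that("convert_reference labels bases by bisulfite fate", {
  loc <- locus("x", "ACGTCA", 1L, primer_len = 0L)
  cr <- convert_reference(loc)
  # A, T_from_CpG, G, T_plain, T_from_CpH, A
  expect_identical(cr$labels, c(1L, 5L, 2L, 3L, 4L, 1L))
  expect_identical(cr$ordinals, c(0L, 1L, 0L, 0L, 0L, 0L))
  expect_identical(cr$sequence, "ATGTTA")
  expect_identical(cr$n_cpg, 1L)
  # no cytosine -> no converted labels
  cr2 <- convert_reference(locus("y", "AGTTAG", integer(), 0L))
  expect_false(any(cr2$labels %in% c(4L, 5L)))
  # primer region excluded; label counts cross-check against the locus
  loc3 <- build_locus("z", 180, 6, 0.5, seed = 31)
  cr3 <- convert_reference(loc3)
  expect_identical(length(cr3$labels), nchar(loc3$sequence) - loc3$primer_len)
  expect_identical(sum(cr3$labels == 5L), length(loc3$cpg_positions))
  gch <- strsplit(loc3$sequence, "", fixed = TRUE)[[1]]
  body <- gch[-seq_len(loc3$primer_len)]
  expect_identical(sum(cr3$labels == 4L),
                   sum(body == "C") - length(loc3$cpg_positions))
})

test_that("self-alignment gives full identity, conversion, and score", {
  loc <- build_locus("L", 160, 5, 0.5, seed = 8)
  cr <- convert_reference(loc)
  unmeth <- cr$sequence                      # fully converted, unmethylated
  a <- align_read(unmeth, cr)
  expect_identical(a$identity_pct, 100)
  expect_identical(a$conversion_pct, 100)
  expect_identical(a$cpg_calls, rep("U", cr$n_cpg))
  expect_identical(a$score, as.numeric(nchar(unmeth)))
  # methylated version: C at every CpG column
  ch <- strsplit(unmeth, "", fixed = TRUE)[[1]]
  ch[cr$labels == 5L] <- "C"
  am <- align_read(paste(ch, collapse = ""), cr)
  expect_identical(am$identity_pct, 100)
  expect_identical(am$conversion_pct, 100)
  expect_identical(am$cpg_calls, rep("M", cr$n_cpg))
  expect_error(align_read("", cr), "empty read")
})

test_that("DP scores equal the independent reference scorer on random small instances", {
  set.seed(4242)
  params <- align_params()
  for (i in 1:400) {
    inst <- random_instance(10L)
    expect_identical(dp_align_score(inst$read, inst$labels, params),
                     ref_align_score(inst$read, inst$labels, params))
  }
  # and with a different scoring scheme
  p2 <- align_params(match = 2, mismatch = -3, gap_open = -4,
                     gap_extend = -2)
  for (i in 1:100) {
    inst <- random_instance(8L)
    expect_identical(dp_align_score(inst$read, inst$labels, p2),
                     ref_align_score(inst$read, inst$labels, p2))
  }
})

test_that("reference scorer agrees with complete path enumeration on tiny instances", {
  set.seed(77)
  for (i in 1:200) {
    inst <- random_instance(5L)
    expect_identical(ref_align_score(inst$read, inst$labels),
                     enum_align_score(inst$read, inst$labels))
  }
})

test_that("identity arithmetic: mismatches count, CpG columns do not", {
  # reference of ten A's, read with one G: 1 mismatch in 10 eligible
  cr <- convert_reference(locus("a", "AAAAAAAAAA", integer(), 0L))
  a <- align_read("AAAAAAAAAG", cr)
  expect_identical(a$identity_pct, 90)
  expect_identical(compute_identity(a), 90)
  # flipping a CpG call between M and U never changes identity
  loc <- build_locus("L", 150, 5, 0.5, seed = 12)
  cr2 <- convert_reference(loc)
  ch <- strsplit(cr2$sequence, "", fixed = TRUE)[[1]]
  for (i in 1:20) {
    flip <- runif(cr2$n_cpg) < 0.5
    ch2 <- ch
    ch2[which(cr2$labels == 5L)[flip]] <- "C"
    a2 <- align_read(paste(ch2, collapse = ""), cr2)
    expect_identical(a2$identity_pct, 100)
  }
})

test_that("conversion efficiency counts unconverted CpH cytosines only", {
  # 20 CpH positions, one read C among them -> 95%
  seqs <- paste(rep("CA", 20), collapse = "")          # 20 CpH cytosines
  cr <- convert_reference(locus("c", seqs, integer(), 0L))
  conv <- gsub("C", "T", seqs)
  a <- align_read(conv, cr)
  expect_identical(a$conversion_pct, 100)
  ch <- strsplit(conv, "", fixed = TRUE)[[1]]
  ch[1] <- "C"
  a1 <- align_read(paste(ch, collapse = ""), cr)
  expect_identical(a1$conversion_pct, 95)
  expect_identical(compute_conversion(a1), 95)
  # forgiven in identity (default mode), penalised in strict mode
  expect_identical(a1$identity_pct, 100)
  expect_lt(compute_identity(a1, "strict"), 100)
})

test_that("CpG calls become MISSING under deletions and foreign bases", {
  loc <- toy_locus()
  cr <- convert_reference(loc)
  body <- toy_body_unmeth()
  # delete the first CpG's column (position 1 of the body)
  del <- paste0(substr(body, 1, 0), substr(body, 2, nchar(body)))
  a <- align_read(del, cr)
  expect_identical(a$cpg_calls[1], ".")
  expect_identical(a$cpg_calls[2], "U")
  # foreign base at a CpG column
  ch <- strsplit(body, "", fixed = TRUE)[[1]]
  ch[which(cr$labels == 5L)[1]] <- "A"
  af <- align_read(paste(ch, collapse = ""), cr)
  expect_identical(af$cpg_calls[1], ".")
  expect_identical(call_cpgs(af), af$cpg_calls)
})

test_that("a single homopolymer deletion costs exactly one identity column", {
  loc <- build_locus("L", 150, 4, 0.5, seed = 19)
  cr <- convert_reference(loc)
  ch <- strsplit(cr$sequence, "", fixed = TRUE)[[1]]
  runs <- rle(ch)
  ends <- cumsum(runs$lengths)
  long <- which(runs$lengths >= 4 & runs$values %in% c("A", "T"))
  expect_gt(length(long), 0)
  cut <- ends[long[1]]                       # delete one base of the run
  read <- paste(ch[-cut], collapse = "")
  a <- align_read(read, cr)
  eligible <- sum(cr$labels != 5L)
  expect_equal(a$identity_pct, 100 * (eligible - 1) / eligible)
  base <- align_read(cr$sequence, cr)
  expect_lte(sum(a$cpg_calls != base$cpg_calls), 1L)
})

test_that("R metric functions agree with the compiled fast path", {
  run <- toy_run(reads_per_bin = 30L, seed = 5, error = error_model(
    conversion_failure_rate = 0.02, substitution_rate = 0.01,
    hp_indel_base_rate = 0.05, deletion_bias = 0.8))
  dx <- demultiplex_batch(run$reads, run$tag_table)
  crefs <- lapply(run$loci, convert_reference)
  a <- dx$assignments
  for (i in sample(nrow(a), 40)) {
    al <- align_read(a$sequence[i], crefs[[a$locus[i]]],
                     read_id = a$read_id[i])
    expect_equal(compute_identity(al), al$identity_pct)
    expect_equal(compute_conversion(al), al$conversion_pct)
    expect_identical(call_cpgs(al), al$cpg_calls)
  }
})

test_that("degenerate alignments are rejected with clear errors", {
  # all columns at CpG positions -> no eligible identity column
  fake <- fake_alignment("C", labels = 5L)
  expect_error(compute_identity(fake), "zero eligible columns")
  expect_identical(compute_conversion(fake), 100)
  expect_error(align_params(match = 1, mismatch = 2), "mismatch")
  expect_error(align_params(gap_open = 1), "gap penalties")
})
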