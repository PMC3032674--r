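# Independent reference implementations for the alignment score, used to
# cross-check the compiled dynamic program.
#
# Scoring model (shared by all implementations): alignment paths start at
# (0,0) (both 5' ends anchored) and may stop at any cell in the last row
# (read consumed) or last column (reference consumed); affine gaps cost
# gap_open + L * gap_extend; bisulfite-aware substitution contract as in
# the package.

oracle_match <- function(r, lab) {
  switch(lab,
         r == "A",                 # 1: A
         r == "G",                 # 2: G
         r == "T",                 # 3: genomic T
         r %in% c("T", "C"),       # 4: T from CpH
         r %in% c("T", "C"))       # 5: T from CpG
}

# Top-down memoized recursive scorer (pure R; independent of the
# bottom-up compiled DP). Layers: 1 = diagonal, 2 = read-vs-gap,
# 3 = gap-vs-reference.
ref_align_score <- function(read, labels, params = align_params()) {
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  m <- length(rc); n <- length(labels)
  go <- params$gap_open; ge <- params$gap_extend
  memo <- array(NA_real_, c(m + 1, n + 1, 3))
  f <- function(i, j, l) {
    v <- memo[i + 1, j + 1, l]
    if (!is.na(v)) return(v)
    v <- if (i == 0 && j == 0) {
      if (l == 1) 0 else -Inf
    } else if (l == 1) {
      if (i == 0 || j == 0) -Inf
      else max(f(i - 1, j - 1, 1), f(i - 1, j - 1, 2), f(i - 1, j - 1, 3)) +
        (if (oracle_match(rc[i], labels[j])) params$match
         else params$mismatch)
    } else if (l == 2) {
      if (i == 0) -Inf
      else max(f(i - 1, j, 1) + go + ge, f(i - 1, j, 2) + ge,
               f(i - 1, j, 3) + go + ge)
    } else {
      if (j == 0) -Inf
      else max(f(i, j - 1, 1) + go + ge, f(i, j - 1, 2) + go + ge,
               f(i, j - 1, 3) + ge)
    }
    memo[i + 1, j + 1, l] <<- v
    v
  }
  best <- -Inf
  for (j in 0:n) for (l in 1:3) best <- max(best, f(m, j, l))
  for (i in 0:m) for (l in 1:3) best <- max(best, f(i, n, l))
  best
}

# Exhaustive enumeration of every alignment path (exponential; only for
# tiny instances). Validates ref_align_score itself.
enum_align_score <- function(read, labels, params = align_params()) {
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  m <- length(rc); n <- length(labels)
  go <- params$gap_open; ge <- params$gap_extend
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i == m || j == n) best <<- max(best, sc)
    if (i < m && j < n)
      rec(i + 1, j + 1, 0L,
          sc + (if (oracle_match(rc[i + 1], labels[j + 1])) params$match
                else params$mismatch))
    if (i < m)
      rec(i + 1, j, 1L, sc + (if (last == 1L) ge else go + ge))
    if (j < n)
      rec(i, j + 1, 2L, sc + (if (last == 2L) ge else go + ge))
  }
  rec(0L, 0L, 0L, 0)
  best
}

# random alignment instance: read over ACGT, reference labels over 1..5
random_instance <- function(max_len = 10L) {
  m <- sample.int(max_len, 1L)
  n <- sample.int(max_len, 1L)
  list(read = paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = ""),
       labels = sample.int(5L, n, TRUE))
}

# package DP score for a raw (read, labels) instance
dp_align_score <- function(read, labels, params = align_params()) {
  ords <- integer(length(labels))
  ords[labels == 5L] <- seq_len(sum(labels == 5L))
  b <- deepmeth:::bs_align_batch_cpp(read, as.integer(labels), ords,
                                     sum(labels == 5L), params$match,
                                     params$mismatch, params$gap_open,
                                     params$gap_extend, FALSE)
  b$score[1]
}
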