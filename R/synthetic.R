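# Synthetic 454-style bisulfite amplicon data with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: forward-strand reads consisting of a sample tag, a
# bisulfite-converted locus-specific primer and the converted amplicon
# body; mixtures of fully methylated / fully unmethylated / heterogeneous
# epialleles; incomplete bisulfite conversion; substitution miscalls; and
# single-base indels concentrated in homopolymer runs (the dominant
# 454 error mode).

BASES <- c("A", "C", "G", "T")

#' Packaged multiplex identifier (MID) tags
#'
#' Ten mutually distinct 10-nt sample tags in the style of the public
#' 454 MID set; minimum pairwise Hamming distance 6.
#'
#' @return Character vector of 10 tags.
#' @export
mid_tags <- function() {
  c("ACGAGTGCGT", "ACGCTCGACA", "AGACGCACTC", "AGCACTGTAG", "ATCAGACACG",
    "ATATCGCGAG", "CGTGTCTCTA", "CTCGCGTGTC", "TAGTATCAGC", "TCTCTATGCG")
}

#' Sequencing / conversion error model
#'
#' @param conversion_failure_rate Per-cytosine probability that an
#'   unmethylated C survives bisulfite conversion (default 0.005).
#' @param substitution_rate Per-base miscall probability (default 0.002).
#' @param hp_indel_base_rate Per-homopolymer indel probability multiplier:
#'   a maximal run of length L >= 2 receives an indel with probability
#'   `min(1, hp_indel_base_rate * (L - 1))` (default 0.01).
#' @param deletion_bias Fraction of homopolymer indels that are deletions
#'   (default 0.8; deletions dominate 454 homopolymer errors).
#' @return An object of class `bs_error_model`.
#' @export
error_model <- function(conversion_failure_rate = 0.005,
                        substitution_rate = 0.002,
                        hp_indel_base_rate = 0.01,
                        deletion_bias = 0.8) {
  stopifnot_prob(conversion_failure_rate, "conversion_failure_rate")
  stopifnot_prob(substitution_rate, "substitution_rate")
  stopifnot_prob(hp_indel_base_rate, "hp_indel_base_rate")
  stopifnot_prob(deletion_bias, "deletion_bias")
  structure(list(conversion_failure_rate = conversion_failure_rate,
                 substitution_rate = substitution_rate,
                 hp_indel_base_rate = hp_indel_base_rate,
                 deletion_bias = deletion_bias),
            class = "bs_error_model")
}

#' Epiallele pattern mixture model
#'
#' A molecule is fully methylated with probability `p_full`, fully
#' unmethylated with probability `p_none`, and otherwise draws each CpG
#' independently from `site_probs` ("heterogeneous" epialleles).
#'
#' @param p_full Probability of a fully methylated molecule.
#' @param p_none Probability of a fully unmethylated molecule.
#' @param site_probs Per-CpG methylation probabilities for heterogeneous
#'   molecules (length = number of CpGs).
#' @return An object of class `bs_epiallele_model`.
#' @export
epiallele_model <- function(p_full, p_none, site_probs) {
  stopifnot_prob(p_full, "p_full")
  stopifnot_prob(p_none, "p_none")
  stopifnot_prob(site_probs, "site_probs")
  if (p_full + p_none > 1 + 1e-12)
    stop("p_full + p_none must be <= 1")
  structure(list(p_full = p_full, p_none = p_none,
                 site_probs = as.numeric(site_probs)),
            class = "bs_epiallele_model")
}

#' Construct a reference locus
#'
#' @param name Locus identifier.
#' @param sequence Uppercase genomic (unconverted) A/C/G/T string.
#' @param cpg_positions 0-based indices of the C of each CpG.
#' @param primer_len Number of leading bases occupied by the
#'   locus-specific forward primer.
#' @return An object of class `bs_locus`.
#' @export
locus <- function(name, sequence, cpg_positions, primer_len) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("locus sequence must be A/C/G/T")
  L <- nchar(sequence)
  cpg_positions <- as.integer(cpg_positions)
  if (is.unsorted(cpg_positions, strictly = TRUE))
    stop("cpg_positions must be strictly increasing")
  if (length(cpg_positions)) {
    if (any(cpg_positions < primer_len) || any(cpg_positions > L - 2))
      stop("cpg_positions must lie in [primer_len, length - 2]")
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    if (any(ch[cpg_positions + 1] != "C" | ch[cpg_positions + 2] != "G"))
      stop("every cpg_position must point at the C of a CpG dinucleotide")
  }
  structure(list(name = name, sequence = sequence,
                 cpg_positions = cpg_positions,
                 primer_len = as.integer(primer_len)),
            class = "bs_locus")
}

#' Build a locus from a genomic sequence by scanning for CpG sites
#'
#' All CG dinucleotides at or beyond `primer_len` are annotated as CpG
#' sites; used when loading reference FASTA files.
#'
#' @inheritParams locus
#' @return An object of class `bs_locus`.
#' @export
locus_from_sequence <- function(name, sequence, primer_len) {
  sequence <- toupper(sequence)
  pos <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1]]
  pos <- if (pos[1] == -1) integer() else as.integer(pos) - 1L
  pos <- pos[pos >= primer_len & pos <= nchar(sequence) - 2]
  locus(name, sequence, pos, primer_len)
}

#' Generate a random reference locus
#'
#' Draws a random genomic sequence at a target GC fraction, removes
#' accidental CG dinucleotides (by composition-preserving swaps), stamps
#' `n_cpg` CpG sites at random positions beyond the primer region, and
#' guarantees at least one homopolymer run of length >= 4 so that the
#' homopolymer error model is exercised.
#'
#' @param name Locus identifier.
#' @param length Amplicon length in bp (100-350).
#' @param n_cpg Number of CpG sites (>= 1).
#' @param gc_fraction Target G+C fraction.
#' @param seed Integer seed; the same seed reproduces the same locus.
#' @param primer_len Leading bases reserved for the forward primer
#'   (default 20).
#' @return An object of class `bs_locus`.
#' @export
build_locus <- function(name, length, n_cpg, gc_fraction = 0.5, seed,
                        primer_len = 20L) {
  length <- as.integer(length); n_cpg <- as.integer(n_cpg)
  primer_len <- as.integer(primer_len)
  if (n_cpg < 1) stop("n_cpg must be >= 1")
  if (length < 100 || length > 350)
    stop("amplicon length must be between 100 and 350 bp")
  if (length < primer_len + 2L * n_cpg + 2L)
    stop("impossible placement: too many CpGs for amplicon length")
  with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
           (1 - gc_fraction) / 2)
    ch <- sample(BASES, length, replace = TRUE, prob = p)
    # remove accidental CG dinucleotides; swapping CG -> GC preserves
    # composition and terminates (each swap moves a C rightward)
    repeat {
      hit <- which(ch[-length] == "C" & ch[-1] == "G")
      if (!length(hit)) break
      for (i in hit) if (ch[i] == "C" && ch[i + 1] == "G") {
        ch[i] <- "G"; ch[i + 1] <- "C"
      }
    }
    # stamp CpG sites with pairwise spacing >= 2
    navail <- (length - 1L) - primer_len          # valid 0-based starts
    y <- sort(sample.int(navail - (n_cpg - 1L), n_cpg))
    pos <- primer_len + (y - 1L) + (seq_len(n_cpg) - 1L)  # 0-based, gap >= 2
    if (any(pos > length - 2L)) stop("impossible placement: CpGs do not fit")
    ch[pos + 1] <- "C"; ch[pos + 2] <- "G"
    # guarantee one homopolymer run >= 4 (A or T: cannot create a CG)
    forbidden <- c(pos, pos + 1L)
    starts <- setdiff(primer_len:(length - 4L), unique(c(
      outer(forbidden, -3:0, `+`))))
    if (!length(starts)) stop("impossible placement: no room for homopolymer")
    s0 <- starts[sample.int(length(starts), 1L)]
    ch[(s0 + 1):(s0 + 4)] <- sample(c("A", "T"), 1)
    locus(name, paste(ch, collapse = ""), pos, primer_len)
  })
}

#' Draw single-molecule methylation patterns from a mixture model
#'
#' @param model An [epiallele_model()].
#' @param n_molecules Number of molecules (rows).
#' @param seed Integer seed (or `NULL` to draw from the current stream).
#' @return Integer matrix, `n_molecules` x `n_cpg`, entries 0/1.
#' @export
sample_epialleles <- function(model, n_molecules, seed = NULL) {
  stopifnot(inherits(model, "bs_epiallele_model"))
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  k <- length(model$site_probs)
  with_seed(seed, {
    u <- runif(n_molecules)
    mat <- matrix(0L, n_molecules, k)
    full <- u < model$p_full
    het <- u >= model$p_full + model$p_none
    mat[full, ] <- 1L
    if (any(het)) {
      nh <- sum(het)
      for (j in seq_len(k))
        mat[het, j] <- rbinom(nh, 1L, model$site_probs[j])
    }
    mat
  })
}

#' Bisulfite-convert one molecule (forward strand)
#'
#' Every genomic C at a CpG whose pattern entry is 1 stays C; every other
#' C (CpH, and unmethylated CpG) converts to T, except that with
#' probability `conversion_failure_rate` it survives as C.
#'
#' @param locus A `bs_locus`.
#' @param pattern 0/1 vector, one entry per CpG of the locus.
#' @param error_model An [error_model()].
#' @param seed Integer seed (or `NULL`).
#' @return Converted sequence string.
#' @export
bisulfite_convert_molecule <- function(locus, pattern,
                                       error_model = deepmeth::error_model(),
                                       seed = NULL) {
  stopifnot(inherits(locus, "bs_locus"))
  if (length(pattern) != length(locus$cpg_positions))
    stop("pattern length must equal the number of CpGs")
  ch <- strsplit(locus$sequence, "", fixed = TRUE)[[1]]
  keep <- locus$cpg_positions[pattern == 1] + 1L   # methylated: stays C
  cs <- setdiff(which(ch == "C"), keep)
  with_seed(seed, {
    survive <- runif(length(cs)) < error_model$conversion_failure_rate
    ch[cs[!survive]] <- "T"
    paste(ch, collapse = "")
  })
}

#' Apply 454-style sequencing errors to a read
#'
#' Per-base substitutions at `substitution_rate`, then one single-base
#' indel per maximal homopolymer run of length L >= 2 with probability
#' `min(1, hp_indel_base_rate * (L - 1))`; each indel is a deletion with
#' probability `deletion_bias`, otherwise a duplication insertion.
#'
#' @param sequence Input sequence string.
#' @param error_model An [error_model()].
#' @param seed Integer seed (or `NULL`).
#' @return Mutated sequence string.
#' @export
apply_read_errors <- function(sequence, error_model = deepmeth::error_model(),
                              seed = NULL) {
  stopifnot(inherits(error_model, "bs_error_model"))
  with_seed(seed, {
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n == 0L) return("")
    if (error_model$substitution_rate > 0) {
      hit <- which(runif(n) < error_model$substitution_rate)
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        ch[hit] <- BASES[((match(ch[hit], BASES) - 1L + shift) %% 4L) + 1L]
      }
    }
    if (error_model$hp_indel_base_rate > 0) {
      rl <- rle(ch)
      L <- rl$lengths
      elig <- L >= 2L
      if (any(elig)) {
        pr <- pmin(1, error_model$hp_indel_base_rate * (L[elig] - 1))
        ev <- runif(sum(elig)) < pr
        del <- runif(sum(elig)) < error_model$deletion_bias
        dL <- integer(length(L))
        dL[which(elig)[ev & del]] <- -1L
        dL[which(elig)[ev & !del]] <- 1L
        ch <- inverse.rle(list(lengths = L + dL, values = rl$values))
      }
    }
    paste(ch, collapse = "")
  })
}

bisulfite_primer <- function(locus) {
  gsub("C", "T", substr(locus$sequence, 1L, locus$primer_len), fixed = TRUE)
}

resolve_model <- function(models, sample_id, locus_name) {
  if (inherits(models, "bs_epiallele_model")) return(models)
  key <- paste(sample_id, locus_name, sep = "|")
  m <- models[[key]]
  if (is.null(m)) m <- models[[sample_id]]
  if (is.null(m)) stop("no epiallele model for bin ", key)
  m
}

#' Simulate a multiplexed bisulfite amplicon run
#'
#' Generates tagged reads for every sample x locus bin together with the
#' full ground truth. Each read is `tag + converted molecule + errors`;
#' sequencing and conversion errors apply downstream of the tag so the
#' true bin of every read stays defined.
#'
#' @param loci List of `bs_locus` objects.
#' @param samples Character vector of sample identifiers (max 10 with the
#'   packaged tag set).
#' @param models A single [epiallele_model()] applied to every bin, or a
#'   list keyed by `"<sample>|<locus>"` (falling back to `"<sample>"`).
#' @param reads_per_bin Integer scalar, or matrix `samples x loci`.
#' @param error_model An [error_model()].
#' @param seed Integer run seed.
#' @param tags Sample tags, one per sample (default [mid_tags()]).
#' @return An object of class `bs_run`: list with `reads` (named character
#'   vector), `tag_table`, `truth_patterns`, `truth_levels`, `bin_counts`,
#'   `loci` and `seed`.
#' @export
simulate_run <- function(loci, samples, models, reads_per_bin,
                         error_model = deepmeth::error_model(), seed = 1L,
                         tags = mid_tags()) {
  if (anyDuplicated(tags)) stop("duplicate tags in tag set")
  if (length(samples) > length(tags))
    stop("more samples than available tags")
  if (is.null(names(loci))) names(loci) <- vapply(loci, `[[`, "", "name")
  tags <- tags[seq_along(samples)]
  if (anyDuplicated(vapply(loci, `[[`, "", "name")))
    stop("duplicate locus names")

  nb <- function(si, li) {
    if (is.matrix(reads_per_bin)) reads_per_bin[si, li]
    else as.integer(reads_per_bin)
  }

  tag_table <- do.call(rbind, lapply(seq_along(samples), function(si) {
    data.frame(sample_id = samples[si],
               locus = vapply(loci, `[[`, "", "name"),
               tag = tags[si],
               primer = vapply(loci, bisulfite_primer, ""),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (anyDuplicated(paste0(tag_table$tag, tag_table$primer)))
    stop("tag+primer combinations are not pairwise distinct")

  reads <- character(); pat_rows <- list(); lev_rows <- list(); cnt <- list()
  with_seed(seed, {
    for (si in seq_along(samples)) for (li in seq_along(loci)) {
      loc <- loci[[li]]; smp <- samples[si]
      n <- nb(si, li)
      if (n < 1L) next
      model <- resolve_model(models, smp, loc$name)
      if (length(model$site_probs) != length(loc$cpg_positions))
        stop("model CpG count does not match locus ", loc$name)
      pats <- sample_epialleles(model, n)
      ids <- sprintf("%s_%s_r%05d", smp, loc$name, seq_len(n))
      body <- vapply(seq_len(n), function(i) {
        mol <- bisulfite_convert_molecule(loc, pats[i, ], error_model)
        apply_read_errors(mol, error_model)
      }, "")
      rd <- paste0(tags[si], body)
      names(rd) <- ids
      reads <- c(reads, rd)
      pat_rows[[length(pat_rows) + 1L]] <- data.frame(
        sample = smp, locus = loc$name, read_id = ids,
        pattern = apply(pats, 1, paste, collapse = ""),
        stringsAsFactors = FALSE)
      lev_rows[[length(lev_rows) + 1L]] <- data.frame(
        sample = smp, locus = loc$name,
        cpg_index = seq_len(ncol(pats)),
        true_level_pct = 100 * colMeans(pats),
        stringsAsFactors = FALSE)
      cnt[[length(cnt) + 1L]] <- data.frame(
        sample = smp, locus = loc$name, n_reads = n,
        stringsAsFactors = FALSE)
    }
  })
  structure(list(reads = reads, tag_table = tag_table,
                 truth_patterns = do.call(rbind, pat_rows),
                 truth_levels = do.call(rbind, lev_rows),
                 bin_counts = do.call(rbind, cnt),
                 loci = loci, seed = seed),
            class = "bs_run")
}

#' Simulate noisy bulk pyrosequencing measurements
#'
#' Adds Gaussian noise (SD `noise_sd` percentage points, the stated
#' technical variability range of conventional pyrosequencing is 2-10
#' points) to true per-CpG levels and clips to \[0, 100\].
#'
#' @param truth_levels Data frame with columns `sample`, `locus`,
#'   `cpg_index`, `true_level_pct` (as emitted by [simulate_run()]).
#' @param noise_sd Noise standard deviation in percentage points (>= 0).
#' @param seed Integer seed (or `NULL`).
#' @return Data frame `sample`, `locus`, `cpg_index`, `level_pct`.
#' @export
simulate_pyro <- function(truth_levels, noise_sd = 3, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(truth_levels$true_level_pct < 0 |
          truth_levels$true_level_pct > 100))
    stop("true levels must be in [0, 100]")
  with_seed(seed, {
    lv <- truth_levels$true_level_pct +
      rnorm(nrow(truth_levels), 0, noise_sd)
    data.frame(sample = truth_levels$sample, locus = truth_levels$locus,
               cpg_index = truth_levels$cpg_index,
               level_pct = clip(lv, 0, 100), stringsAsFactors = FALSE)
  })
}

#' Write a simulated run to disk
#'
#' Emits `reads.fasta`, `tags.tsv`, `truth_patterns.tsv` and
#' `truth_levels.tsv` in `dir`.
#'
#' @param run A `bs_run` from [simulate_run()].
#' @param dir Output directory (created if needed).
#' @param meta Named character vector of provenance lines for the TSVs.
#' @return Named list of file paths, invisibly.
#' @export
write_run <- function(run, dir, meta = character()) {
  stopifnot(inherits(run, "bs_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(reads = file.path(dir, "reads.fasta"),
            tags = file.path(dir, "tags.tsv"),
            patterns = file.path(dir, "truth_patterns.tsv"),
            levels = file.path(dir, "truth_levels.tsv"))
  write_fasta(run$reads, p$reads)
  write_tsv_c(run$tag_table, p$tags, meta)
  write_tsv_c(run$truth_patterns, p$patterns, meta)
  write_tsv_c(run$truth_levels, p$levels, meta)
  invisible(p)
}
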