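# Bisulfite-aware pairwise alignment against an in silico converted
# reference. The reference is converted assuming the unmethylated state
# with CpG positions labelled; methylation is read off C/T at labelled
# columns (QUMA-style). Labels:
#   1 = A, 2 = G, 3 = T (genomic T), 4 = T from CpH, 5 = T from CpG.

LAB_A <- 1L; LAB_G <- 2L; LAB_T <- 3L; LAB_CPH <- 4L; LAB_CPG <- 5L

#' Alignment scoring parameters
#'
#' Affine-gap scores: a gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1; must be below `match`).
#' @param gap_open Gap opening score (default -2; must be <= 0).
#' @param gap_extend Gap extension score (default -1; must be <= 0).
#' @return Object of class `bs_align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1) {
  if (!(gap_open <= 0 && gap_extend <= 0 && match >= 0))
    stop("gap penalties must be <= 0 <= match score")
  if (!(mismatch < match)) stop("mismatch score must be below match score")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "bs_align_params")
}

#' Convert a locus to its bisulfite-converted labelled reference
#'
#' Within the alignable region (the amplicon beyond the forward primer):
#' C at an annotated CpG becomes a `T_from_CpG` label, every other C a
#' `T_from_CpH` label, and A/G/T keep their own labels.
#'
#' @param locus A `bs_locus`.
#' @return Object of class `bs_converted_ref`: `locus_name`, `labels`
#'   (integer vector over the alignable region), `ordinals` (CpG ordinal
#'   per position, 0 elsewhere), `sequence` (converted bases), `n_cpg`,
#'   `offset` (primer length, 0-based offset of the alignable region).
#' @export
convert_reference <- function(locus) {
  stopifnot(inherits(locus, "bs_locus"))
  ch <- strsplit(locus$sequence, "", fixed = TRUE)[[1]]
  labels <- c(A = LAB_A, C = LAB_CPH, G = LAB_G, T = LAB_T)[ch]
  ords <- integer(length(ch))
  if (length(locus$cpg_positions)) {
    labels[locus$cpg_positions + 1L] <- LAB_CPG
    ords[locus$cpg_positions + 1L] <- seq_along(locus$cpg_positions)
  }
  keep <- seq.int(locus$primer_len + 1L, length(ch))
  conv <- ch[keep]
  conv[conv == "C"] <- "T"
  structure(list(locus_name = locus$name,
                 labels = unname(labels[keep]), ordinals = ords[keep],
                 sequence = paste(conv, collapse = ""),
                 n_cpg = sum(ords[keep] > 0L),
                 offset = locus$primer_len),
            class = "bs_converted_ref")
}

#' Align a trimmed read to a converted reference
#'
#' Global affine-gap alignment anchored at the 5' end (reads are tag- and
#' primer-stripped) with free trailing gaps (reads may end before the
#' amplicon does). The substitution contract is bisulfite-aware: read T
#' matches any T-derived reference label; read C additionally matches
#' CpG columns (methylated) and CpH columns (conversion failure, forgiven
#' in scoring but counted by the conversion filter). Dynamic-program ties
#' break deterministically preferring diagonal, then up, then left.
#'
#' @param trimmed_read Read sequence (non-empty).
#' @param converted_ref A `bs_converted_ref`.
#' @param params [align_params()].
#' @param read_id Identifier carried into the result.
#' @param identity_mode `"filtered"` (default: CpG columns excluded from
#'   identity and unconverted CpH forgiven) or `"strict"` (all columns
#'   count; unconverted CpH is a mismatch).
#' @return Object of class `bs_alignment`: `read_id`, `score`,
#'   `read_gapped`, `labels_gapped`, `ordinals_gapped`, `n_cpg`,
#'   `identity_pct`, `conversion_pct`, `cpg_calls` (per CpG ordinal one of
#'   `"M"`, `"U"`, `"."`).
#' @export
align_read <- function(trimmed_read, converted_ref,
                       params = align_params(), read_id = "read",
                       identity_mode = c("filtered", "strict")) {
  identity_mode <- match.arg(identity_mode)
  stopifnot(inherits(converted_ref, "bs_converted_ref"))
  if (!nchar(trimmed_read)) stop("empty read")
  b <- bs_align_batch_cpp(trimmed_read, converted_ref$labels,
                          converted_ref$ordinals, converted_ref$n_cpg,
                          params$match, params$mismatch, params$gap_open,
                          params$gap_extend, identity_mode == "strict")
  structure(list(read_id = read_id, score = b$score[1],
                 read_gapped = b$read_gapped[1],
                 labels_gapped = b$labels_gapped[[1]],
                 ordinals_gapped = b$ords_gapped[[1]],
                 n_cpg = converted_ref$n_cpg,
                 identity_pct = b$identity_pct[1],
                 conversion_pct = b$conversion_pct[1],
                 cpg_calls = strsplit(b$calls[1], "", fixed = TRUE)[[1]]),
            class = "bs_alignment")
}

#' Align all reads of one demultiplexed bin
#'
#' Batch interface used by the pipeline; metrics are computed in compiled
#' code and agree with [compute_identity()], [compute_conversion()] and
#' [call_cpgs()] applied to the gapped pairs.
#'
#' @param reads Named character vector of trimmed reads.
#' @param converted_ref A `bs_converted_ref`.
#' @param params [align_params()].
#' @param identity_mode See [align_read()].
#' @param sample,locus Bin identifiers carried into the table.
#' @return Data frame: read_id, sample, locus, score, identity_pct,
#'   conversion_pct, calls (string over `M`, `U`, `.`).
#' @export
align_bin <- function(reads, converted_ref, params = align_params(),
                      identity_mode = c("filtered", "strict"),
                      sample = NA_character_, locus = NA_character_) {
  identity_mode <- match.arg(identity_mode)
  if (!length(reads))
    return(data.frame(read_id = character(), sample = character(),
                      locus = character(), score = numeric(),
                      identity_pct = numeric(), conversion_pct = numeric(),
                      calls = character(), stringsAsFactors = FALSE))
  if (any(!nchar(reads))) stop("empty read in bin")
  b <- bs_align_batch_cpp(unname(reads), converted_ref$labels,
                          converted_ref$ordinals, converted_ref$n_cpg,
                          params$match, params$mismatch, params$gap_open,
                          params$gap_extend, identity_mode == "strict")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  data.frame(read_id = ids, sample = sample, locus = locus,
             score = b$score, identity_pct = b$identity_pct,
             conversion_pct = b$conversion_pct, calls = b$calls,
             stringsAsFactors = FALSE)
}

aln_columns <- function(alignment) {
  stopifnot(inherits(alignment, "bs_alignment"))
  list(read = strsplit(alignment$read_gapped, "", fixed = TRUE)[[1]],
       lab = alignment$labels_gapped,
       ord = alignment$ordinals_gapped)
}

r_base_matches <- function(rc, lab) {
  (lab == LAB_A & rc == "A") | (lab == LAB_G & rc == "G") |
    (lab %in% c(LAB_T, LAB_CPH, LAB_CPG) & rc == "T") |
    (lab %in% c(LAB_CPH, LAB_CPG) & rc == "C")
}

#' Percent identity of a bisulfite alignment
#'
#' Pure function of the gapped pair. In the default mode, columns at CpG
#' positions are excluded (the methylation state must not affect
#' identity) and a read C at a CpH column counts as matched (conversion
#' failure is penalised by its own filter, not here); gap columns are
#' eligible and unmatched.
#'
#' @param alignment A `bs_alignment`.
#' @param identity_mode `"filtered"` (default) or `"strict"`.
#' @return Identity percentage in \[0, 100\], at full precision.
#' @export
compute_identity <- function(alignment,
                             identity_mode = c("filtered", "strict")) {
  identity_mode <- match.arg(identity_mode)
  cc <- aln_columns(alignment)
  gap <- cc$read == "-" | cc$lab == 0L
  matched <- !gap & r_base_matches(cc$read, cc$lab)
  if (identity_mode == "strict") {
    matched[cc$lab == LAB_CPH & cc$read == "C"] <- FALSE
    eligible <- rep(TRUE, length(cc$lab))
  } else {
    eligible <- cc$lab != LAB_CPG
  }
  if (!sum(eligible)) stop("zero eligible columns")
  100 * sum(matched & eligible) / sum(eligible)
}

#' CpH conversion efficiency of a bisulfite alignment
#'
#' Fraction of CpH reference columns read as T among those read as C or
#' T; other columns (gaps, miscalls) are excluded from both counts. With
#' no countable CpH column the efficiency is 100 (no evidence of
#' failure).
#'
#' @param alignment A `bs_alignment`.
#' @return Conversion percentage in \[0, 100\].
#' @export
compute_conversion <- function(alignment) {
  cc <- aln_columns(alignment)
  cph <- cc$lab == LAB_CPH
  conv <- sum(cph & cc$read == "T")
  unconv <- sum(cph & cc$read == "C")
  if (conv + unconv == 0L) 100 else 100 * conv / (conv + unconv)
}

#' Per-CpG methylation calls from a bisulfite alignment
#'
#' @param alignment A `bs_alignment`.
#' @return Character vector over CpG ordinals: `"M"` (read C), `"U"`
#'   (read T), `"."` (gap, other base, or CpG beyond the aligned region).
#' @export
call_cpgs <- function(alignment) {
  cc <- aln_columns(alignment)
  calls <- rep(".", alignment$n_cpg)
  at <- which(cc$ord > 0L)
  for (i in at) {
    o <- cc$ord[i]
    calls[o] <- if (cc$read[i] == "C") "M"
                else if (cc$read[i] == "T") "U" else "."
  }
  calls
}
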