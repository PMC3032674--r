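# MID-tag demultiplexing: assign each read to a unique sample x locus bin
# by its 5' sample tag (exact match) and locus-specific forward primer
# (bounded mismatch, no indels).

#' Read a tag/primer table
#'
#' TSV with columns `sample_id`, `locus`, `tag`, `primer` (the dialect
#' written by [write_run()]). Tag lengths must be 9 or 10 nt and
#' tag+primer combinations pairwise distinct.
#'
#' @param path TSV path.
#' @return Data frame of tagged primer records.
#' @export
read_tag_table <- function(path) {
  if (!file.exists(path)) stop("tag table not found: ", path)
  tt <- read_tsv_c(path)
  validate_tag_table(tt)
}

validate_tag_table <- function(tt) {
  need <- c("sample_id", "locus", "tag", "primer")
  if (!all(need %in% names(tt)))
    stop("tag table must have columns: ", paste(need, collapse = ", "))
  if (!all(nchar(tt$tag) %in% c(9L, 10L)))
    stop("sample tags must be 9 or 10 nt")
  if (anyDuplicated(paste0(tt$tag, tt$primer)))
    stop("tag+primer combinations must be pairwise distinct")
  tt
}

# classify every read against every record; vectorised over reads.
# Returns an integer matrix of per-read status plus the matching record.
demux_classify <- function(reads, records, max_primer_mismatch) {
  n <- length(reads)
  nc <- nchar(reads)
  n_ok <- integer(n); ok_idx <- integer(n)
  any_tag <- logical(n); any_short <- logical(n)
  for (r in seq_len(nrow(records))) {
    tag <- records$tag[r]; primer <- records$primer[r]
    tl <- nchar(tag); pl <- nchar(primer)
    tag_hit <- substr(reads, 1L, tl) == tag & nc >= tl
    any_tag <- any_tag | tag_hit
    short <- tag_hit & nc < tl + pl
    any_short <- any_short | short
    cand <- which(tag_hit & !short)
    if (length(cand)) {
      mm <- hamming_to_pattern_cpp(substr(reads[cand], tl + 1L, tl + pl),
                                   primer)
      good <- cand[!is.na(mm) & mm <= max_primer_mismatch]
      n_ok[good] <- n_ok[good] + 1L
      ok_idx[good] <- r
    }
  }
  list(n_ok = n_ok, ok_idx = ok_idx, any_tag = any_tag,
       any_short = any_short)
}

demux_reason <- function(cl, nc) {
  ifelse(nc == 0L, "empty",
  ifelse(cl$n_ok > 1L, "ambiguous",
  ifelse(cl$any_short & !cl$n_ok, "too_short",
  ifelse(cl$any_tag, "primer_mismatch", "no_tag"))))
}

#' Match a single read against the tagged primer records
#'
#' The tag must match exactly at the read start; the primer that follows
#' may carry up to `max_primer_mismatch` substitutions (no indels).
#' Exactly one matching record assigns the read; zero or several leave it
#' unassigned with a reason.
#'
#' @param read Read sequence.
#' @param records Tag/primer table (see [read_tag_table()]).
#' @param max_primer_mismatch Allowed primer substitutions (default 2).
#' @return List with `assigned` (logical); on success `sample_id`,
#'   `locus`, `sequence` (tag+primer stripped); otherwise `reason`, one of
#'   `"empty"`, `"no_tag"`, `"too_short"`, `"primer_mismatch"`,
#'   `"ambiguous"`.
#' @export
match_read <- function(read, records, max_primer_mismatch = 2L) {
  if (!nrow(records)) stop("records must be non-empty")
  cl <- demux_classify(read, records, max_primer_mismatch)
  if (cl$n_ok == 1L) {
    r <- cl$ok_idx
    strip <- nchar(records$tag[r]) + nchar(records$primer[r])
    list(assigned = TRUE, sample_id = records$sample_id[r],
         locus = records$locus[r],
         sequence = substr(read, strip + 1L, nchar(read)))
  } else {
    list(assigned = FALSE,
         reason = demux_reason(cl, nchar(read)))
  }
}

#' Demultiplex a batch of reads
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   reads.
#' @param records Tag/primer table.
#' @param max_primer_mismatch Allowed primer substitutions (default 2).
#' @param revcomp Also try the reverse complement of unassigned reads
#'   (default `FALSE`; forward-strand data).
#' @return Object of class `bs_demux`: list with `assignments` (read_id,
#'   sample_id, locus, sequence), `unassigned` (read_id, reason), `funnel`
#'   (total_reads, assigned_reads, assigned_pct at one decimal) and
#'   `bin_counts`.
#' @export
demultiplex_batch <- function(fasta, records, max_primer_mismatch = 2L,
                              revcomp = FALSE) {
  validate_tag_table(records)
  reads <- if (is.character(fasta) && length(fasta) == 1L &&
               !grepl("^[ACGTN-]+$", fasta)) read_fasta(fasta) else fasta
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_len(n))
  if (n == 0L) {
    return(structure(list(
      assignments = data.frame(read_id = character(),
                               sample_id = character(),
                               locus = character(), sequence = character(),
                               stringsAsFactors = FALSE),
      unassigned = data.frame(read_id = character(), reason = character(),
                              stringsAsFactors = FALSE),
      funnel = list(total_reads = 0L, assigned_reads = 0L,
                    assigned_pct = 0.0),
      bin_counts = data.frame(sample_id = character(), locus = character(),
                              n_reads = integer(),
                              stringsAsFactors = FALSE)),
      class = "bs_demux"))
  }
  cl <- demux_classify(reads, records, max_primer_mismatch)
  if (revcomp) {
    miss <- which(cl$n_ok != 1L & nchar(reads) > 0L)
    if (length(miss)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(gsub("-", "N", reads[miss]))))
      cl2 <- demux_classify(rc, records, max_primer_mismatch)
      take <- cl2$n_ok == 1L
      reads[miss[take]] <- rc[take]
      cl$n_ok[miss[take]] <- 1L
      cl$ok_idx[miss[take]] <- cl2$ok_idx[take]
    }
  }
  hit <- cl$n_ok == 1L
  r <- cl$ok_idx[hit]
  strip <- nchar(records$tag[r]) + nchar(records$primer[r])
  assignments <- data.frame(
    read_id = ids[hit],
    sample_id = records$sample_id[r],
    locus = records$locus[r],
    sequence = substr(reads[hit], strip + 1L, nchar(reads[hit])),
    stringsAsFactors = FALSE, row.names = NULL)
  unassigned <- data.frame(
    read_id = ids[!hit],
    reason = demux_reason(lapply(cl, `[`, !hit), nchar(reads[!hit])),
    stringsAsFactors = FALSE, row.names = NULL)
  bin_counts <- as.data.frame(
    table(sample_id = assignments$sample_id, locus = assignments$locus),
    responseName = "n_reads", stringsAsFactors = FALSE)
  bin_counts <- bin_counts[bin_counts$n_reads > 0, , drop = FALSE]
  row.names(bin_counts) <- NULL
  structure(list(
    assignments = assignments, unassigned = unassigned,
    funnel = list(total_reads = n, assigned_reads = sum(hit),
                  assigned_pct = funnel_pct(sum(hit), n)),
    bin_counts = bin_counts),
    class = "bs_demux")
}

#' Write demultiplexing results
#'
#' Emits one FASTA per bin (`<sample>_<locus>.fasta`), a funnel TSV and an
#' unassigned-read TSV.
#'
#' @param demux A `bs_demux` from [demultiplex_batch()].
#' @param dir Output directory.
#' @param meta Provenance lines for the TSVs.
#' @return Invisibly, the output directory.
#' @export
write_demux <- function(demux, dir, meta = character()) {
  stopifnot(inherits(demux, "bs_demux"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- demux$assignments
  for (key in unique(paste(a$sample_id, a$locus, sep = "_"))) {
    sel <- paste(a$sample_id, a$locus, sep = "_") == key
    seqs <- a$sequence[sel]; names(seqs) <- a$read_id[sel]
    write_fasta(seqs, file.path(dir, paste0(key, ".fasta")))
  }
  fdf <- data.frame(total_reads = demux$funnel$total_reads,
                    assigned_reads = demux$funnel$assigned_reads,
                    assigned_pct = demux$funnel$assigned_pct)
  write_tsv_c(fdf, file.path(dir, "demux_funnel.tsv"), meta)
  write_tsv_c(demux$unassigned, file.path(dir, "unassigned.tsv"), meta)
  invisible(dir)
}
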