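# Shared helpers: seeded evaluation, funnel percentages, TSV/FASTA I/O.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from the run seed
#'
#' All pipeline randomness flows from one run seed; each stage uses a
#' deterministic offset so stages can be re-run independently and still
#' reproduce a full-pipeline run.
#'
#' @param seed Integer run seed.
#' @param stage Small integer stage index.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 9973 * as.numeric(stage)) %% 2147483587)
}

#' Funnel percentage at one decimal
#'
#' Percentage of `count` out of `total`, truncated (not rounded) to one
#' decimal place -- the convention used throughout the read-funnel and
#' congruence reports (e.g. 720/869 reads as 82.8). An empty total gives
#' 0.0 by convention.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @return Numeric percentage with one decimal.
#' @examples
#' funnel_pct(50118, 59366)  # 84.4
#' funnel_pct(720, 869)      # 82.8
#' @export
funnel_pct <- function(count, total) {
  if (length(total) == 1L && total == 0) return(0.0)
  out <- trunc(1000 * count / total + 1e-9) / 10
  ifelse(total == 0, 0.0, out)
}

#' Write a data frame as TSV with a provenance comment header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named character vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_c <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "N/A")
  invisible(path)
}

#' Read a TSV written by [write_tsv_c()]
#'
#' @param path Input path.
#' @return Data frame (comment lines beginning `#` are skipped; `N/A`
#'   cells become `NA`).
#' @export
read_tsv_c <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, comment.char = "#", na.strings = "N/A",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a FASTA file of reads
#'
#' Multi-line sequences and CRLF line endings are handled; each record is
#' validated against the DNA alphabet (ACGTN, case-insensitive, gaps
#' allowed) and a malformed record is reported by name.
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e)))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("malformed FASTA record '", names(seqs)[which(bad)[1]],
         "': non-DNA characters")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# clip numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must be in [0, 1]")
  invisible(x)
}
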