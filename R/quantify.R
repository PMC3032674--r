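# QC filtering and per-CpG / per-molecule methylation quantification.

#' Quality-filter configuration
#'
#' Defaults follow the standard stringent amplicon bisulfite criteria:
#' reads below 90% alignment identity or below 100% CpH conversion are
#' discarded, and bins with fewer than `min_reads_per_bin` passing reads
#' are flagged `low_coverage` (excluded from cross-method comparison).
#' 100-150 reads per amplicon are recommended for stable quantification.
#'
#' @param min_identity_pct Minimum alignment identity (default 90).
#' @param min_conversion_pct Minimum CpH conversion (default 100).
#' @param min_reads_per_bin Minimum passing reads per bin (default 10).
#' @param recommended_reads Informational recommended coverage range.
#' @return Object of class `bs_filter_config`.
#' @export
filter_config <- function(min_identity_pct = 90, min_conversion_pct = 100,
                          min_reads_per_bin = 10L,
                          recommended_reads = c(100L, 150L)) {
  if (min_identity_pct < 0 || min_identity_pct > 100 ||
      min_conversion_pct < 0 || min_conversion_pct > 100)
    stop("thresholds must lie in [0, 100]")
  structure(list(min_identity_pct = min_identity_pct,
                 min_conversion_pct = min_conversion_pct,
                 min_reads_per_bin = as.integer(min_reads_per_bin),
                 recommended_reads = recommended_reads),
            class = "bs_filter_config")
}

#' Filter alignments by identity and conversion thresholds
#'
#' A read passes iff `identity_pct >= min_identity_pct` and
#' `conversion_pct >= min_conversion_pct` (thresholds compared before any
#' rounding; identity exactly at the threshold passes).
#'
#' @param alignments Data frame from [align_bin()] (or rbind thereof).
#' @param config [filter_config()].
#' @return List: `passing` (data frame), `rejected` (data frame with
#'   `reason`, `"identity"` or `"conversion"`), `funnel`
#'   (`total`, `passing`, `passing_pct` at one decimal).
#' @export
filter_alignments <- function(alignments, config = filter_config()) {
  ok_id <- alignments$identity_pct >= config$min_identity_pct
  ok_cv <- alignments$conversion_pct >= config$min_conversion_pct
  pass <- ok_id & ok_cv
  rejected <- alignments[!pass, , drop = FALSE]
  rejected$reason <- ifelse(!ok_id[!pass], "identity", "conversion")
  row.names(rejected) <- NULL
  passing <- alignments[pass, , drop = FALSE]
  row.names(passing) <- NULL
  list(passing = passing, rejected = rejected,
       funnel = list(total = nrow(alignments), passing = sum(pass),
                     passing_pct = funnel_pct(sum(pass),
                                              nrow(alignments))))
}

#' Call strings to an epiallele matrix
#'
#' @param calls Character vector of per-read call strings over
#'   `M`/`U`/`.`.
#' @return Integer matrix (rows = reads, columns = CpG ordinals) with
#'   entries 1 (methylated), 0 (unmethylated), `NA` (missing).
#' @export
calls_to_matrix <- function(calls) {
  if (!length(calls)) return(matrix(integer(), 0, 0))
  ch <- strsplit(calls, "", fixed = TRUE)
  k <- unique(lengths(ch))
  if (length(k) != 1L) stop("call strings of unequal length")
  m <- matrix(unlist(ch), ncol = k, byrow = TRUE)
  out <- matrix(NA_integer_, nrow(m), k)
  out[m == "M"] <- 1L
  out[m == "U"] <- 0L
  rownames(out) <- names(calls)
  out
}

#' Per-CpG methylation levels for one bin
#'
#' The level at a CpG is `100 * n_meth / (n_meth + n_unmeth)`; missing
#' calls (gaps) carry no information and are excluded from both counts.
#' The per-bin mean is the unweighted mean over CpGs with coverage.
#'
#' @param calls Per-read call strings (passing reads of one bin), or an
#'   epiallele matrix from [calls_to_matrix()].
#' @param sample,locus Bin identifiers.
#' @param config [filter_config()] (supplies `min_reads_per_bin`).
#' @return Object of class `bs_profile`: `sample`, `locus`, `per_cpg`
#'   data frame (cpg_index, n_meth, n_unmeth, coverage, level_pct),
#'   `mean_level_pct`, `n_reads_passing`, `low_coverage` flag, `matrix`.
#' @export
methylation_levels <- function(calls, sample = NA_character_,
                               locus = NA_character_,
                               config = filter_config()) {
  mat <- if (is.matrix(calls)) calls else calls_to_matrix(calls)
  n <- nrow(mat); k <- ncol(mat)
  if (n == 0L || k == 0L) {
    return(structure(list(sample = sample, locus = locus,
                          per_cpg = data.frame(cpg_index = integer(),
                                               n_meth = integer(),
                                               n_unmeth = integer(),
                                               coverage = integer(),
                                               level_pct = numeric()),
                          mean_level_pct = NA_real_, n_reads_passing = n,
                          low_coverage = TRUE, matrix = mat),
                     class = "bs_profile"))
  }
  n_meth <- colSums(mat == 1L, na.rm = TRUE)
  n_unmeth <- colSums(mat == 0L, na.rm = TRUE)
  coverage <- n_meth + n_unmeth
  level <- ifelse(coverage > 0, 100 * n_meth / coverage, NA_real_)
  structure(list(
    sample = sample, locus = locus,
    per_cpg = data.frame(cpg_index = seq_len(k), n_meth = n_meth,
                         n_unmeth = n_unmeth, coverage = coverage,
                         level_pct = level, row.names = NULL),
    mean_level_pct = if (any(coverage > 0)) mean(level[coverage > 0])
                     else NA_real_,
    n_reads_passing = n,
    low_coverage = n < config$min_reads_per_bin,
    matrix = mat), class = "bs_profile")
}

#' Single-molecule epiallele summary
#'
#' A read counts as fully methylated iff all its non-missing calls are
#' methylated and at least `min_called_sites` sites are called (default:
#' every site, so short/gapped reads cannot inflate the fraction);
#' analogously for fully unmethylated. Pattern counts are keyed by the
#' call string (`.` = missing).
#'
#' @param mat Epiallele matrix ([calls_to_matrix()]) or call strings.
#' @param min_called_sites Minimum non-missing calls for the full-pattern
#'   fractions (default: number of CpGs).
#' @return List: `n_reads`, `full_meth_pct`, `full_unmeth_pct`,
#'   `n_patterns`, `pattern_counts` (named integer vector, decreasing).
#' @export
epiallele_summary <- function(mat, min_called_sites = NULL) {
  if (!is.matrix(mat)) mat <- calls_to_matrix(mat)
  if (!nrow(mat)) stop("epiallele matrix is empty")
  k <- ncol(mat)
  if (is.null(min_called_sites)) min_called_sites <- k
  called <- rowSums(!is.na(mat))
  meth <- rowSums(mat == 1L, na.rm = TRUE)
  full_m <- called >= min_called_sites & meth == called & called > 0
  full_u <- called >= min_called_sites & meth == 0L & called > 0
  pat <- apply(mat, 1, function(r)
    paste(ifelse(is.na(r), ".", r), collapse = ""))
  tab <- sort(table(pat), decreasing = TRUE)
  counts <- as.integer(tab); names(counts) <- names(tab)
  list(n_reads = nrow(mat),
       full_meth_pct = 100 * sum(full_m) / nrow(mat),
       full_unmeth_pct = 100 * sum(full_u) / nrow(mat),
       n_patterns = length(counts),
       pattern_counts = counts)
}

#' Combine bin profiles into a per-CpG table
#'
#' @param profiles List of `bs_profile` objects.
#' @return Data frame: sample, locus, cpg_index, n_meth, n_unmeth,
#'   coverage, level_pct, low_coverage.
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    if (!nrow(p$per_cpg)) return(NULL)
    cbind(data.frame(sample = p$sample, locus = p$locus,
                     stringsAsFactors = FALSE),
          p$per_cpg,
          data.frame(low_coverage = p$low_coverage))
  }))
}

#' Render the locus x sample mean-methylation matrix
#'
#' Mean levels rounded to whole percent (`"10%"`); bins that are absent
#' or flagged low-coverage render as `"N/A"`.
#'
#' @param profiles List of `bs_profile` objects.
#' @param loci,samples Optional universe (defaults to those observed).
#' @return Character matrix, rows = loci, columns = samples.
#' @export
render_profile_table <- function(profiles, loci = NULL, samples = NULL) {
  ls <- vapply(profiles, function(p) p$locus, "")
  ss <- vapply(profiles, function(p) p$sample, "")
  if (is.null(loci)) loci <- unique(ls)
  if (is.null(samples)) samples <- unique(ss)
  out <- matrix("N/A", length(loci), length(samples),
                dimnames = list(loci, samples))
  for (p in profiles) {
    if (p$low_coverage || is.na(p$mean_level_pct)) next
    out[p$locus, p$sample] <- sprintf("%d%%", round(p$mean_level_pct))
  }
  out
}
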