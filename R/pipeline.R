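# End-to-end pipeline: simulate (or load) -> demultiplex -> align ->
# filter/quantify -> cross-method concordance, with a reproducible output
# bundle. All randomness flows from the single run seed through
# derive_seed(); every TSV/JSON output carries version, config hash and
# seed (FASTA is left comment-free, as comment lines are not portable;
# its provenance lives in the run manifest).

STAGE_SIM <- 2L; STAGE_PYRO <- 3L; STAGE_MODELS <- 4L; STAGE_LOCI <- 10L

#' Pipeline configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param mode `"simulate"` (generate reads with ground truth) or
#'   `"files"` (read FASTA/TSV inputs from `paths`).
#' @param seed Integer run seed.
#' @param n_samples,n_loci Study size (simulate mode).
#' @param locus_lengths Amplicon lengths in bp, recycled over loci
#'   (default spreads 140-280 bp, inside the 454 amplicon range).
#' @param n_cpg CpGs per locus (default 7, a typical amplicon CpG count).
#' @param gc_fraction Target locus GC fraction.
#' @param reads_per_bin Reads per sample x locus bin: scalar, per-locus
#'   vector, or samples x loci matrix.
#' @param noise_sd Bulk pyrosequencing noise SD in percentage points.
#' @param error [error_model()].
#' @param models Epiallele models (see [simulate_run()]); `NULL` draws a
#'   random mixture per bin from the run seed.
#' @param filter [filter_config()].
#' @param align [align_params()].
#' @param identity_mode Identity denominator switch (see [align_read()]).
#' @param max_primer_mismatch Demultiplexing primer tolerance.
#' @param through_origin Regression mode.
#' @param ba_method Bland-Altman band type.
#' @param paths Named list for `"files"` mode: `reads`, `tags`, `refs`,
#'   optionally `bulk`.
#' @return Object of class `bs_config`.
#' @export
pipeline_config <- function(out_dir, mode = c("simulate", "files"),
                            seed = 1L, n_samples = 4L, n_loci = 4L,
                            locus_lengths = NULL, n_cpg = 7L,
                            gc_fraction = 0.5, reads_per_bin = 150L,
                            noise_sd = 3, error = error_model(),
                            models = NULL, filter = filter_config(),
                            align = align_params(),
                            identity_mode = "filtered",
                            max_primer_mismatch = 2L,
                            through_origin = FALSE, ba_method = "loa",
                            paths = list()) {
  mode <- match.arg(mode)
  if (is.null(locus_lengths))
    locus_lengths <- as.integer(round(seq(140, 280,
                                          length.out = max(n_loci, 2L))))
  structure(list(out_dir = out_dir, mode = mode, seed = as.integer(seed),
                 n_samples = as.integer(n_samples),
                 n_loci = as.integer(n_loci),
                 locus_lengths = locus_lengths, n_cpg = as.integer(n_cpg),
                 gc_fraction = gc_fraction, reads_per_bin = reads_per_bin,
                 noise_sd = noise_sd, error = error, models = models,
                 filter = filter, align = align,
                 identity_mode = identity_mode,
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 through_origin = through_origin, ba_method = ba_method,
                 paths = paths),
            class = "bs_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' nested `error`, `filter` and `align` blocks onto [error_model()],
#' [filter_config()] and [align_params()]. Explicit `...` overrides take
#' precedence over the file.
#'
#' @param path YAML path.
#' @param ... Overrides passed to [pipeline_config()].
#' @return Object of class `bs_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("error", "filter", "align"))]
  if (!is.null(y$error)) args$error <- do.call(error_model, y$error)
  if (!is.null(y$filter)) args$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$align)) args$align <- do.call(align_params, y$align)
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

random_bin_models <- function(samples, loci, n_cpg, seed) {
  with_seed(seed, {
    out <- list()
    for (s in samples) for (l in loci) {
      p_full <- runif(1, 0, 0.25)
      p_none <- runif(1, 0, 0.45)
      out[[paste(s, l, sep = "|")]] <-
        epiallele_model(p_full, p_none, runif(n_cpg))
    }
    out
  })
}

reads_matrix <- function(reads_per_bin, n_samples, n_loci) {
  if (is.matrix(reads_per_bin)) return(reads_per_bin)
  if (length(reads_per_bin) == n_loci && n_loci > 1L)
    return(matrix(as.integer(reads_per_bin), n_samples, n_loci,
                  byrow = TRUE))
  matrix(as.integer(reads_per_bin), n_samples, n_loci)
}

#' Run the full analysis pipeline
#'
#' Produces the complete report bundle in `config$out_dir`: the read
#' funnel (raw -> assigned -> passing, counts and one-decimal
#' percentages), per-read alignment metrics, per-CpG levels, epiallele
#' pattern counts, the locus x sample mean-level matrix, concordance
#' statistics against the bulk table, plot-ready tables, and a run
#' manifest (version + config hash + seed). Stage failures are logged
#' and reported through a nonzero status; partial outputs are preserved.
#'
#' @param config A `bs_config` from [pipeline_config()].
#' @return List: `status` (0 on success), `out_dir`, and on success
#'   `funnel`, `report`, `profiles`, `paths`; on failure `error`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bs_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch(run_pipeline_impl(config), error = function(e) {
    message("pipeline failed: ", conditionMessage(e))
    list(status = 1L, out_dir = config$out_dir,
         error = conditionMessage(e))
  })
  res
}

run_pipeline_impl <- function(config) {
  out <- config$out_dir
  meta <- c(tool = paste0("deepmeth ", packageVersion("deepmeth")),
            config_hash = config_hash(config),
            seed = as.character(config$seed),
            diff_sign = "deep_minus_bulk")

  if (config$mode == "simulate") {
    samples <- sprintf("S%02d", seq_len(config$n_samples))
    lens <- rep_len(config$locus_lengths, config$n_loci)
    loci <- lapply(seq_len(config$n_loci), function(i)
      build_locus(sprintf("L%02d", i), lens[i], config$n_cpg,
                  config$gc_fraction,
                  seed = derive_seed(config$seed, STAGE_LOCI + i)))
    names(loci) <- vapply(loci, `[[`, "", "name")
    models <- config$models
    if (is.null(models))
      models <- random_bin_models(samples, names(loci), config$n_cpg,
                                  derive_seed(config$seed, STAGE_MODELS))
    rpb <- reads_matrix(config$reads_per_bin, length(samples),
                        length(loci))
    run <- simulate_run(loci, samples, models, rpb, config$error,
                        seed = derive_seed(config$seed, STAGE_SIM))
    write_run(run, out, meta)
    bulk <- simulate_pyro(run$truth_levels, config$noise_sd,
                          seed = derive_seed(config$seed, STAGE_PYRO))
    write_tsv_c(bulk, file.path(out, "pyro.tsv"), meta)
    reads <- run$reads
    records <- run$tag_table
    truth <- run$truth_levels
  } else {
    p <- config$paths
    if (is.null(p$tags) || !file.exists(p$tags))
      stop("tag table not found: ",
           if (is.null(p$tags)) "(no path given)" else p$tags)
    records <- read_tag_table(p$tags)
    if (is.null(p$reads) || !file.exists(p$reads))
      stop("reads FASTA not found: ",
           if (is.null(p$reads)) "(no path given)" else p$reads)
    reads <- read_fasta(p$reads)
    if (is.null(p$refs) || !file.exists(p$refs))
      stop("reference FASTA not found: ",
           if (is.null(p$refs)) "(no path given)" else p$refs)
    refseqs <- read_fasta(p$refs)
    plen <- nchar(records$primer)[match(names(refseqs), records$locus)]
    if (anyNA(plen))
      stop("reference loci missing from tag table: ",
           paste(names(refseqs)[is.na(plen)], collapse = ", "))
    loci <- lapply(seq_along(refseqs), function(i)
      locus_from_sequence(names(refseqs)[i], refseqs[[i]], plen[i]))
    names(loci) <- names(refseqs)
    bulk <- if (!is.null(p$bulk)) read_tsv_c(p$bulk) else NULL
    truth <- NULL
  }

  message(sprintf("[demux] %d raw reads", length(reads)))
  demux <- demultiplex_batch(reads, records,
                             max_primer_mismatch =
                               config$max_primer_mismatch)
  message(sprintf("[demux] %d assigned (%s%%)",
                  demux$funnel$assigned_reads,
                  demux$funnel$assigned_pct))
  write_tsv_c(demux$bin_counts, file.path(out, "bin_counts.tsv"), meta)
  write_tsv_c(demux$unassigned, file.path(out, "unassigned.tsv"), meta)

  crefs <- lapply(loci, convert_reference)
  a <- demux$assignments
  aln <- do.call(rbind, lapply(split(a, paste(a$sample_id, a$locus)),
    function(bin) {
      seqs <- bin$sequence
      names(seqs) <- bin$read_id
      align_bin(seqs, crefs[[bin$locus[1]]], config$align,
                identity_mode = config$identity_mode,
                sample = bin$sample_id[1], locus = bin$locus[1])
    }))
  row.names(aln) <- NULL
  write_tsv_c(aln, file.path(out, "alignments.tsv"), meta)

  flt <- filter_alignments(aln, config$filter)
  message(sprintf("[filter] %d of %d aligned reads pass QC",
                  flt$funnel$passing, flt$funnel$total))
  write_tsv_c(flt$rejected[, c("read_id", "sample", "locus", "reason")],
              file.path(out, "rejected.tsv"), meta)

  keys <- split(flt$passing, list(flt$passing$sample, flt$passing$locus),
                drop = TRUE)
  profiles <- lapply(keys, function(bin) {
    calls <- bin$calls
    names(calls) <- bin$read_id
    methylation_levels(calls, sample = bin$sample[1],
                       locus = bin$locus[1], config = config$filter)
  })
  percpg <- profile_table(profiles)
  write_tsv_c(percpg, file.path(out, "percpg.tsv"), meta)

  epi <- do.call(rbind, lapply(profiles, function(p) {
    if (!p$n_reads_passing) return(NULL)
    es <- epiallele_summary(p$matrix)
    data.frame(sample = p$sample, locus = p$locus,
               pattern = names(es$pattern_counts),
               count = es$pattern_counts,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(epi))
    epi <- data.frame(sample = character(), locus = character(),
                      pattern = character(), count = integer())
  write_tsv_c(epi, file.path(out, "epialleles.tsv"), meta)

  pm <- render_profile_table(profiles, loci = names(loci),
                             samples = sort(unique(percpg$sample)))
  write_tsv_c(data.frame(locus = rownames(pm), pm, check.names = FALSE),
              file.path(out, "profile_matrix.tsv"), meta)

  funnel <- list(total_reads = demux$funnel$total_reads,
                 assigned_reads = demux$funnel$assigned_reads,
                 assigned_pct = demux$funnel$assigned_pct,
                 passing_reads = flt$funnel$passing,
                 passing_pct = funnel_pct(flt$funnel$passing,
                                          demux$funnel$total_reads))
  jsonlite::write_json(c(list(tool = unname(meta["tool"]),
                              config_hash = unname(meta["config_hash"]),
                              seed = config$seed), funnel),
                       file.path(out, "funnel.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # per-amplicon yield (passing reads) vs length
  pass_bins <- vapply(profiles, function(p) p$n_reads_passing, 0L)
  bin_locus <- vapply(profiles, function(p) p$locus, "")
  yield <- data.frame(
    locus = names(loci),
    length = vapply(loci, function(l) nchar(l$sequence), 0L),
    mean_reads = vapply(names(loci), function(l) {
      v <- pass_bins[bin_locus == l]
      if (length(v)) mean(v) else 0
    }, 0), row.names = NULL, stringsAsFactors = FALSE)
  write_tsv_c(yield, file.path(out, "yield.tsv"), meta)
  yield_r <- tryCatch(correlate_yield(yield)$r, error = function(e)
    NA_real_)

  report <- NULL
  if (!is.null(bulk)) {
    pairs <- pair_measurements(percpg, bulk)
    write_tsv_c(pairs, file.path(out, "pairs.tsv"), meta)
    report <- concordance_report(pairs,
                                 through_origin = config$through_origin,
                                 ba_method = config$ba_method)
    report$yield_length_r <- yield_r
    ba <- bland_altman(pairs, method = config$ba_method)
    write_tsv_c(cbind(pairs[c("sample", "locus", "cpg_index")],
                      ba$table),
                file.path(out, "bland_altman.tsv"), meta)
    cov <- coverage_vs_congruence(pairs)
    write_tsv_c(cov$table, file.path(out, "coverage_congruence.tsv"),
                meta)
    gm <- stats::aggregate(cbind(level_deep, level_bulk) ~
                             sample + locus, data = pairs, FUN = mean)
    write_tsv_c(gm, file.path(out, "gene_means.tsv"), meta)
    rep_json <- report
    rep_json$congruence <- as.list(report$congruence)
    jsonlite::write_json(c(list(tool = unname(meta["tool"]),
                                config_hash = unname(meta["config_hash"]),
                                seed = config$seed,
                                diff_sign = "deep_minus_bulk"), rep_json),
                         file.path(out, "concordance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    message(sprintf("[compare] %d pairs, r2 = %.3f", report$n_pairs,
                    report$regression$r2))
  }

  manifest <- list(tool = "deepmeth",
                   version = as.character(packageVersion("deepmeth")),
                   config_hash = unname(meta["config_hash"]),
                   seed = config$seed, mode = config$mode,
                   n_raw_reads = length(reads))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(status = 0L, out_dir = out, funnel = funnel, report = report,
       profiles = profiles, percpg = percpg, demux = demux,
       alignments = aln, truth = truth, yield = yield,
       yield_length_r = yield_r)
}
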