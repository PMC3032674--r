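---
title: "Methods: deep bisulfite amplicon methylation analysis in deepmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep bisulfite amplicon methylation analysis in deepmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`deepmeth` analyses multiplexed amplicon bisulfite sequencing of the
454/pyrosequencing era: forward-strand FASTA reads, each consisting of a
9–10 nt sample tag (MID), a locus-specific forward primer, and the
bisulfite-converted amplicon body. The quantity of interest is the
methylation level of each CpG dinucleotide in each sample — the fraction
of sequenced molecules carrying an unconverted (methylated) cytosine at
that position — together with the single-molecule epiallele patterns
that a bulk assay cannot resolve.

The statistical model underlying every validation in the package is
simple and explicit: a molecule's CpG pattern is drawn from a three-part
mixture (fully methylated with probability $p_{full}$, fully
unmethylated with $p_{none}$, otherwise per-site independent Bernoulli
draws); sequencing observes each molecule once; a site's recovered level
is a binomial proportion of its covered reads. Everything downstream —
coverage recommendations, congruence bands, sensitivity to rare fully
methylated alleles — follows from binomial sampling plus the error
processes described below.

## The pipeline stages

**Demultiplexing.** The sample tag must match exactly at the read start
(tags in the packaged set are 10-mers with pairwise Hamming distance 6,
so a tag corrupted by sequencing error is far more likely to match
nothing than to match the wrong sample). The primer that follows may
carry up to 2 substitutions (`max_primer_mismatch`, no indels); the
tolerance is a repository decision — short designed primers diverge by
far more than 2 mismatches across loci, so the rule rescues lightly
damaged reads without risking cross-assignment. A read matching zero
records is reported as `no_tag`, `too_short` or `primer_mismatch`;
matching more than one record, `ambiguous`. Reads are never assigned to
two bins, and demultiplexing is order-independent.

**Reference conversion.** Each locus is converted *in silico* assuming
the fully unmethylated state, with every position labelled by its
bisulfite fate: A, G, genomic T, T-from-CpH, or T-from-CpG. The primer
region is excluded from the alignable reference (reads are tag- and
primer-stripped before alignment, so the 5′ end is anchored).

**Alignment.** A global affine-gap dynamic program (Rcpp) anchored at
the 5′ end with free trailing gaps — reads may legitimately end before
the amplicon does, and vice versa. The substitution contract is
bisulfite-aware: read T matches any T-derived label; read C additionally
matches T-from-CpG (methylated) and T-from-CpH (conversion failure —
*forgiven in scoring* so that a poorly converted read still aligns
correctly, and penalised instead by the dedicated conversion filter).
Default scores are match +1, mismatch −1, gap open −2, gap extend −1
(a gap of length $L$ costs $open + L\cdot extend$); no scoring scheme is
inherited from prior tools, so these conventional values are exposed in
`align_params()`. Dynamic-program ties break deterministically
(diagonal, then up, then left), which makes whole-pipeline runs
byte-reproducible. The compiled scorer is validated against an
independent pure-R reference scorer on thousands of random small
instances, and that reference in turn against complete enumeration of
all alignment paths on tiny instances.

**Identity and conversion.** From the gapped pair alone:

- identity = matched / eligible columns, where columns at CpG positions
  are excluded (the methylation state must not affect identity) and a
  read C at CpH counts as matched; gap columns are eligible and
  unmatched. How the original web tools counted these columns is not
  documented, so the stricter reading (every column counts, unconverted
  CpH is a mismatch) is available behind `identity_mode = "strict"`.
- conversion = CpH columns read as T / CpH columns read as C or T. A
  read with no countable CpH column has conversion 100 by decision — it
  offers no evidence of failure; with the default 100 % threshold any
  other convention would discard such reads for a reason they cannot
  exhibit.

**Filtering.** A read passes iff identity ≥ 90 and conversion ≥ 100
(percentages carried at full precision; thresholds compared before any
rounding, so identity exactly 90.0 passes). Bins with fewer than
`min_reads_per_bin = 10` passing reads are flagged `low_coverage` and
excluded from cross-method comparison; 100–150 reads per amplicon is the
informational recommendation for stable per-CpG quantification (a
binomial 95 % interval at level 50 % and n = 150 is about ±8 points).

**Quantification.** Missing calls (gaps, foreign bases, CpGs beyond the
aligned region) are excluded from both numerator and denominator — a
read with a gap at a site carries no information there. The per-bin
mean level is the unweighted mean over CpGs with coverage: each CpG is
one biological position regardless of its read depth. A molecule counts
as fully methylated only when *every* site is called and methylated
(`min_called_sites` defaults to all sites), so short or gapped reads
cannot inflate the rare-epiallele fraction; the requirement is
relaxable. Rendered mean-level matrices round to whole percent and show
`N/A` for absent or low-coverage bins.

**Concordance.** Differences are always deep − bulk (stated in output
headers). The 95 % band defaults to Bland–Altman limits of agreement,
mean ± 1.96 SD; since "95 % tolerance interval" is ambiguous
terminology in method-comparison reports, a strict 95 %/95 % normal
tolerance interval (Howe's k-factor) is available behind
`ba_method = "tolerance"`. Regression includes an intercept by default
with a through-origin option, because published slope/r² pairs rarely
state which was fitted. Congruence fractions use strict inequality
(|Δ| < t for t = 2, 5, 10 points). The coverage threshold is the
smallest observed coverage c such that every pair with coverage ≥ c
lies inside the overall band; it is reported as undefined when the
highest-coverage pair is itself outside. No multiple-testing correction
is applied anywhere: these are descriptive agreement statistics, not a
family of hypothesis tests.

**Percentages in reports.** Funnel and congruence percentages are
truncated (not rounded) to one decimal; this matches the arithmetic
convention of the published read-funnel figures the report format
imitates (e.g. 720/869 prints as 82.8).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with all randomness flowing from one seed:

- **Loci** — random sequences of 100–350 bp at a target GC fraction,
  with `n_cpg` annotated CpG sites (no accidental CpGs are left in the
  sequence, so truth is unambiguous), a reserved forward-primer region
  (default 20 bp), and a guaranteed homopolymer run of length ≥ 4 so
  the homopolymer error model is always exercised. Default study shape
  in the pipeline: 7 CpGs per locus, amplicon lengths spread over
  140–280 bp (12-locus panels in this assay class average ~7 CpGs per
  amplicon and reads of ~210 bp).
- **Epialleles** — the $p_{full}/p_{none}$/heterogeneous mixture above.
  True per-locus epiallele distributions in clinical samples are
  unknown; these are free knobs, not estimates, and pipeline defaults
  draw a different mixture per bin from the run seed.
- **Conversion** — methylated CpG cytosines survive; every other C
  converts to T except with probability `conversion_failure_rate`
  (default 0.005 per cytosine).
- **Sequencing error** — per-base substitutions
  (`substitution_rate = 0.002`) and one single-base indel per
  homopolymer run of length L ≥ 2 with probability
  `min(1, 0.01·(L−1))`, 80 % of them deletions. The defaults reproduce
  the qualitative 454 error spectrum — deletions in homopolymers
  dominant, occasional partial conversion, overall per-base accuracy
  near 99.6 % — and are all configurable.
- **Bulk pyrosequencing** — truth plus Gaussian noise (default SD 3
  percentage points, inside the 2–10 point technical variability quoted
  for the assay), clipped to [0, 100].

Deliberate simplifications: reads span the full amplicon (no truncation
model — the QC filters act on identity and conversion, not length);
errors apply downstream of the sample tag so each read's true bin stays
defined for accuracy tests; forward strand only; no flowgram signal
model, no quality scores, no emulsion-PCR amplification bias beyond the
per-bin read-count parameter. Consequently, passing tests demonstrate
correctness of the *analysis* under binomial sampling with realistic
error rates — they do not certify behaviour under pathologies the
generator does not produce (chimeric reads, severe 3′ quality decay,
bisulfite degradation bias).

## Numerical and degenerate-input conventions

- Coordinates are 0-based internally (`cpg_positions`); output tables
  key CpGs by 1-based within-amplicon ordinal `cpg_index`.
- An empty demultiplexing batch has `assigned_pct = 0.0` by convention;
  an empty bin yields a flagged empty profile, not an exception.
- A site with zero coverage has undefined level (`NA`, rendered `N/A`).
- Degenerate statistics error loudly: fewer than 3 pairs
  (Bland–Altman/regression), zero variance (regression, Pearson),
  zero eligible identity columns.
- Per-stage seeds derive deterministically from the run seed, so a
  stage re-run in isolation reproduces its slice of a full run, and two
  runs with the same configuration and seed are byte-identical
  (FASTA outputs carry no comment header — comments are not portable
  FASTA — so their provenance lives in the run manifest).

## Validation problem sizes

The test suite validates parameter recovery at 10 loci × 300 reads per
bin over 100 simulated replicates (recovered levels inside their 95 %
binomial intervals at ≥ 93 % of sites; exact recovery with all error
rates zero), epiallele sensitivity with 1.4 % fully methylated
molecules among 5 000 reads, the alignment scorer on 10 000 random
instances, and the concordance engine against closed forms
(band ±1.96σ, within-t fraction → 2Φ(t/σ)−1). The acceptance script
runs a 6-locus × 10-sample study (~16 000 reads) chosen to exercise
every stage at realistic scale while staying quick on one CPU.

## Known limitations

- Reverse-complement handling exists only as an opt-in demultiplexing
  flag; the alignment stage assumes forward-strand reads.
- The aligner is pairwise-global per locus; it does not re-bin reads by
  best alignment across loci (binning is the demultiplexer's job).
- Levels are raw proportions; no shrinkage, smoothing, or differential
  methylation testing is provided.
- SNP-aware allele-specific methylation analysis is out of scope.
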