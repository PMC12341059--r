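#' Simulate aligned base calls over a variant position
#'
#' Stand-in generator for RNA-seq read pileups at a heterozygous site: each
#' call carries the alternate base with probability `alt_fraction` and the
#' reference base otherwise; a sequencing error then substitutes a uniformly
#' chosen different base with probability `error_rate`. Base and mapping
#' qualities are drawn around Q30.
#'
#' @param depth Number of reads covering the position.
#' @param alt_fraction True alternate-allele fraction in `[0, 1]`.
#' @param error_rate Per-base substitution error rate in `[0, 0.1)`.
#' @param ref,alt Reference and alternate bases.
#' @param seed Optional integer seed.
#' @return A tibble of base calls: `read_id`, `base`, `base_quality`,
#'   `map_quality`.
#' @export
simulate_pileup <- function(depth, alt_fraction, error_rate = 0.001,
                            ref = "T", alt = "C", seed = NULL) {
  stopifnot(depth >= 0, alt_fraction >= 0, alt_fraction <= 1,
            error_rate >= 0, error_rate < 0.1, ref != alt)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  true_base <- ifelse(stats::runif(depth) < alt_fraction, alt, ref)
  err <- stats::runif(depth) < error_rate
  obs <- true_base
  if (any(err)) {
    obs[err] <- vapply(true_base[err],
                       function(b) sample(setdiff(bases, b), 1), character(1))
  }
  tibble::tibble(
    read_id = sprintf("read%06d", seq_len(depth)),
    base = obs,
    base_quality = pmax(2L, as.integer(round(stats::rnorm(depth, 30, 3)))),
    map_quality = pmax(0L, as.integer(round(stats::rnorm(depth, 50, 5)))))
}

#' Pileup base counts at one position
#'
#' Tallies base calls into per-base counts after applying base- and
#' mapping-quality floors; `N` calls and calls failing either floor are
#' excluded, so `depth` equals the retained call count.
#'
#' @param calls Tibble of base calls (`base`, `base_quality`, `map_quality`),
#'   e.g. from [simulate_pileup()] or [read_base_calls()].
#' @param min_base_q,min_map_q Phred quality floors (defaults 20/20).
#' @param contig,position Coordinates stored with the counts (1-based).
#' @return A list of class `pileup_counts`: `contig`, `position`, `counts`
#'   (named A/C/G/T), `depth`.
#' @export
pileup <- function(calls, min_base_q = 20, min_map_q = 20,
                   contig = NA_character_, position = NA_integer_) {
  stopifnot(all(c("base", "base_quality", "map_quality") %in% names(calls)))
  keep <- calls$base %in% c("A", "C", "G", "T") &
    calls$base_quality >= min_base_q & calls$map_quality >= min_map_q
  counts <- table(factor(calls$base[keep], levels = c("A", "C", "G", "T")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  out <- structure(list(contig = contig, position = position,
                        counts = counts, depth = sum(counts)),
                   class = "pileup_counts")
  if (out$depth == 0) attr(out, "empty") <- TRUE
  out
}

#' @export
print.pileup_counts <- function(x, ...) {
  cat("<pileup_counts> ", x$contig, ":", x$position, " depth ", x$depth,
      "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Allele fractions and exact imbalance test
#'
#' Computes reference and alternate base fractions of a pileup, an exact
#' two-sided binomial test of the alternate fraction against the heterozygous
#' expectation 0.5 (restricted to ref+alt calls), and a 95% Clopper-Pearson
#' confidence interval for the alternate fraction.
#'
#' @param counts A [pileup()] result.
#' @param ref,alt Reference and alternate bases (must differ).
#' @return A tibble of class `allele_call`: `ref_base`, `alt_base`,
#'   `ref_count`, `alt_count`, `depth`, `ref_fraction`, `alt_fraction`,
#'   `binom_p`, `ci_lower`, `ci_upper`.
#' @export
allele_fractions <- function(counts, ref, alt) {
  stopifnot(inherits(counts, "pileup_counts"))
  if (ref == alt) stop("ref and alt bases must differ")
  if (counts$depth < 1) stop("empty pileup: depth 0")
  nref <- counts$counts[[ref]]
  nalt <- counts$counts[[alt]]
  bt <- stats::binom.test(nalt, nref + nalt, p = 0.5,
                          alternative = "two.sided")
  out <- tibble::tibble(
    ref_base = ref, alt_base = alt,
    ref_count = nref, alt_count = nalt, depth = counts$depth,
    ref_fraction = nref / counts$depth,
    alt_fraction = nalt / counts$depth,
    binom_p = bt$p.value,
    ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2])
  structure(out, class = c("allele_call", class(out)))
}

#' Read base calls from a plain tabular file
#'
#' Reads the package's plain base-call format: a TSV with columns `read_id`,
#' `base`, `base_quality`, `map_quality` (one row per aligned base overlapping
#' the position of interest).
#'
#' @param file Path to the TSV.
#' @return A tibble of base calls.
#' @export
read_base_calls <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    read_id = readr::col_character(),
    base = readr::col_character(),
    base_quality = readr::col_integer(),
    map_quality = readr::col_integer()))
}

#' Pileup counts from a BAM/SAM file via Rsamtools
#'
#' Delegates alignment parsing to Rsamtools (SAM files are converted with
#' `asBam()` first) and returns the per-base counts at one position with the
#' same quality-floor semantics as [pileup()].
#'
#' @param file Path to a BAM or SAM file.
#' @param contig,position 1-based position of interest.
#' @param min_base_q,min_map_q Phred quality floors.
#' @return A `pileup_counts`.
#' @export
pileup_from_bam <- function(file, contig, position,
                            min_base_q = 20, min_map_q = 20) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("pileup_from_bam() requires the Rsamtools package")
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile()
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(file, ".bai"))) {
    Rsamtools::indexBam(file)
  }
  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(position, position))
  res <- Rsamtools::pileup(
    file,
    scanBamParam = Rsamtools::ScanBamParam(which = which),
    pileupParam = Rsamtools::PileupParam(
      min_base_quality = as.integer(min_base_q),
      min_mapq = as.integer(min_map_q),
      min_nucleotide_depth = 0L,
      distinguish_strands = FALSE,
      include_deletions = FALSE, include_insertions = FALSE))
  res <- res[res$pos == position & res$nucleotide %in% c("A", "C", "G", "T"), ]
  counts <- stats::setNames(integer(4), c("A", "C", "G", "T"))
  counts[as.character(res$nucleotide)] <- res$count
  structure(list(contig = contig, position = as.integer(position),
                 counts = counts, depth = sum(counts)),
            class = "pileup_counts")
}
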