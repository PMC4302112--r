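#' Assembly parameters
#'
#' Bundles every tunable of the assembler with its default. Defaults for the
#' intron ratio (0.1), the maximum spliced-read distance (1 kb), the tail-trim
#' depth (3), and the high-coverage threshold (20) follow the values the method
#' was calibrated with on *Saccharomyces* transcriptomes; `min_reads` and
#' `min_gap_forced_join` are the noise filter and forced-join gap the user is
#' expected to adapt to library depth.
#'
#' @param min_gap_forced_join Zero-coverage gaps strictly shorter than this
#'   (bases) never split a block: the assembler is forced to join across them.
#' @param min_reads Minimum number of reads a block must contain; smaller
#'   blocks are discarded as background noise.
#' @param intron_ratio Minimum ratio of spliced-read support to unspliced depth
#'   at the intron-exon boundary for an intron call to be accepted. Use 0.65
#'   for genomes with many spurious junctions (the *N. castellii* setting).
#' @param max_spliced_distance Maximum intron length (bases) a spliced read may
#'   span; longer gaps discard the read.
#' @param small_deletion_max Reference skips at or below this length (bases)
#'   are treated as alignment deletions, not introns.
#' @param trim_depth Terminal bases with depth less than or equal to this are
#'   trimmed from high-coverage transcripts.
#' @param high_coverage_threshold Mean coverage a transcript must exceed before
#'   tail trimming (and UTR comparison filtering) applies.
#' @param sd_multiplier Width of the adaptive joining rule in standard
#'   deviations of the learned gap/coverage-ratio distributions.
#' @param trim_enabled Master switch for the tail-trimming pass.
#' @param t_intergenic Minimum ratio of mean intergenic depth to the weaker
#'   gene's mean depth for a polycistronic pair to be validated.
#' @param t_genes Minimum min/max ratio of the two genes' mean depths for a
#'   polycistronic pair to be validated.
#' @param antisense_frac Fraction of a transcript's length that must lie
#'   antisense to protein-coding genes before it is classed as a SAUT
#'   (strict inequality: exactly this fraction does not qualify).
#' @param utr_diff_threshold Minimum 5'-UTR length difference (bases) between
#'   two samples for a gene to count as variable in that comparison.
#' @param highly_variable_min Minimum number of variable pairwise comparisons
#'   for a gene to be classed highly variable.
#'
#' @return A list of class `tx_params`.
#' @examples
#' p <- assembly_params(min_reads = 3)
#' p$intron_ratio
#' @export
assembly_params <- function(min_gap_forced_join = 25,
                            min_reads = 5,
                            intron_ratio = 0.1,
                            max_spliced_distance = 1000,
                            small_deletion_max = 10,
                            trim_depth = 3,
                            high_coverage_threshold = 20,
                            sd_multiplier = 2,
                            trim_enabled = TRUE,
                            t_intergenic = 0.5,
                            t_genes = 0.5,
                            antisense_frac = 0.5,
                            utr_diff_threshold = 50,
                            highly_variable_min = 6) {
  p <- list(
    min_gap_forced_join = min_gap_forced_join,
    min_reads = min_reads,
    intron_ratio = intron_ratio,
    max_spliced_distance = max_spliced_distance,
    small_deletion_max = small_deletion_max,
    trim_depth = trim_depth,
    high_coverage_threshold = high_coverage_threshold,
    sd_multiplier = sd_multiplier,
    trim_enabled = isTRUE(trim_enabled),
    t_intergenic = t_intergenic,
    t_genes = t_genes,
    antisense_frac = antisense_frac,
    utr_diff_threshold = utr_diff_threshold,
    highly_variable_min = highly_variable_min
  )
  num <- p[!names(p) %in% "trim_enabled"]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && x > 0, TRUE))) {
    abort("all assembly parameters must be positive scalars")
  }
  if (p$intron_ratio > 1) abort("`intron_ratio` must lie in (0, 1]")
  if (p$antisense_frac >= 1) abort("`antisense_frac` must lie in (0, 1)")
  structure(p, class = "tx_params")
}

#' @export
print.tx_params <- function(x, ...) {
  cat("<tx_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "tx_params")) return(params)
  if (is.list(params)) return(do.call(assembly_params, params))
  abort("`params` must be created by `assembly_params()`")
}

# Transcript class vocabulary, in reporting order.
TX_CLASSES <- c("protein_coding", "SAUT", "SUT", "tRNA", "other_ncRNA",
                "intronic_ncRNA")
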