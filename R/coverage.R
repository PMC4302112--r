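#' Build strand-specific per-base coverage
#'
#' Computes, for every (chromosome, strand), an integer depth vector over the
#' full chromosome. Depth from unspliced reads and depth contributed by the
#' segments of spliced reads are kept in separate tracks: block construction
#' and tail trimming work on the unspliced track, while intron calling
#' contrasts the two.
#'
#' @param reads A read tibble (one row per segment; see [read_alignments()]).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A tibble with one row per (chromosome, strand) and columns `chrom`,
#'   `strand`, `length`, and list-columns `depth` and `spliced_depth` holding
#'   integer vectors of per-base depth.
#' @examples
#' r <- tibble::tibble(read_id = c("a", "b"), chrom = "chrI", strand = "+",
#'                     start = c(100L, 100L), end = c(149L, 149L),
#'                     segment = 1L, n_segments = 1L)
#' cov <- build_coverage(r, c(chrI = 300L))
#' sum(cov$depth[[1]])  # 100 aligned bases
#' @export
build_coverage <- function(reads, chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyNA(chrom_lengths)) {
    abort("`chrom_lengths` must be a named integer vector")
  }
  grid <- tidyr::expand_grid(chrom = names(chrom_lengths),
                             strand = c("+", "-"))
  if (nrow(reads) > 0) {
    bad <- setdiff(unique(reads$chrom), names(chrom_lengths))
    if (length(bad)) {
      abort(paste0("reads on unknown chromosome(s): ",
                   paste(bad, collapse = ", ")))
    }
    over <- reads$end > chrom_lengths[reads$chrom]
    if (any(over)) abort("read segment extends beyond chromosome length")
  }
  grid |>
    mutate(length = as.integer(chrom_lengths[.data$chrom]),
           depth = pmap(list(.data$chrom, .data$strand, .data$length),
                        function(ch, st, len) {
                          seg_depth(reads, ch, st, len, spliced = FALSE)
                        }),
           spliced_depth = pmap(list(.data$chrom, .data$strand, .data$length),
                                function(ch, st, len) {
                                  seg_depth(reads, ch, st, len, spliced = TRUE)
                                }))
}

seg_depth <- function(reads, ch, st, len, spliced) {
  if (nrow(reads) == 0) return(integer(len))
  sel <- reads$chrom == ch & reads$strand == st &
    (reads$n_segments > 1) == spliced
  if (!any(sel)) return(integer(len))
  delta <- integer(len + 1L)
  s <- reads$start[sel]
  e <- reads$end[sel]
  add <- tapply(rep(1L, length(s)), s, sum)
  sub <- tapply(rep(1L, length(e)), e + 1L, sum)
  delta[as.integer(names(add))] <- as.integer(add)
  i <- as.integer(names(sub))
  delta[i] <- delta[i] - as.integer(sub)
  cumsum(delta)[seq_len(len)]
}

#' Extract one per-base depth vector from a coverage tibble
#'
#' @param coverage A coverage tibble from [build_coverage()].
#' @param ch Chromosome name.
#' @param st Strand, `"+"` or `"-"`.
#' @param which Track to return: unspliced `depth` (default) or
#'   `spliced_depth`.
#' @return Integer vector of per-base depth along the chromosome.
#' @export
cov_vec <- function(coverage, ch, st, which = c("depth", "spliced_depth")) {
  which <- match.arg(which)
  i <- which(coverage$chrom == ch & coverage$strand == st)
  if (length(i) != 1) abort(paste0("no coverage track for ", ch, " ", st))
  coverage[[which]][[i]]
}
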