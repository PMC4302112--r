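#' Join overlapping reads into strand-specific blocks
#'
#' Unspliced read segments on one strand that overlap (or are separated by a
#' zero-coverage gap strictly shorter than `min_gap_forced_join`) are joined
#' into maximal blocks, the assembler's unit of merging. Blocks containing
#' fewer than `min_reads` reads are discarded as background noise — isolated
#' reads scattered over intergenic regions.
#'
#' @param reads A read tibble (see [read_alignments()]).
#' @param params An [assembly_params()] object.
#' @return A tibble of blocks: `chrom`, `strand`, `start`, `end`, `read_count`,
#'   `mean_coverage` (mean unspliced depth over the full span, zero-depth
#'   positions included), and an empty `genes` list-column to be filled by
#'   [classify_blocks()].
#' @examples
#' r <- tibble::tibble(read_id = c("a", "b"), chrom = "c", strand = "+",
#'                     start = c(1L, 30L), end = c(50L, 80L),
#'                     segment = 1L, n_segments = 1L)
#' build_blocks(r, assembly_params(min_reads = 1))
#' @export
build_blocks <- function(reads, params = assembly_params()) {
  params <- as_params(params)
  segs <- filter(reads, .data$n_segments == 1)
  if (nrow(segs) == 0) return(empty_blocks())
  segs |>
    arrange(.data$chrom, .data$strand, .data$start, .data$end) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(reach = cummax(lag(.data$end, default = 0L)),
           gap = .data$start - .data$reach - 1L,
           block = cumsum(row_number() == 1L |
                            .data$gap >= params$min_gap_forced_join)) |>
    group_by(.data$chrom, .data$strand, .data$block) |>
    summarise(seg_bases = sum(.data$end - .data$start + 1),
              start = min(.data$start), end = max(.data$end),
              read_count = n(),
              mean_coverage = .data$seg_bases / (.data$end - .data$start + 1),
              .groups = "drop") |>
    select(-"seg_bases") |>
    filter(.data$read_count >= params$min_reads) |>
    mutate(genes = rep(list(character()), n())) |>
    select(-"block") |>
    arrange(.data$chrom, .data$strand, .data$start)
}

empty_blocks <- function() {
  tibble(chrom = character(), strand = character(), start = integer(),
         end = integer(), read_count = integer(), mean_coverage = numeric(),
         genes = list())
}

#' Assign blocks to annotated genes
#'
#' A block is reference-based when it overlaps at least one same-strand
#' annotated gene by one base or more; all such genes are listed in genomic
#' order. Blocks with no same-strand overlap (intergenic or antisense) keep an
#' empty gene list and are candidate novel transcripts.
#'
#' @param blocks A block tibble from [build_blocks()].
#' @param annotation An annotation tibble from [read_annotation()].
#' @return `blocks` with the `genes` list-column filled.
#' @export
classify_blocks <- function(blocks, annotation) {
  if (nrow(blocks) == 0) return(blocks)
  ann <- arrange(annotation, .data$chrom, .data$start)
  blocks$genes <- pmap(
    list(blocks$chrom, blocks$strand, blocks$start, blocks$end),
    function(ch, st, s, e) {
      hit <- ann$chrom == ch & ann$strand == st & ann$start <= e & ann$end >= s
      ann$gene_id[hit]
    })
  blocks
}

#' Learn gap and coverage-ratio statistics from reference-based blocks
#'
#' Over all consecutive same-strand block pairs that share an assigned gene —
#' i.e. fragments of one transcript split by sequencing dropouts — records the
#' inter-block gap size and the min/max ratio of the two blocks' mean
#' coverages, and summarises each as mean and sample standard deviation. These
#' learned distributions (GRBB/CRRBB in the assembler's vocabulary) calibrate
#' the adaptive joining rule of [join_intergenic_blocks()] to the library's own
#' dropout behaviour.
#'
#' @param blocks A classified block tibble ([classify_blocks()]).
#' @return An object of class `tx_gap_stats` with fields `grbb_mean`,
#'   `grbb_sd`, `crrbb_mean`, `crrbb_sd`, `n_pairs`. [tidy()] and [glance()]
#'   methods are provided.
#' @export
compute_gap_stats <- function(blocks) {
  pairs <- consecutive_shared_gene_pairs(blocks)
  n <- nrow(pairs)
  if (n == 0) {
    return(new_gap_stats(NA_real_, 0, NA_real_, 0, 0L))
  }
  new_gap_stats(mean(pairs$gap), if (n < 2) 0 else sd(pairs$gap),
                mean(pairs$ratio), if (n < 2) 0 else sd(pairs$ratio),
                n)
}

consecutive_shared_gene_pairs <- function(blocks) {
  if (nrow(blocks) < 2) {
    return(tibble(gap = numeric(), ratio = numeric()))
  }
  blocks |>
    arrange(.data$chrom, .data$strand, .data$start) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(
      next_start = lead(.data$start),
      next_cov = lead(.data$mean_coverage),
      shares = map2_lgl(.data$genes, lead(.data$genes),
                        function(a, b) {
                          !is.null(b) && length(intersect(a, b)) > 0
                        })) |>
    ungroup() |>
    filter(.data$shares) |>
    transmute(gap = .data$next_start - .data$end - 1,
              ratio = pmin(.data$mean_coverage, .data$next_cov) /
                pmax(.data$mean_coverage, .data$next_cov))
}

new_gap_stats <- function(gm, gs, cm, cs, n) {
  structure(list(grbb_mean = gm, grbb_sd = gs, crrbb_mean = cm,
                 crrbb_sd = cs, n_pairs = as.integer(n)),
            class = "tx_gap_stats")
}

#' @export
print.tx_gap_stats <- function(x, ...) {
  cat("<tx_gap_stats>  learned from", x$n_pairs, "within-gene block pairs\n")
  cat(sprintf("  gap size:       %.2f +/- %.2f bases\n", x$grbb_mean, x$grbb_sd))
  cat(sprintf("  coverage ratio: %.3f +/- %.3f\n", x$crrbb_mean, x$crrbb_sd))
  invisible(x)
}

#' @rdname compute_gap_stats
#' @param x A `tx_gap_stats` object.
#' @param ... Unused.
#' @export
tidy.tx_gap_stats <- function(x, ...) {
  tibble(statistic = c("gap", "coverage_ratio"),
         mean = c(x$grbb_mean, x$crrbb_mean),
         sd = c(x$grbb_sd, x$crrbb_sd),
         n_pairs = x$n_pairs)
}

#' @rdname compute_gap_stats
#' @export
glance.tx_gap_stats <- function(x, ...) {
  tibble(grbb_mean = x$grbb_mean, grbb_sd = x$grbb_sd,
         crrbb_mean = x$crrbb_mean, crrbb_sd = x$crrbb_sd,
         n_pairs = x$n_pairs)
}

# Joining thresholds from learned statistics; conservative fallbacks when too
# few within-gene pairs exist to estimate a spread.
gap_stats_thresholds <- function(stats, params) {
  if (stats$n_pairs < 2 || is.na(stats$grbb_mean)) {
    list(gap_max = params$min_gap_forced_join * 5, ratio_min = 0.5)
  } else {
    list(gap_max = stats$grbb_mean + params$sd_multiplier * stats$grbb_sd,
         ratio_min = stats$crrbb_mean - params$sd_multiplier * stats$crrbb_sd)
  }
}

#' Absorb intergenic blocks into adjacent reference-based blocks
#'
#' Iteratively merges each unassigned (intergenic) block into an adjacent
#' reference-based block on the same strand when the gap between them and
#' their coverage ratio fall inside `sd_multiplier` standard deviations of the
#' learned distributions ([compute_gap_stats()]). After every pass the merged
#' spans, coverages and statistics are recomputed and the procedure repeats
#' until no further block can be joined. Blocks that never qualify remain as
#' candidate novel/non-coding transcripts.
#'
#' When a block qualifies on both sides it is merged toward the smaller gap;
#' ties go to the higher coverage ratio, then upstream.
#'
#' @param blocks A classified block tibble.
#' @param params An [assembly_params()] object.
#' @param stats Optional pre-computed `tx_gap_stats` for the first pass;
#'   recomputed after each pass regardless.
#' @return The merged block tibble at fixed point.
#' @export
join_intergenic_blocks <- function(blocks, params = assembly_params(),
                                   stats = NULL) {
  params <- as_params(params)
  if (nrow(blocks) == 0) return(blocks)
  repeat {
    if (is.null(stats)) stats <- compute_gap_stats(blocks)
    thr <- gap_stats_thresholds(stats, params)
    merged <- join_pass(blocks, thr)
    if (merged$n_merges == 0) return(merged$blocks)
    blocks <- merged$blocks
    stats <- NULL
  }
}

# One left-to-right pass with frozen thresholds; returns merged blocks and the
# number of merges performed.
join_pass <- function(blocks, thr) {
  out <- blocks |>
    arrange(.data$chrom, .data$strand, .data$start) |>
    group_by(.data$chrom, .data$strand) |>
    group_split()
  n_merges <- 0L
  res <- vector("list", length(out))
  for (g in seq_along(out)) {
    b <- as.list(out[[g]])
    i <- 1L
    while (i <= length(b$start)) {
      if (length(b$genes[[i]]) > 0) { i <- i + 1L; next }
      side <- pick_merge_side(b, i, thr)
      if (is.na(side)) { i <- i + 1L; next }
      j <- if (side == "left") i - 1L else i + 1L
      b <- merge_block_rows(b, min(i, j), max(i, j))
      n_merges <- n_merges + 1L
      i <- min(i, j)  # re-examine neighbourhood after the merge
    }
    res[[g]] <- as_tibble(b[c("chrom", "strand", "start", "end", "read_count",
                              "mean_coverage", "genes")])
  }
  list(blocks = arrange(bind_rows(res), .data$chrom, .data$strand,
                        .data$start),
       n_merges = n_merges)
}

pick_merge_side <- function(b, i, thr) {
  n <- length(b$start)
  cand <- list()
  if (i > 1L && length(b$genes[[i - 1L]]) > 0) {
    cand$left <- list(gap = b$start[i] - b$end[i - 1L] - 1,
                      ratio = min(b$mean_coverage[i], b$mean_coverage[i - 1L]) /
                        max(b$mean_coverage[i], b$mean_coverage[i - 1L]))
  }
  if (i < n && length(b$genes[[i + 1L]]) > 0) {
    cand$right <- list(gap = b$start[i + 1L] - b$end[i] - 1,
                       ratio = min(b$mean_coverage[i], b$mean_coverage[i + 1L]) /
                         max(b$mean_coverage[i], b$mean_coverage[i + 1L]))
  }
  ok <- vapply(cand, function(x) x$gap <= thr$gap_max && x$ratio >= thr$ratio_min,
               TRUE)
  cand <- cand[ok]
  if (length(cand) == 0) return(NA_character_)
  if (length(cand) == 1) return(names(cand))
  # qualifies on both sides: smaller gap, then higher ratio, then upstream
  if (cand$left$gap != cand$right$gap) {
    return(if (cand$left$gap < cand$right$gap) "left" else "right")
  }
  if (cand$left$ratio != cand$right$ratio) {
    return(if (cand$left$ratio > cand$right$ratio) "left" else "right")
  }
  "left"
}

# merge rows i < j (adjacent) of a block list; span/coverage/read_count
# recomputed, gene assignment taken from the union
merge_block_rows <- function(b, i, j) {
  new_start <- b$start[i]
  new_end <- b$end[j]
  covered <- b$mean_coverage[i] * (b$end[i] - b$start[i] + 1) +
    b$mean_coverage[j] * (b$end[j] - b$start[j] + 1)
  b$end[i] <- new_end
  b$mean_coverage[i] <- covered / (new_end - new_start + 1)
  b$read_count[i] <- b$read_count[i] + b$read_count[j]
  b$genes[[i]] <- union(b$genes[[i]], b$genes[[j]])
  for (f in c("chrom", "strand", "start", "end", "read_count",
              "mean_coverage")) {
    b[[f]] <- b[[f]][-j]
  }
  b$genes <- b$genes[-j]
  b
}
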