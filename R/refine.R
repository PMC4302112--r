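#' Call introns from spliced reads
#'
#' Groups spliced reads by their exact junction (first and last intronic base)
#' and accepts a junction when its spliced support is at least `intron_ratio`
#' times the unspliced depth at the flanking exonic bases. The ratio filter
#' suppresses false junctions from mis-aligned reads: genuine introns drain
#' unspliced coverage at the boundary, spurious ones face deep unspliced
#' competition. A junction with support but zero unspliced competition is
#' accepted with an infinite ratio.
#'
#' @param reads A read tibble (see [read_alignments()]).
#' @param coverage A coverage tibble from [build_coverage()].
#' @param params An [assembly_params()] object; `intron_ratio` is the
#'   acceptance threshold (0.1 default; 0.65 for junction-noisy genomes).
#' @return A tibble of junctions: `chrom`, `strand`, `donor`, `acceptor`,
#'   `spliced_support`, `boundary_unspliced`, `ratio`, `accepted`.
#' @export
detect_introns <- function(reads, coverage, params = assembly_params()) {
  params <- as_params(params)
  spl <- filter(reads, .data$n_segments > 1)
  if (nrow(spl) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  donor = integer(), acceptor = integer(),
                  spliced_support = integer(), boundary_unspliced = numeric(),
                  ratio = numeric(), accepted = logical()))
  }
  junc <- spl |>
    arrange(.data$read_id, .data$segment) |>
    group_by(.data$read_id) |>
    mutate(donor = .data$end + 1L, acceptor = lead(.data$start) - 1L) |>
    ungroup() |>
    filter(!is.na(.data$acceptor)) |>
    count(.data$chrom, .data$strand, .data$donor, .data$acceptor,
          name = "spliced_support")

  junc |>
    mutate(boundary_unspliced = pmap_dbl(
      list(.data$chrom, .data$strand, .data$donor, .data$acceptor),
      function(ch, st, d, a) {
        dep <- cov_vec(coverage, ch, st, "depth")
        left <- if (d - 1L >= 1L) dep[d - 1L] else 0L
        right <- if (a + 1L <= length(dep)) dep[a + 1L] else 0L
        (left + right) / 2
      }),
      ratio = ifelse(.data$boundary_unspliced == 0, Inf,
                     .data$spliced_support / .data$boundary_unspliced),
      accepted = .data$ratio >= params$intron_ratio) |>
    arrange(.data$chrom, .data$strand, .data$donor)
}

#' Merge within-gene blocks into draft transcripts
#'
#' Consecutive blocks assigned to the same gene are fragments of one
#' transcript split by coverage dropouts; they are merged across their gaps,
#' and a gap is recorded as an intron when an accepted junction lies inside
#' it. Surviving unassigned blocks become drafts with no covered gene —
#' candidate novel/non-coding transcripts. Draft mean coverage is the mean
#' unspliced depth over exonic positions (intron bases excluded).
#'
#' @param blocks Block tibble at the joining fixed point.
#' @param introns Junction tibble from [detect_introns()]; only accepted
#'   junctions are used.
#' @param annotation Annotation tibble (orders covered genes genomically).
#' @param coverage Coverage tibble from [build_coverage()].
#' @return A draft transcript tibble: `chrom`, `strand`, `start`, `end`,
#'   `covered_genes` (list), `introns` (list of tibbles with `donor`,
#'   `acceptor`), `mean_coverage`, `polycistronic_status`.
#' @export
merge_within_gene <- function(blocks, introns, annotation, coverage) {
  if (nrow(blocks) == 0) return(empty_drafts())
  acc <- filter(introns, .data$accepted)
  drafts <- blocks |>
    arrange(.data$chrom, .data$strand, .data$start) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(linked = map2_lgl(.data$genes, lag(.data$genes),
                             function(a, b) {
                               !is.null(b) && length(intersect(a, b)) > 0
                             }),
           draft = cumsum(!.data$linked)) |>
    group_by(.data$chrom, .data$strand, .data$draft) |>
    summarise(start = min(.data$start), end = max(.data$end),
              covered_genes = list(unique(unlist(.data$genes))),
              .groups = "drop") |>
    select(-"draft")

  drafts$covered_genes <- map(drafts$covered_genes, function(g) {
    if (is.null(g) || length(g) == 0) return(character())
    ord <- match(g, annotation$gene_id)
    g[order(annotation$start[ord])]
  })
  drafts$introns <- pmap(
    list(drafts$chrom, drafts$strand, drafts$start, drafts$end),
    function(ch, st, s, e) transcript_introns(acc, ch, st, s, e))
  drafts$mean_coverage <- exonic_mean_coverage(drafts, coverage)
  drafts$polycistronic_status <- ifelse(
    map_int(drafts$covered_genes, length) >= 2L, "candidate", "monocistronic")
  arrange(drafts, .data$chrom, .data$strand, .data$start)
}

empty_drafts <- function() {
  tibble(chrom = character(), strand = character(), start = integer(),
         end = integer(), covered_genes = list(), introns = list(),
         mean_coverage = numeric(), polycistronic_status = character())
}

# accepted introns strictly inside [s, e]; overlapping calls resolved greedily
# by support (then position) so recorded introns are pairwise disjoint
transcript_introns <- function(acc, ch, st, s, e) {
  cand <- acc[acc$chrom == ch & acc$strand == st &
                acc$donor > s & acc$acceptor < e, ]
  if (nrow(cand) == 0) return(tibble(donor = integer(), acceptor = integer()))
  cand <- cand[order(-cand$spliced_support, cand$donor), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    keep[i] <- !any(keep & cand$donor <= cand$acceptor[i] &
                      cand$acceptor >= cand$donor[i])
  }
  out <- cand[keep, c("donor", "acceptor")]
  out[order(out$donor), ]
}

exonic_mean_coverage <- function(drafts, coverage) {
  pmap_dbl(list(drafts$chrom, drafts$strand, drafts$start, drafts$end,
                drafts$introns),
           function(ch, st, s, e, iv) {
             dep <- cov_vec(coverage, ch, st, "depth")
             pos <- seq.int(s, e)
             if (!is.null(iv) && nrow(iv) > 0) {
               intronic <- unlist(map2(iv$donor, iv$acceptor, seq.int))
               pos <- setdiff(pos, intronic)
             }
             mean(dep[pos])
           })
}

#' Trim low-coverage transcript tails
#'
#' High-coverage transcripts tend to carry long terminal "tails" of very low
#' depth that inflate UTR estimates. For drafts whose mean coverage exceeds
#' `high_coverage_threshold`, both ends are advanced inward while the per-base
#' unspliced depth is at or below `trim_depth`; lower-coverage drafts are left
#' untouched. The operation is idempotent. A draft consumed entirely by
#' trimming is dropped with a warning.
#'
#' @param transcripts Draft transcript tibble ([merge_within_gene()]).
#' @param coverage Coverage tibble.
#' @param params An [assembly_params()] object.
#' @return The trimmed transcript tibble (mean coverage recomputed over the
#'   trimmed exonic span for transcripts that moved).
#' @export
trim_ends <- function(transcripts, coverage, params = assembly_params()) {
  params <- as_params(params)
  if (!params$trim_enabled || nrow(transcripts) == 0) return(transcripts)
  t <- transcripts
  drop <- logical(nrow(t))
  moved <- logical(nrow(t))
  for (i in seq_len(nrow(t))) {
    if (t$mean_coverage[i] <= params$high_coverage_threshold) next
    dep <- cov_vec(coverage, t$chrom[i], t$strand[i], "depth")
    s <- t$start[i]; e <- t$end[i]
    while (s <= e && dep[s] <= params$trim_depth) s <- s + 1L
    while (e >= s && dep[e] <= params$trim_depth) e <- e - 1L
    if (s > e) { drop[i] <- TRUE; next }
    if (s != t$start[i] || e != t$end[i]) {
      moved[i] <- TRUE
      t$start[i] <- s
      t$end[i] <- e
      t$introns[[i]] <- t$introns[[i]][t$introns[[i]]$donor > s &
                                         t$introns[[i]]$acceptor < e, ]
    }
  }
  if (any(drop)) {
    warn(sprintf("%d transcript(s) consumed entirely by trimming were dropped",
                 sum(drop)))
    t <- t[!drop, ]
    moved <- moved[!drop]
  }
  if (any(moved)) {
    t$mean_coverage[moved] <- exonic_mean_coverage(t[moved, ], coverage)
  }
  t
}

#' Validate polycistronic transcript candidates
#'
#' A draft spanning two or more same-strand genes may be a genuine
#' polycistronic transcript or two independent transcripts merely adjacent on
#' the genome. For each adjacent gene pair inside a draft the inter-gene
#' interval must (a) have no zero-depth base, (b) have mean depth at least
#' `t_intergenic` times the weaker gene's mean depth, and (c) the two genes'
#' mean depths must agree within `t_genes` (min/max). A failing draft is split
#' at the deepest minimum of the failing inter-gene interval and its pieces
#' are re-validated; passing drafts get status `validated`.
#'
#' @param transcripts Draft transcript tibble.
#' @param coverage Coverage tibble.
#' @param annotation Annotation tibble.
#' @param params An [assembly_params()] object (`t_intergenic`, `t_genes`).
#' @return The transcript tibble with candidates split where required and
#'   `polycistronic_status` set to `monocistronic` / `validated`.
#' @export
validate_polycistronic <- function(transcripts, coverage, annotation,
                                   params = assembly_params()) {
  params <- as_params(params)
  if (nrow(transcripts) == 0) return(transcripts)
  out <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    out[[i]] <- validate_one(transcripts[i, ], coverage, annotation, params)
  }
  arrange(bind_rows(out), .data$chrom, .data$strand, .data$start)
}

validate_one <- function(t, coverage, annotation, params) {
  genes <- t$covered_genes[[1]]
  if (length(genes) < 2) {
    t$polycistronic_status <- "monocistronic"
    return(t)
  }
  dep <- cov_vec(coverage, t$chrom, t$strand, "depth")
  g <- annotation[match(genes, annotation$gene_id), ]
  g <- g[order(g$start), ]
  for (k in seq_len(nrow(g) - 1)) {
    istart <- g$end[k] + 1L
    iend <- g$start[k + 1L] - 1L
    if (istart > iend) next  # abutting genes: nothing to test
    iv <- dep[istart:iend]
    span_l <- max(g$start[k], t$start):min(g$end[k], t$end)
    span_r <- max(g$start[k + 1L], t$start):min(g$end[k + 1L], t$end)
    mean_l <- mean(dep[span_l]); mean_r <- mean(dep[span_r])
    ok <- min(iv) > 0 &&
      mean(iv) >= params$t_intergenic * min(mean_l, mean_r) &&
      min(mean_l, mean_r) / max(mean_l, mean_r) >= params$t_genes
    if (!ok) {
      cut <- istart + which.min(iv) - 1L
      left <- resize_draft(t, t$start, cut - 1L, coverage, annotation)
      right <- resize_draft(t, cut + 1L, t$end, coverage, annotation)
      return(bind_rows(
        validate_one(left, coverage, annotation, params),
        validate_one(right, coverage, annotation, params)))
    }
  }
  t$polycistronic_status <- "validated"
  t
}

# rebuild a draft row over a sub-span: covered genes, introns, coverage
resize_draft <- function(t, s, e, coverage, annotation) {
  d <- t
  d$start <- as.integer(s)
  d$end <- as.integer(e)
  genes <- t$covered_genes[[1]]
  g <- annotation[match(genes, annotation$gene_id), ]
  keep <- g$start <= e & g$end >= s
  d$covered_genes <- list(genes[keep][order(g$start[keep])])
  iv <- t$introns[[1]]
  d$introns <- list(iv[iv$donor > s & iv$acceptor < e, ])
  d$mean_coverage <- exonic_mean_coverage(d, coverage)
  d
}

#' Compute signed UTR lengths
#'
#' Measures the 5'- and 3'-UTR of each coding transcript as the distance
#' between the assembled transcript end and the annotated boundary of the
#' 5'-most (respectively 3'-most) covered gene, in transcript orientation: on
#' the minus strand the 5'-UTR lies at the right end of the span. Negative
#' values flag transcripts truncated relative to the annotation and are
#' deliberately not clamped.
#'
#' @param transcripts Transcript tibble with `covered_genes`.
#' @param annotation Annotation tibble.
#' @return `transcripts` with integer columns `utr5_len`, `utr3_len` (`NA` for
#'   transcripts covering no gene).
#' @export
compute_utrs <- function(transcripts, annotation) {
  if (nrow(transcripts) == 0) {
    return(mutate(transcripts, utr5_len = integer(), utr3_len = integer()))
  }
  utr <- pmap(
    list(transcripts$covered_genes, transcripts$strand, transcripts$start,
         transcripts$end),
    function(genes, st, s, e) {
      if (length(genes) == 0) return(c(NA_integer_, NA_integer_))
      g <- annotation[match(genes, annotation$gene_id), ]
      gs <- min(g$start); ge <- max(g$end)
      if (st == "+") c(gs - s, e - ge) else c(e - ge, gs - s)
    })
  transcripts$utr5_len <- as.integer(map_dbl(utr, 1))
  transcripts$utr3_len <- as.integer(map_dbl(utr, 2))
  transcripts
}
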