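#' Compare 5'-UTR lengths across samples
#'
#' For every gene covered by a high-coverage protein-coding transcript in
#' *all* samples, compares the 5'-UTR length between every pair of samples
#' and counts the comparisons in which the lengths differ by
#' `utr_diff_threshold` bases or more. Genes below `min_coverage` in any
#' sample are excluded: low-coverage UTR calls are unreliable. The per-gene
#' count feeds [classify_variability()].
#'
#' @param transcriptomes Named list (sample -> classified transcript tibble).
#' @param utr_diff_threshold Minimum |difference| in bases to call a pair of
#'   samples variable for a gene (boundary values count as variable).
#' @param min_coverage Genes must exceed this mean coverage in every sample.
#' @param highly_variable_min Passed to [classify_variability()].
#' @param ortholog_map Optional tibble mapping `gene_id` -> `group_id` for
#'   cross-species comparisons; defaults to identity.
#' @return A tibble of class `tx_utr_comparison`: `gene_id`, one `utr5_*` and
#'   one `cov_*` column per sample, `n_variable_comparisons`,
#'   `variability_class`.
#' @export
compare_utrs <- function(transcriptomes, utr_diff_threshold = 50,
                         min_coverage = 20, highly_variable_min = 6,
                         ortholog_map = NULL) {
  if (!is.list(transcriptomes) || length(transcriptomes) < 2) {
    abort("`transcriptomes` must be a named list of at least two samples")
  }
  if (is.null(names(transcriptomes)) || any(!nzchar(names(transcriptomes)))) {
    abort("`transcriptomes` must be named by sample")
  }
  samples <- names(transcriptomes)
  per <- purrr::imap(transcriptomes, function(t, nm) {
    gene_utr_table(t, ortholog_map) |> mutate(sample = nm)
  }) |> bind_rows()

  wide <- per |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "sample",
                       values_from = c("utr5", "coverage"))
  utr_cols <- paste0("utr5_", samples)
  cov_cols <- paste0("coverage_", samples)
  keep <- stats::complete.cases(wide[utr_cols]) &
    apply(as.matrix(wide[cov_cols]), 1, function(x) {
      !anyNA(x) && all(x > min_coverage)
    })
  wide <- wide[keep, , drop = FALSE]

  nvar <- apply(as.matrix(wide[utr_cols]), 1, function(u) {
    d <- abs(outer(u, u, `-`))
    sum(d[upper.tri(d)] >= utr_diff_threshold)
  })
  out <- wide |>
    mutate(n_variable_comparisons = as.integer(nvar),
           variability_class = classify_variability(
             .data$n_variable_comparisons, highly_variable_min)) |>
    arrange(.data$gene_id)
  structure(out, class = c("tx_utr_comparison", class(out)))
}

# one row per gene: the 5'-UTR and coverage of its best (deepest) coding
# transcript in one sample
gene_utr_table <- function(t, ortholog_map = NULL) {
  t <- filter(t, .data$class_label == "protein_coding",
              lengths(.data$covered_genes) > 0)
  if (nrow(t) == 0) {
    return(tibble(gene_id = character(), utr5 = integer(),
                  coverage = numeric()))
  }
  tab <- t |>
    select("covered_genes", "utr5_len", "mean_coverage") |>
    tidyr::unnest_longer("covered_genes", values_to = "gene_id") |>
    group_by(.data$gene_id) |>
    slice_max(.data$mean_coverage, n = 1, with_ties = FALSE) |>
    ungroup() |>
    transmute(gene_id = .data$gene_id, utr5 = .data$utr5_len,
              coverage = .data$mean_coverage)
  if (!is.null(ortholog_map)) {
    tab <- tab |>
      inner_join(ortholog_map, by = "gene_id") |>
      mutate(gene_id = .data$group_id) |>
      select(-"group_id")
  }
  tab
}

#' Assign UTR variability classes
#'
#' Genes variable in no pairwise comparison are `conserved`; in at least one
#' but fewer than `highly_variable_min` comparisons, `variable`; in
#' `highly_variable_min` or more, `highly_variable`.
#'
#' @param n_variable_comparisons Integer vector of per-gene counts.
#' @param highly_variable_min Threshold for the highly variable class.
#' @return A character vector of class labels.
#' @export
classify_variability <- function(n_variable_comparisons,
                                 highly_variable_min = 6) {
  dplyr::case_when(
    n_variable_comparisons == 0 ~ "conserved",
    n_variable_comparisons < highly_variable_min ~ "variable",
    TRUE ~ "highly_variable"
  )
}

#' Genes with a conserved antisense transcript across all samples
#'
#' A SAUT is conserved when the same (orthologous) gene carries at least one
#' SAUT-classified transcript on its antisense strand in *every* sample —
#' antisense transcription that survives strain or species divergence is the
#' strongest available hint of function.
#'
#' @param transcriptomes Named list (sample -> classified transcript tibble).
#' @param ortholog_map Optional `gene_id` -> `group_id` tibble; identity by
#'   default.
#' @return Sorted character vector of gene (or ortholog-group) identifiers.
#' @export
conserved_sauts <- function(transcriptomes, ortholog_map = NULL) {
  if (!is.list(transcriptomes) || length(transcriptomes) == 0) {
    abort("`transcriptomes` must be a non-empty named list")
  }
  sets <- map(transcriptomes, function(t) {
    g <- unique(t$anti_gene[t$class_label == "SAUT" & !is.na(t$anti_gene)])
    if (!is.null(ortholog_map)) {
      g <- ortholog_map$group_id[match(g, ortholog_map$gene_id)]
      g <- unique(g[!is.na(g)])
    }
    g
  })
  sort(Reduce(intersect, sets))
}

#' Retain polycistronic pairs validated in every condition
#'
#' Gene pairs called polycistronic in only some growth conditions are distinct
#' transcripts whose intergenic region happens to be transcribed in that
#' condition, not real fusion transcripts; only pairs validated in *all*
#' conditions are retained.
#'
#' @param calls Named list (condition -> tibble with columns `gene_left`,
#'   `gene_right`), e.g. from [polycistronic_pairs()] per condition.
#' @return A tibble of the retained `gene_left`/`gene_right` pairs.
#' @export
filter_bicistronic_by_condition <- function(calls) {
  if (!is.list(calls) || length(calls) == 0) {
    abort("`calls` must be a non-empty named list of per-condition pair sets")
  }
  if (length(calls) == 1) {
    warn("single condition supplied: returning its pairs unchanged")
    return(as_tibble(calls[[1]]))
  }
  keys <- map(calls, function(x) paste(x$gene_left, x$gene_right, sep = "\r"))
  shared <- Reduce(intersect, keys)
  first <- as_tibble(calls[[1]])
  out <- first[match(shared, keys[[1]]), c("gene_left", "gene_right")]
  arrange(out, .data$gene_left, .data$gene_right)
}

#' Extract validated polycistronic gene pairs
#'
#' @param transcripts A transcript tibble after [validate_polycistronic()].
#' @return A tibble with one row per adjacent gene pair inside a validated
#'   polycistronic transcript (`gene_left`, `gene_right`, `transcript_id` when
#'   present).
#' @export
polycistronic_pairs <- function(transcripts) {
  v <- filter(transcripts, .data$polycistronic_status == "validated",
              lengths(.data$covered_genes) >= 2)
  if (nrow(v) == 0) {
    return(tibble(gene_left = character(), gene_right = character()))
  }
  bind_rows(map(seq_len(nrow(v)), function(i) {
    g <- v$covered_genes[[i]]
    tibble(gene_left = g[-length(g)], gene_right = g[-1])
  })) |> distinct()
}

#' Write a UTR comparison report as a tab-separated table
#'
#' @param comparison A `tx_utr_comparison` from [compare_utrs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_utr_comparison <- function(comparison, path) {
  write.table(as.data.frame(comparison), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
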