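#' Assemble a transcriptome from aligned reads and an annotation
#'
#' Runs the full reconstruction: strand-specific coverage, block building,
#' gene assignment, adaptive intergenic-block joining, intron calling,
#' within-gene merging, tail trimming, polycistronic validation, UTR
#' measurement and classification. The result is one tibble row per final
#' transcript.
#'
#' @param reads A read tibble from [read_alignments()] or [sim_reads()].
#' @param annotation An annotation tibble from [read_annotation()].
#' @param chrom_lengths Named integer vector; defaults to the
#'   `chrom_lengths` attribute of `reads`.
#' @param params An [assembly_params()] object.
#' @return A transcript tibble: `transcript_id`, `chrom`, `strand`, `start`,
#'   `end`, `mean_coverage` (rounded to 3 decimals), `covered_genes`,
#'   `introns`, `utr5_len`, `utr3_len`, `class_label`,
#'   `polycistronic_status`, `anti_gene`, `closest_gene`. The learned gap
#'   statistics are attached as attribute `gap_stats`.
#' @examples
#' sim <- sim_genome(n_genes = 2, seed = 7)
#' reads <- sim_reads(sim, depth = 30, seed = 7)
#' tx <- assemble_transcriptome(reads, sim$annotation)
#' tx[, c("start", "end", "utr5_len", "utr3_len", "class_label")]
#' @export
assemble_transcriptome <- function(reads, annotation, chrom_lengths = NULL,
                                   params = assembly_params()) {
  params <- as_params(params)
  chrom_lengths <- chrom_lengths %||% attr(reads, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    abort("`chrom_lengths` missing and not attached to `reads`")
  }
  coverage <- build_coverage(reads, chrom_lengths)
  blocks <- build_blocks(reads, params) |>
    classify_blocks(annotation)
  stats <- compute_gap_stats(blocks)
  blocks <- join_intergenic_blocks(blocks, params, stats = stats)
  introns <- detect_introns(reads, coverage, params)
  tx <- merge_within_gene(blocks, introns, annotation, coverage) |>
    trim_ends(coverage, params) |>
    validate_polycistronic(coverage, annotation, params) |>
    compute_utrs(annotation) |>
    classify_transcripts(annotation, params) |>
    finalize_transcripts()
  attr(tx, "gap_stats") <- stats
  tx
}

finalize_transcripts <- function(tx) {
  if (nrow(tx) == 0) return(empty_transcripts())
  tx |>
    arrange(.data$chrom, .data$start, .data$strand) |>
    mutate(transcript_id = sprintf("tx%05d", row_number()),
           mean_coverage = round(.data$mean_coverage, 3)) |>
    select("transcript_id", "chrom", "strand", "start", "end",
           "mean_coverage", "covered_genes", "introns", "utr5_len",
           "utr3_len", "class_label", "polycistronic_status", "anti_gene",
           "closest_gene")
}

#' Assemble a transcriptome from files
#'
#' File-level wrapper around the pipeline: reads alignments (SAM/BAM) and a
#' GFF3 annotation, checks that both agree on chromosome names, assembles,
#' and writes `transcripts.gff`, per-chromosome coverage tracks,
#' `classes.tsv` and a `run_log.txt` recording every effective parameter.
#'
#' @param alignments Path to a SAM or BAM file.
#' @param annotation_gff Path to a GFF3 annotation.
#' @param out_dir Output directory (created if missing).
#' @param params An [assembly_params()] object.
#' @return The transcript tibble, invisibly.
#' @export
assemble_files <- function(alignments, annotation_gff, out_dir,
                           params = assembly_params()) {
  params <- as_params(params)
  annotation <- read_annotation(annotation_gff)
  reads <- read_alignments(alignments,
                           max_spliced_distance = params$max_spliced_distance,
                           small_deletion_max = params$small_deletion_max)
  chrom_lengths <- attr(reads, "chrom_lengths")
  shared <- intersect(names(chrom_lengths), unique(annotation$chrom))
  if (length(shared) == 0) {
    abort(paste0(
      "no chromosome name shared between alignments and annotation\n",
      "  alignments: ", paste(names(chrom_lengths), collapse = ", "), "\n",
      "  annotation: ", paste(unique(annotation$chrom), collapse = ", ")))
  }
  reads <- filter(reads, .data$chrom %in% shared)
  attr(reads, "chrom_lengths") <- chrom_lengths[shared]

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tx <- assemble_transcriptome(reads, annotation, chrom_lengths[shared],
                               params)
  coverage <- build_coverage(reads, chrom_lengths[shared])
  write_transcripts_gff(tx, file.path(out_dir, "transcripts.gff"))
  write_coverage_tracks(coverage, file.path(out_dir, "coverage"))
  write_class_summary(class_summary(tx), file.path(out_dir, "classes.tsv"))
  write_run_log(params, file.path(out_dir, "run_log.txt"),
                alignments = alignments, annotation = annotation_gff)
  invisible(tx)
}

write_run_log <- function(params, path, ...) {
  extra <- list(...)
  lines <- c(sprintf("%s=%s", names(extra), unlist(extra)),
             sprintf("%s=%s", names(params),
                     vapply(params, format, character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Compare assembled transcriptomes from files
#'
#' Reads two or more transcript GFFs written by [assemble_files()], compares
#' 5'-UTR lengths across samples and detects conserved antisense transcripts;
#' writes `utr_compare.tsv` and `conserved_sauts.txt`.
#'
#' @param gffs Named character vector of transcript GFF paths (names are
#'   sample labels; basenames are used when unnamed).
#' @param out_dir Output directory.
#' @param ortholog_tsv Optional two-column TSV (`gene_id`, `group_id`).
#' @param utr_diff_threshold,min_coverage,highly_variable_min Passed to
#'   [compare_utrs()].
#' @return A list with elements `utr` (the comparison tibble) and `sauts`
#'   (conserved-SAUT gene vector), invisibly.
#' @export
compare_files <- function(gffs, out_dir, ortholog_tsv = NULL,
                          utr_diff_threshold = 50, min_coverage = 20,
                          highly_variable_min = 6) {
  if (length(gffs) < 2) abort("at least two transcript GFFs are required")
  nm <- names(gffs) %||% basename(gffs)
  if (is.null(names(gffs))) names(gffs) <- nm
  samples <- map(gffs, read_transcripts_gff)
  omap <- NULL
  if (!is.null(ortholog_tsv)) {
    omap <- as_tibble(read.table(ortholog_tsv, sep = "\t", header = FALSE,
                                 col.names = c("gene_id", "group_id"),
                                 colClasses = "character"))
  }
  cmp <- compare_utrs(samples, utr_diff_threshold = utr_diff_threshold,
                      min_coverage = min_coverage,
                      highly_variable_min = highly_variable_min,
                      ortholog_map = omap)
  sauts <- conserved_sauts(samples, ortholog_map = omap)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_utr_comparison(cmp, file.path(out_dir, "utr_compare.tsv"))
  writeLines(sauts, file.path(out_dir, "conserved_sauts.txt"))
  invisible(list(utr = cmp, sauts = sauts))
}

#' Simulate a dataset to files
#'
#' Generates a toy genome and reads ([sim_genome()], [sim_reads()]) and
#' writes `reads.sam`, `annotation.gff3` and `truth.tsv` into `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_genes Number of coding genes.
#' @param ... Further arguments split between [sim_genome()] and
#'   [sim_reads()] by name.
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_files <- function(out_dir, seed = 1, n_genes = 20, ...) {
  dots <- list(...)
  g_args <- dots[names(dots) %in% names(formals(sim_genome))]
  r_args <- dots[names(dots) %in% names(formals(sim_reads))]
  unknown <- setdiff(names(dots), c(names(g_args), names(r_args)))
  if (length(unknown)) {
    abort(paste0("unknown simulation parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  sim <- do.call(sim_genome, c(list(n_genes = n_genes, seed = seed), g_args))
  reads <- do.call(sim_reads, c(list(sim = sim, seed = seed), r_args))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(sam = file.path(out_dir, "reads.sam"),
             gff = file.path(out_dir, "annotation.gff3"),
             truth = file.path(out_dir, "truth.tsv"))
  write_sam(reads, sim$chrom_lengths, files[["sam"]])
  write_annotation_gff(sim$annotation, files[["gff"]])
  write_truth_tsv(sim, files[["truth"]])
  invisible(files)
}
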