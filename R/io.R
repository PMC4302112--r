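#' Read strand-specific single-end alignments
#'
#' Loads uniquely mapped primary alignments from a SAM or BAM file and returns
#' one row per aligned genomic segment, 1-based inclusive. Gapped alignments
#' (reference skips) become multi-segment, "spliced" reads; skips at or below
#' `small_deletion_max` are treated as alignment deletions and fused into a
#' contiguous segment; reads with any skip longer than `max_spliced_distance`
#' are discarded. Unmapped, secondary and supplementary records are skipped, as
#' the protocol relies on uniquely mapped shotgun reads.
#'
#' @param path Path to a SAM or BAM file.
#' @param max_spliced_distance Maximum allowed reference skip (bases).
#' @param small_deletion_max Reference skips at or below this length are fused.
#' @param chroms Optional character vector of expected chromosome names
#'   (typically `unique(annotation$chrom)`); alignments on other chromosomes
#'   are dropped with a warning.
#' @return A tibble with columns `read_id`, `chrom`, `strand`, `start`, `end`,
#'   `segment`, `n_segments`, and an attribute `chrom_lengths` (named integer
#'   vector from the file header).
#' @seealso [build_coverage()], [build_blocks()]
#' @export
read_alignments <- function(path, max_spliced_distance = 1000,
                            small_deletion_max = 10, chroms = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read alignment file: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag, what = "qname"))
  chrom_lengths <- GenomeInfoDb::seqlengths(ga)

  if (length(ga) == 0) {
    out <- tibble(read_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  segment = integer(), n_segments = integer())
    attr(out, "chrom_lengths") <- chrom_lengths
    return(out)
  }

  seg <- GenomicAlignments::extractAlignmentRangesOnReference(
    GenomicAlignments::cigar(ga), pos = BiocGenerics::start(ga),
    drop.D.ranges = FALSE)
  n_per <- S4Vectors::elementNROWS(seg)
  flat <- unlist(seg, use.names = FALSE)
  idx <- rep(seq_along(ga), n_per)

  reads <- tibble(
    read_id = S4Vectors::mcols(ga)$qname[idx],
    chrom = as.character(GenomeInfoDb::seqnames(ga))[idx],
    strand = as.character(BiocGenerics::strand(ga))[idx],
    start = BiocGenerics::start(flat),
    end = BiocGenerics::end(flat),
    .row = idx
  )

  # fuse segments across short skips, then apply the spliced-distance cap
  reads <- reads |>
    group_by(.data$.row) |>
    mutate(gap_prev = .data$start - lag(.data$end) - 1L,
           piece = cumsum(is.na(.data$gap_prev) |
                            .data$gap_prev > small_deletion_max)) |>
    group_by(.data$.row, .data$piece) |>
    summarise(read_id = first(.data$read_id), chrom = first(.data$chrom),
              strand = first(.data$strand), start = min(.data$start),
              end = max(.data$end), .groups = "drop_last") |>
    mutate(gap_prev = .data$start - lag(.data$end) - 1L) |>
    filter(all(is.na(.data$gap_prev) | .data$gap_prev <= max_spliced_distance)) |>
    mutate(segment = row_number(), n_segments = n()) |>
    ungroup() |>
    select("read_id", "chrom", "strand", "start", "end", "segment",
           "n_segments")

  if (!is.null(chroms)) {
    bad <- setdiff(unique(reads$chrom), chroms)
    if (length(bad)) {
      warn(paste0("skipping alignments on chromosomes absent from the ",
                  "annotation: ", paste(bad, collapse = ", ")))
      reads <- filter(reads, .data$chrom %in% chroms)
    }
  }
  attr(reads, "chrom_lengths") <- chrom_lengths
  reads
}

#' Read a gene annotation from GFF3
#'
#' Imports gene-level features and returns one gene model per row. The feature
#' class is inferred from the GFF `type` (or a `biotype`/`gene_biotype`
#' attribute when the type is a bare `gene`): tRNA features map to `tRNA`,
#' other non-coding types to `other_ncRNA`, and everything else defaults to
#' `protein_coding`.
#'
#' @param path Path to a GFF3 file with gene-level features.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `feature_class`, `standard_name`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read annotation file: ", path))
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  keep <- grepl("gene|RNA", type) & !type %in% c("mRNA", "transcript")
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0) abort("annotation contains no gene-level features")

  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    bad <- if (is.null(ids)) seq_along(gr) else which(is.na(ids))
    abort(paste0("annotation feature(s) without an ID attribute: record(s) ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated gene ID(s) in annotation: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }

  biotype <- gr$biotype %||% gr$gene_biotype %||% rep(NA_character_, length(gr))
  cls <- dplyr::case_when(
    grepl("tRNA", type) | grepl("tRNA", biotype) ~ "tRNA",
    grepl("sno|snRNA|ncRNA|rRNA", type) ~ "other_ncRNA",
    !is.na(biotype) & biotype != "protein_coding" ~ "other_ncRNA",
    TRUE ~ "protein_coding"
  )
  std <- gr$Name %||% rep(NA_character_, length(gr))

  ann <- tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    feature_class = cls,
    standard_name = as.character(std)
  )
  if (any(ann$end < ann$start)) abort("annotation feature with end < start")
  if (!all(ann$strand %in% c("+", "-"))) {
    abort("annotation features must be stranded (+ or -)")
  }
  arrange(ann, .data$chrom, .data$start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write assembled transcripts as GFF3
#'
#' Emits one GFF3 line per transcript in the assembler's reporting dialect:
#' coding transcripts carry the covered gene ID(s) as `Name`, antisense
#' non-coding transcripts are named `ncRNA_anti_<geneID>`, and intergenic
#' non-coding transcripts `ncRNAs_<closestGeneID>`; transcript length and mean
#' coverage are emitted as `note=` entries. [read_transcripts_gff()] restores
#' the records exactly.
#'
#' @param transcripts A transcript tibble from [assemble_transcriptome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff <- function(transcripts, path) {
  hdr <- "##gff-version 3"
  if (nrow(transcripts) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  t <- transcripts
  name <- transcript_display_name(t)
  introns <- map_chr(t$introns, function(iv) {
    if (is.null(iv) || nrow(iv) == 0) return("")
    paste(sprintf("%d-%d", iv$donor, iv$acceptor), collapse = ",")
  })
  genes <- map_chr(t$covered_genes, paste, collapse = ",")
  attrs <- sprintf(
    paste0("ID=%s;Name=%s;class=%s;status=%s;genes=%s;utr5=%s;utr3=%s;",
           "introns=%s;note=length %d;note=coverage %s"),
    t$transcript_id, name, t$class_label, t$polycistronic_status, genes,
    fmt_na(t$utr5_len), fmt_na(t$utr3_len), introns,
    t$end - t$start + 1L, format(t$mean_coverage, trim = TRUE))
  lines <- sprintf("%s\ttxblocks\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                   t$chrom, t$start, t$end, t$strand, attrs)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

fmt_na <- function(x) ifelse(is.na(x), "NA", as.character(x))

transcript_display_name <- function(t) {
  dplyr::case_when(
    t$class_label == "SAUT" ~ paste0("ncRNA_anti_", t$anti_gene),
    t$class_label %in% c("SUT", "intronic_ncRNA") ~
      paste0("ncRNAs_", t$closest_gene),
    lengths(t$covered_genes) > 0 ~ map_chr(t$covered_genes, paste,
                                           collapse = ","),
    TRUE ~ t$transcript_id
  )
}

#' Read transcripts written by [write_transcripts_gff()]
#'
#' @param path Path to a GFF3 file in the assembler's dialect.
#' @return A transcript tibble with the same columns as
#'   [assemble_transcriptome()] output.
#' @export
read_transcripts_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_transcripts())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) abort("malformed GFF line: expected 9 columns")
  f <- do.call(rbind, f)
  attr_field <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    map_chr(m, function(x) if (length(x) == 2) x[2] else NA_character_)
  }
  a <- f[, 9]
  name <- attr_field(a, "Name")
  cls <- attr_field(a, "class")
  genes <- attr_field(a, "genes")
  intr <- attr_field(a, "introns")
  cov <- as.numeric(sub(".*note=coverage ([^;]*).*", "\\1", a))
  tibble(
    transcript_id = attr_field(a, "ID"),
    chrom = f[, 1],
    strand = f[, 7],
    start = as.integer(f[, 4]),
    end = as.integer(f[, 5]),
    mean_coverage = cov,
    covered_genes = map(genes, function(g) {
      if (is.na(g) || g == "") character() else strsplit(g, ",")[[1]]
    }),
    introns = map(intr, parse_intron_field),
    utr5_len = suppressWarnings(as.integer(attr_field(a, "utr5"))),
    utr3_len = suppressWarnings(as.integer(attr_field(a, "utr3"))),
    class_label = cls,
    polycistronic_status = attr_field(a, "status"),
    anti_gene = ifelse(cls == "SAUT", sub("^ncRNA_anti_", "", name),
                       NA_character_),
    closest_gene = ifelse(cls %in% c("SUT", "intronic_ncRNA"),
                          sub("^ncRNAs_", "", name), NA_character_)
  )
}

parse_intron_field <- function(x) {
  if (is.na(x) || x == "") {
    return(tibble(donor = integer(), acceptor = integer()))
  }
  parts <- strsplit(strsplit(x, ",")[[1]], "-", fixed = TRUE)
  tibble(donor = as.integer(map_chr(parts, 1)),
         acceptor = as.integer(map_chr(parts, 2)))
}

empty_transcripts <- function() {
  tibble(transcript_id = character(), chrom = character(), strand = character(),
         start = integer(), end = integer(), mean_coverage = numeric(),
         covered_genes = list(), introns = list(), utr5_len = integer(),
         utr3_len = integer(), class_label = character(),
         polycistronic_status = character(), anti_gene = character(),
         closest_gene = character())
}

#' Write per-base coverage tracks
#'
#' Writes one plain-text file per (chromosome, strand) with one total depth
#' value (unspliced plus spliced) per line, line *k* holding the depth at
#' position *k* — the userplot convention genome browsers such as Artemis read
#' directly.
#'
#' @param coverage A coverage tibble from [build_coverage()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_coverage_tracks <- function(coverage, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(coverage))
  for (i in seq_len(nrow(coverage))) {
    tag <- if (coverage$strand[i] == "+") "fwd" else "rev"
    files[i] <- file.path(out_dir, paste0(coverage$chrom[i], ".", tag, ".cov"))
    total <- coverage$depth[[i]] + coverage$spliced_depth[[i]]
    writeLines(as.character(total), files[i])
  }
  invisible(files)
}

#' Write a gene annotation as GFF3
#'
#' Companion writer for annotations produced by [sim_genome()]; output is
#' readable by [read_annotation()].
#'
#' @param annotation An annotation tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff <- function(annotation, path) {
  type <- dplyr::recode(annotation$feature_class, tRNA = "tRNA_gene",
                        other_ncRNA = "ncRNA_gene", .default = "gene")
  lines <- sprintf("%s\ttxblocks\t%s\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                   annotation$chrom, type, annotation$start, annotation$end,
                   annotation$strand, annotation$gene_id,
                   annotation$feature_class)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write reads as SAM
#'
#' Serialises a read tibble (one row per segment) as single-end SAM records
#' with correct strand flags and `N`-gapped CIGAR strings for spliced reads,
#' so simulated alignments can round-trip through [read_alignments()].
#'
#' @param reads A read tibble (columns as returned by [read_alignments()]).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  if (nrow(reads) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  rec <- reads |>
    arrange(.data$chrom, .data$read_id, .data$segment) |>
    group_by(.data$read_id, .data$chrom, .data$strand) |>
    summarise(pos = first(.data$start), cigar = sam_cigar(.data$start, .data$end),
              .groups = "drop") |>
    arrange(.data$chrom, .data$pos, .data$read_id)
  flag <- ifelse(rec$strand == "-", 16L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                   rec$read_id, flag, rec$chrom, rec$pos, rec$cigar)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

sam_cigar <- function(start, end) {
  m <- sprintf("%dM", end - start + 1L)
  if (length(start) == 1) return(m)
  gaps <- start[-1] - end[-length(end)] - 1L
  paste0(paste0(m[-length(m)], sprintf("%dN", gaps), collapse = ""),
         m[length(m)])
}
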