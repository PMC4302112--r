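# Builders for in-memory fixtures and the independent block oracle.

# one unspliced read (a single segment)
r1 <- function(id, start, end, strand = "+", chrom = "chrT") {
  tibble::tibble(read_id = id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 segment = 1L, n_segments = 1L)
}

# n identical stacked unspliced reads
stack_reads <- function(n, start, end, strand = "+", chrom = "chrT",
                        prefix = "r") {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    r1(sprintf("%s_%d_%d", prefix, start, i), start, end, strand, chrom)
  }))
}

# one spliced read from a list of (start, end) segments
r_spliced <- function(id, segs, strand = "+", chrom = "chrT") {
  dplyr::bind_rows(lapply(seq_along(segs), function(k) {
    tibble::tibble(read_id = id, chrom = chrom, strand = strand,
                   start = as.integer(segs[[k]][1]),
                   end = as.integer(segs[[k]][2]),
                   segment = k, n_segments = length(segs))
  }))
}

# coverage tibble for one chromosome from explicit depth vectors
manual_coverage <- function(chrom, plus_depth, minus_depth = NULL,
                            plus_spliced = NULL, minus_spliced = NULL) {
  len <- length(plus_depth)
  minus_depth <- minus_depth %||% integer(len)
  tibble::tibble(
    chrom = chrom, strand = c("+", "-"), length = len,
    depth = list(as.integer(plus_depth), as.integer(minus_depth)),
    spliced_depth = list(as.integer(plus_spliced %||% integer(len)),
                         as.integer(minus_spliced %||% integer(len))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built block tibble row
mk_block <- function(start, end, cov, genes = character(), strand = "+",
                     chrom = "chrT", read_count = 10L) {
  tibble::tibble(chrom = chrom, strand = strand, start = as.integer(start),
                 end = as.integer(end), read_count = read_count,
                 mean_coverage = cov, genes = list(genes))
}

mk_gene <- function(gene_id, start, end, strand = "+", chrom = "chrT",
                    feature_class = "protein_coding") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 feature_class = feature_class,
                 standard_name = NA_character_)
}

# minimal draft transcript row (pre-classification)
mk_draft <- function(start, end, genes = character(), cov = 30,
                     strand = "+", chrom = "chrT",
                     introns = tibble::tibble(donor = integer(),
                                              acceptor = integer()),
                     status = "monocistronic") {
  tibble::tibble(chrom = chrom, strand = strand, start = as.integer(start),
                 end = as.integer(end), covered_genes = list(genes),
                 introns = list(introns), mean_coverage = cov,
                 polycistronic_status = status)
}

# minimal classified transcript row for the comparative layer
mk_tx <- function(gene = NULL, utr5 = NA, cov = 30,
                  class_label = "protein_coding", anti_gene = NA_character_,
                  start = 1000L, end = 2000L, strand = "+", chrom = "chrT") {
  tibble::tibble(
    transcript_id = paste0("tx_", gene %||% anti_gene %||% "x"),
    chrom = chrom, strand = strand, start = start, end = end,
    mean_coverage = cov,
    covered_genes = list(if (is.null(gene)) character() else gene),
    introns = list(tibble::tibble(donor = integer(), acceptor = integer())),
    utr5_len = as.integer(utr5), utr3_len = NA_integer_,
    class_label = class_label, polycistronic_status = "monocistronic",
    anti_gene = anti_gene, closest_gene = NA_character_)
}

# Independent brute-force block oracle: build the interval graph over
# unspliced segments (edge when two segments on one chrom/strand overlap or
# are separated by a gap strictly shorter than min_gap), take connected
# components by label propagation, and apply the read-count filter.
oracle_blocks <- function(reads, min_gap, min_reads) {
  segs <- reads[reads$n_segments == 1, ]
  out <- list()
  for (key in unique(paste(segs$chrom, segs$strand))) {
    s <- segs[paste(segs$chrom, segs$strand) == key, ]
    n <- nrow(s)
    comp <- seq_len(n)
    adj <- outer(seq_len(n), seq_len(n), function(i, j) {
      gap <- pmax(s$start[j] - s$end[i] - 1L, s$start[i] - s$end[j] - 1L)
      gap < min_gap
    })
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        m <- min(comp[adj[i, ]])
        if (m < comp[i]) {
          comp[comp == comp[i]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cmp in unique(comp)) {
      idx <- comp == cmp
      if (sum(idx) < min_reads) next
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = s$chrom[1], strand = s$strand[1],
        start = min(s$start[idx]), end = max(s$end[idx]),
        read_count = sum(idx))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          read_count = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, strand, start)
}

# a junction locus: unspliced reads stacked on both flanks (boundary depth)
# plus `support` spliced reads sharing the exact donor/acceptor
make_junction_reads <- function(donor, acceptor, support, boundary_depth,
                                strand = "+", chrom = "chrT") {
  dplyr::bind_rows(
    stack_reads(boundary_depth, donor - 50, donor - 1, strand, chrom,
                prefix = paste0("l", donor)),
    stack_reads(boundary_depth, acceptor + 1, acceptor + 50, strand, chrom,
                prefix = paste0("r", donor)),
    dplyr::bind_rows(lapply(seq_len(support), function(i) {
      r_spliced(sprintf("sp%d_%d", donor, i),
                list(c(donor - 25, donor - 1), c(acceptor + 1, acceptor + 25)),
                strand, chrom)
    })))
}

# random unspliced read set on a couple of strands, for property tests
random_reads <- function(n, genome_len = 5000, read_len = 50, seed = 1) {
  set.seed(seed)
  start <- sample.int(genome_len - read_len, n, replace = TRUE)
  tibble::tibble(read_id = sprintf("rr%04d", seq_len(n)), chrom = "chrT",
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 start = as.integer(start),
                 end = as.integer(start + read_len - 1L),
                 segment = 1L, n_segments = 1L)
}
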