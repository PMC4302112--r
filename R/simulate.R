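#' Generate a toy annotated genome with a truth transcriptome
#'
#' Lays out non-overlapping transcription units along a single synthetic
#' chromosome and returns both the gene annotation (gene spans *without*
#' UTRs, so UTR recovery is a genuine test) and the truth transcripts (gene
#' span extended by drawn 5'/3'-UTRs, strand-aware). Optional extras plant the
#' structures the downstream layers must recognise: introns inside coding
#' genes, antisense ncRNAs inside coding genes (truth SAUTs), standalone
#' intergenic ncRNAs (truth SUTs), tRNA and other ncRNA genes, and one
#' bicistronic unit in which two adjacent same-strand genes share a single
#' truth transcript.
#'
#' @param n_genes Number of protein-coding genes (>= 1).
#' @param seed Integer seed; fixed seed gives identical truth.
#' @param chrom Chromosome name.
#' @param intergenic Range (bases) of spacing drawn between transcription
#'   units.
#' @param gene_length,utr5_range,utr3_range Ranges the gene lengths and UTR
#'   lengths are drawn from (uniform).
#' @param intron_frac Fraction of coding genes given one intron (0 disables).
#' @param intron_length Range of intron lengths.
#' @param n_antisense Number of coding genes that also carry an antisense
#'   ncRNA transcript.
#' @param n_intergenic Number of standalone intergenic ncRNA transcripts.
#' @param n_trna,n_ncrna Numbers of tRNA / other ncRNA genes (UTR-less).
#' @param bicistronic_pair Number of bicistronic two-gene units to add
#'   (`TRUE` = 1).
#' @param bicistronic_gap Intergenic bases between the two genes of the
#'   bicistronic unit.
#' @return A list of class `tx_sim_truth` with elements `truth` (tibble of
#'   truth transcripts), `annotation` (gene tibble as [read_annotation()]
#'   returns), and `chrom_lengths`.
#' @examples
#' g <- sim_genome(n_genes = 3, seed = 1)
#' g$truth[, c("tx_id", "strand", "start", "end", "utr5", "utr3")]
#' @export
sim_genome <- function(n_genes = 20, seed = 1, chrom = "chrS",
                       intergenic = c(300, 800),
                       gene_length = c(500, 2000),
                       utr5_range = c(20, 200), utr3_range = c(50, 250),
                       intron_frac = 0, intron_length = c(60, 300),
                       n_antisense = 0, n_intergenic = 0,
                       n_trna = 0, n_ncrna = 0,
                       bicistronic_pair = FALSE, bicistronic_gap = 100) {
  if (n_genes < 1) abort("`n_genes` must be >= 1")
  with_seed(seed, {
    units <- list()
    cursor <- 1L + runif_int(1, intergenic)
    add_unit <- function(u) units[[length(units) + 1L]] <<- u

    for (i in seq_len(n_genes)) {
      u5 <- runif_int(1, utr5_range)
      u3 <- runif_int(1, utr3_range)
      glen <- runif_int(1, gene_length)
      st <- sample(c("+", "-"), 1)
      t_start <- cursor
      t_end <- cursor + u5 + glen + u3 - 1L
      if (st == "+") {
        g_start <- t_start + u5; g_end <- t_end - u3
      } else {
        g_start <- t_start + u3; g_end <- t_end - u5
      }
      iv <- tibble(donor = integer(), acceptor = integer())
      if (intron_frac > 0 && runif(1) < intron_frac && glen > 400) {
        ilen <- runif_int(1, intron_length)
        d <- g_start + 100L + runif_int(1, c(0, glen - ilen - 200L))
        iv <- tibble(donor = d, acceptor = d + ilen - 1L)
      }
      add_unit(list(kind = "coding", gene_ids = sprintf("G%04d", i),
                    strand = st, t_start = t_start, t_end = t_end,
                    g_start = g_start, g_end = g_end, utr5 = u5, utr3 = u3,
                    introns = iv, feature_class = "protein_coding"))
      cursor <- t_end + runif_int(1, intergenic)
    }

    for (bi in seq_len(as.integer(bicistronic_pair))) {
      u5 <- runif_int(1, utr5_range); u3 <- runif_int(1, utr3_range)
      l1 <- runif_int(1, gene_length); l2 <- runif_int(1, gene_length)
      st <- sample(c("+", "-"), 1)
      t_start <- cursor
      t_end <- cursor + u5 + l1 + bicistronic_gap + l2 + u3 - 1L
      left5 <- st == "+"
      a_start <- t_start + (if (left5) u5 else u3)
      a_end <- a_start + l1 - 1L
      b_start <- a_end + bicistronic_gap + 1L
      b_end <- b_start + l2 - 1L
      ids <- sprintf("GBIC%02d%s", bi, c("A", "B"))
      add_unit(list(kind = "bicistronic", gene_ids = ids, strand = st,
                    t_start = t_start, t_end = t_end,
                    g_start = c(a_start, b_start), g_end = c(a_end, b_end),
                    utr5 = u5, utr3 = u3,
                    introns = tibble(donor = integer(), acceptor = integer()),
                    feature_class = "protein_coding"))
      cursor <- t_end + runif_int(1, intergenic)
    }

    for (i in seq_len(n_trna + n_ncrna)) {
      glen <- runif_int(1, c(80, 300))
      st <- sample(c("+", "-"), 1)
      cls <- if (i <= n_trna) "tRNA" else "other_ncRNA"
      add_unit(list(kind = "small_gene",
                    gene_ids = sprintf("%s%03d",
                                       if (cls == "tRNA") "T" else "N", i),
                    strand = st, t_start = cursor, t_end = cursor + glen - 1L,
                    g_start = cursor, g_end = cursor + glen - 1L,
                    utr5 = 0L, utr3 = 0L,
                    introns = tibble(donor = integer(), acceptor = integer()),
                    feature_class = cls))
      cursor <- cursor + glen + runif_int(1, intergenic)
    }

    for (i in seq_len(n_intergenic)) {
      len <- runif_int(1, c(200, 600))
      st <- sample(c("+", "-"), 1)
      add_unit(list(kind = "sut", gene_ids = character(), strand = st,
                    t_start = cursor, t_end = cursor + len - 1L,
                    g_start = integer(), g_end = integer(),
                    utr5 = NA_integer_, utr3 = NA_integer_,
                    introns = tibble(donor = integer(), acceptor = integer()),
                    feature_class = NA_character_))
      cursor <- cursor + len + runif_int(1, intergenic)
    }

    chrom_len <- cursor + 500L

    truth <- bind_rows(map(units, function(u) {
      tibble(tx_id = paste0("tx_", paste(u$gene_ids, collapse = "_"),
                            if (u$kind == "sut") sprintf("SUT%06d", u$t_start)
                            else ""),
             chrom = chrom, strand = u$strand,
             start = u$t_start, end = u$t_end,
             class = switch(u$kind, coding = , bicistronic = "protein_coding",
                            small_gene = if (u$feature_class == "tRNA")
                              "tRNA" else "other_ncRNA",
                            sut = "SUT"),
             gene_ids = list(u$gene_ids),
             utr5 = u$utr5, utr3 = u$utr3,
             introns = list(u$introns),
             bicistronic = u$kind == "bicistronic")
    }))

    # antisense ncRNAs inside the bodies of sampled coding genes
    if (n_antisense > 0) {
      coding <- which(map_chr(units, "kind") == "coding")
      if (n_antisense > length(coding)) {
        abort("`n_antisense` exceeds the number of coding genes")
      }
      hosts <- sort(sample(coding, n_antisense))
      anti <- bind_rows(map(units[hosts], function(u) {
        glen <- u$g_end - u$g_start + 1L
        alen <- max(150L, as.integer(0.6 * glen))
        a_start <- u$g_start + (glen - alen) %/% 2L
        tibble(tx_id = paste0("tx_anti_", u$gene_ids),
               chrom = chrom, strand = if (u$strand == "+") "-" else "+",
               start = a_start, end = a_start + alen - 1L,
               class = "SAUT", gene_ids = list(character()),
               utr5 = NA_integer_, utr3 = NA_integer_,
               introns = list(tibble(donor = integer(), acceptor = integer())),
               bicistronic = FALSE, anti_gene = u$gene_ids)
      }))
      truth$anti_gene <- NA_character_
      truth <- bind_rows(truth, anti)
    } else {
      truth$anti_gene <- NA_character_
    }

    annotation <- bind_rows(map(units, function(u) {
      if (length(u$gene_ids) == 0) return(NULL)
      tibble(gene_id = u$gene_ids, chrom = chrom,
             start = as.integer(u$g_start), end = as.integer(u$g_end),
             strand = u$strand, feature_class = u$feature_class,
             standard_name = NA_character_)
    })) |> arrange(.data$chrom, .data$start)

    structure(list(truth = arrange(truth, .data$start),
                   annotation = annotation,
                   chrom_lengths = setNames(as.integer(chrom_len), chrom)),
              class = "tx_sim_truth")
  })
}

#' @export
print.tx_sim_truth <- function(x, ...) {
  cat("<tx_sim_truth> ", nrow(x$truth), "truth transcripts,",
      nrow(x$annotation), "annotated genes,",
      sum(x$chrom_lengths), "bases\n")
  invisible(x)
}

#' Simulate strand-specific aligned reads from a truth transcriptome
#'
#' Samples fixed-length single-end reads along each truth transcript's exonic
#' sequence and maps them back to the genome, so reads crossing a truth intron
#' come out as two-segment spliced alignments. The generator reproduces the
#' characteristic pathologies of strand-specific short-read yeast libraries:
#' preferred start windows ("hotspots") separated by low-coverage regions,
#' short zero-coverage gap windows inside transcripts, uniform background
#' noise reads on random strands, and — when `polyA_loss` is on — removal of
#' every read overlapping the 3'-terminal `read_length` bases of a transcript,
#' the footprint that truncates assembled 3'-UTRs.
#'
#' @param sim A `tx_sim_truth` from [sim_genome()].
#' @param read_length Read length in bases (>= 20).
#' @param depth Target per-base depth: a scalar, a vector along truth
#'   transcripts, or `NULL` to draw per-transcript depths from a log-normal
#'   distribution with `depth_meanlog`/`depth_sdlog`.
#' @param depth_meanlog,depth_sdlog Log-normal depth parameters used when
#'   `depth` is `NULL`.
#' @param hotspot_n,hotspot_width,hotspot_frac Number/width of preferred-start
#'   windows per transcript and the fraction of reads drawn from them.
#' @param gap_n,gap_length Number of zero-coverage windows injected per
#'   transcript and the range their lengths are drawn from; reads overlapping
#'   a window are deleted.
#' @param noise_rate Background reads per kilobase of genome (uniform
#'   positions, random strand), labelled `noise_*` in the read names.
#' @param polyA_loss Drop reads overlapping each transcript's 3'-terminal
#'   `read_length` bases?
#' @param seed Integer seed; fixed seed gives identical reads.
#' @return A read tibble in [read_alignments()] layout with attributes
#'   `chrom_lengths` and `depths` (the per-transcript target depths used).
#' @export
sim_reads <- function(sim, read_length = 50, depth = 30,
                      depth_meanlog = log(30), depth_sdlog = 0.5,
                      hotspot_n = 0, hotspot_width = 100, hotspot_frac = 0.5,
                      gap_n = 0, gap_length = c(10, 20),
                      noise_rate = 0, polyA_loss = FALSE, seed = 1) {
  if (read_length < 20) abort("`read_length` must be >= 20")
  truth <- sim$truth
  with_seed(seed, {
    depths <- if (is.null(depth)) {
      rlnorm(nrow(truth), depth_meanlog, depth_sdlog)
    } else {
      rep_len(depth, nrow(truth))
    }
    pieces <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      pieces[[i]] <- sim_tx_reads(
        truth[i, ], depths[i], read_length, hotspot_n, hotspot_width,
        hotspot_frac, gap_n, gap_length, polyA_loss)
    }
    reads <- bind_rows(pieces)

    genome_len <- sum(sim$chrom_lengths)
    if (noise_rate > 0) {
      n_noise <- rpois(1, noise_rate * genome_len / 1000)
      if (n_noise > 0) {
        ch <- sample(names(sim$chrom_lengths), n_noise, replace = TRUE,
                     prob = sim$chrom_lengths / genome_len)
        st <- sample(c("+", "-"), n_noise, replace = TRUE)
        lens <- sim$chrom_lengths[ch]
        pos <- 1L + as.integer(floor(runif(n_noise) *
                                       (lens - read_length + 1L)))
        reads <- bind_rows(reads, tibble(
          read_id = sprintf("noise_%05d", seq_len(n_noise)),
          chrom = ch, strand = st, start = pos,
          end = pos + as.integer(read_length) - 1L,
          segment = 1L, n_segments = 1L))
      }
    }
    reads <- arrange(reads, .data$chrom, .data$start, .data$read_id,
                     .data$segment)
    attr(reads, "chrom_lengths") <- sim$chrom_lengths
    attr(reads, "depths") <- setNames(depths, truth$tx_id)
    reads
  })
}

# reads for one truth transcript, in exonic coordinate space mapped back to
# the genome through the transcript's intron structure
sim_tx_reads <- function(t, depth, rl, hotspot_n, hotspot_width,
                         hotspot_frac, gap_n, gap_length, polyA_loss) {
  if (depth <= 0) {
    warn(paste0("transcript ", t$tx_id, " has depth 0: no reads generated"))
    return(NULL)
  }
  iv <- t$introns[[1]]
  exonic <- seq.int(t$start, t$end)
  if (nrow(iv) > 0) {
    exonic <- setdiff(exonic, unlist(map2(iv$donor, iv$acceptor, seq.int)))
  }
  L <- length(exonic)
  if (L < rl) return(NULL)
  n_reads <- as.integer(round(depth * L / rl))
  max_start <- L - rl + 1L
  st <- runif_int(n_reads, c(1, max_start))
  if (hotspot_n > 0 && hotspot_frac > 0) {
    ws <- runif_int(hotspot_n, c(1, max(1L, max_start - hotspot_width)))
    hot <- runif(n_reads) < hotspot_frac
    if (any(hot)) {
      w <- sample.int(hotspot_n, sum(hot), replace = TRUE)
      st[hot] <- pmin(ws[w] + runif_int(sum(hot), c(0, hotspot_width - 1L)),
                      max_start)
    }
  }
  # anchor the terminal start positions so truth termini are covered, as they
  # are at study-scale depth; gap/poly-A filters below still apply to anchors
  if (n_reads >= 2) {
    st[1L] <- 1L
    st[n_reads] <- max_start
  }
  keep <- rep(TRUE, n_reads)
  if (gap_n > 0 && L > 2L * rl + max(gap_length) + 2L) {
    placed <- integer(0)  # window starts already placed
    for (k in seq_len(gap_n)) {
      wlen <- runif_int(1, gap_length)
      # keep windows well separated so two never fuse into one longer gap
      ws <- NA_integer_
      for (try in 1:20) {
        cand <- runif_int(1, c(rl + 1L, L - rl - wlen))
        if (!length(placed) ||
            all(abs(placed - cand) > 3L * rl + max(gap_length))) {
          ws <- cand
          break
        }
      }
      if (is.na(ws)) next
      placed <- c(placed, ws)
      keep <- keep & (st + rl - 1L < ws | st > ws + wlen - 1L)
      # pin both window edges with flanking reads so the zero-coverage run
      # is exactly the drawn window, not the window plus sampling dropout
      st <- c(st, ws - rl, ws + wlen)
      keep <- c(keep, TRUE, TRUE)
    }
  }
  if (polyA_loss) {
    if (t$strand == "+") {
      keep <- keep & (st + rl - 1L < L - rl + 1L)
    } else {
      keep <- keep & (st > rl)
    }
  }
  st <- st[keep]
  if (length(st) == 0) return(NULL)
  # map exonic intervals back to the genome; reads whose exonic window is
  # contiguous on the genome are unspliced, the rest straddle a junction
  gs <- exonic[st]
  ge <- exonic[st + rl - 1L]
  ids <- sprintf("%s_r%05d", t$tx_id, seq_along(st))
  contiguous <- (ge - gs) == (rl - 1L)
  out <- tibble(read_id = ids[contiguous], chrom = t$chrom,
                strand = t$strand, start = gs[contiguous],
                end = ge[contiguous], segment = 1L, n_segments = 1L)
  if (all(contiguous)) return(out)
  spliced <- bind_rows(map(which(!contiguous), function(j) {
    gpos <- exonic[st[j]:(st[j] + rl - 1L)]
    brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
    n_seg <- length(brk) - 1L
    tibble(read_id = ids[j], chrom = t$chrom, strand = t$strand,
           start = gpos[brk[-length(brk)] + 1L], end = gpos[brk[-1]],
           segment = seq_len(n_seg), n_segments = n_seg)
  }))
  bind_rows(out, spliced)
}

# uniform integer draw(s) over an inclusive range
runif_int <- function(n, range) {
  lo <- as.integer(range[1]); hi <- as.integer(range[2])
  if (hi < lo) hi <- lo
  lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a strain variant by shifting truth 5'-UTRs
#'
#' Lengthens the 5'-UTR of selected truth transcripts by the given number of
#' bases (strand-aware), leaving the gene annotation untouched — emulating a
#' strain whose transcription start sites moved while its ORFs stayed fixed.
#'
#' @param sim A `tx_sim_truth`.
#' @param genes Character vector of gene IDs whose transcripts shift.
#' @param shift Bases to add to each 5'-UTR (scalar or per gene).
#' @return The modified `tx_sim_truth`.
#' @export
sim_shift_utr5 <- function(sim, genes, shift) {
  shift <- as.integer(rep_len(shift, length(genes)))
  for (k in seq_along(genes)) {
    i <- which(map_lgl(sim$truth$gene_ids, function(g) genes[k] %in% g))
    if (length(i) != 1) abort(paste0("gene not found in truth: ", genes[k]))
    if (sim$truth$strand[i] == "+") {
      sim$truth$start[i] <- sim$truth$start[i] - shift[k]
    } else {
      sim$truth$end[i] <- sim$truth$end[i] + shift[k]
    }
    sim$truth$utr5[i] <- sim$truth$utr5[i] + shift[k]
  }
  if (any(sim$truth$start < 1)) abort("UTR shift runs off the chromosome")
  sim
}

#' Split a truth bicistronic unit into two separate transcripts
#'
#' Replaces one bicistronic truth transcript with two per-gene transcripts —
#' the condition in which the two genes are transcribed independently. With
#' `contiguous = FALSE` the two transcripts leave an untranscribed
#' (zero-coverage) window between them; with `contiguous = TRUE` they abut,
#' so coverage stays continuous but each gene keeps its own depth.
#'
#' @param sim A `tx_sim_truth` built with `bicistronic_pair >= 1`.
#' @param pair Which bicistronic unit to split (1-based).
#' @param margin Bases of the inter-gene interval transcribed on each side
#'   when `contiguous = FALSE`.
#' @param contiguous Make the two transcripts abut instead of leaving a gap.
#' @return The modified `tx_sim_truth`.
#' @export
sim_split_bicistronic <- function(sim, pair = 1, margin = 30,
                                  contiguous = FALSE) {
  idx <- which(sim$truth$bicistronic)
  if (length(idx) < pair) abort("no such bicistronic unit in the truth")
  i <- idx[pair]
  row <- sim$truth[i, ]
  genes <- row$gene_ids[[1]]
  g <- sim$annotation[match(genes, sim$annotation$gene_id), ]
  ord <- order(g$start)
  g <- g[ord, ]; genes <- genes[ord]
  if (contiguous) {
    mid <- (g$end[1] + g$start[2]) %/% 2L
    left_end <- mid; right_start <- mid + 1L
  } else {
    left_end <- g$end[1] + as.integer(margin)
    right_start <- g$start[2] - as.integer(margin)
    if (right_start <= left_end) abort("`margin` too large for the unit's gap")
  }
  halves <- bind_rows(row, row)
  halves$tx_id <- paste0(row$tx_id, c("_L", "_R"))
  halves$end[1] <- left_end
  halves$start[2] <- right_start
  halves$gene_ids <- list(genes[1], genes[2])
  halves$bicistronic <- FALSE
  halves$utr5 <- NA_integer_
  halves$utr3 <- NA_integer_
  sim$truth <- arrange(bind_rows(sim$truth[-i, ], halves), .data$start)
  sim
}

#' Write a truth transcript table as TSV
#'
#' @param sim A `tx_sim_truth` from [sim_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(sim, path) {
  t <- sim$truth |>
    mutate(gene_ids = map_chr(.data$gene_ids, paste, collapse = ","),
           introns = map_chr(.data$introns, function(iv) {
             if (nrow(iv) == 0) "" else
               paste(sprintf("%d-%d", iv$donor, iv$acceptor), collapse = ",")
           }))
  write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
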