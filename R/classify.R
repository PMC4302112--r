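#' Classify transcripts into the six reporting classes
#'
#' Applies the decision cascade: (1) a transcript covering same-strand
#' annotated gene(s) takes its label from the gene's feature class
#' (`protein_coding`, `tRNA`, `other_ncRNA`); (2) otherwise, if more than
#' `antisense_frac` of its length lies antisense to protein-coding genes it is
#' a SAUT (stable antisense untranslated transcript); (3) otherwise, if it
#' lies entirely inside an accepted intron of a same-strand transcript it is
#' an intronic ncRNA; (4) otherwise it is a SUT (stable untranslated
#' transcript, intergenic). Every transcript receives exactly one label.
#'
#' SAUTs record the antisense gene with the largest overlap (`anti_gene`);
#' SUTs and intronic ncRNAs record the annotated gene with the smallest
#' boundary distance on either strand (`closest_gene`; ties resolved toward
#' the downstream gene on the transcript's strand).
#'
#' @param transcripts Transcript tibble (UTRs computed).
#' @param annotation Annotation tibble.
#' @param params An [assembly_params()] object (`antisense_frac`).
#' @return `transcripts` with `class_label`, `anti_gene`, `closest_gene`.
#' @export
classify_transcripts <- function(transcripts, annotation,
                                 params = assembly_params()) {
  params <- as_params(params)
  t <- transcripts
  n <- nrow(t)
  t$class_label <- character(n)
  t$anti_gene <- NA_character_
  t$closest_gene <- NA_character_
  if (n == 0) return(t)
  coding <- annotation[annotation$feature_class == "protein_coding", ]
  for (i in seq_len(n)) {
    genes <- t$covered_genes[[i]]
    if (length(genes) > 0) {
      cls <- annotation$feature_class[match(genes, annotation$gene_id)]
      t$class_label[i] <- if (any(cls == "protein_coding")) {
        "protein_coding"
      } else {
        c(protein_coding = "protein_coding", tRNA = "tRNA",
          other_ncRNA = "other_ncRNA")[[cls[1]]]
      }
      next
    }
    len <- t$end[i] - t$start[i] + 1L
    anti <- coding[coding$chrom == t$chrom[i] &
                     coding$strand != t$strand[i] &
                     coding$start <= t$end[i] & coding$end >= t$start[i], ]
    if (nrow(anti) > 0) {
      ov <- pmin(anti$end, t$end[i]) - pmax(anti$start, t$start[i]) + 1L
      covered <- antisense_covered_bases(anti, t$start[i], t$end[i])
      if (covered > params$antisense_frac * len) {
        t$class_label[i] <- "SAUT"
        t$anti_gene[i] <- anti$gene_id[which.max(ov)]
        next
      }
    }
    host <- host_intron(t, i)
    if (!is.na(host)) {
      t$class_label[i] <- "intronic_ncRNA"
      t$closest_gene[i] <- closest_gene(annotation, t$chrom[i], t$strand[i],
                                        t$start[i], t$end[i])
      next
    }
    t$class_label[i] <- "SUT"
    t$closest_gene[i] <- closest_gene(annotation, t$chrom[i], t$strand[i],
                                      t$start[i], t$end[i])
  }
  t
}

# total bases of [s, e] covered by the union of antisense gene spans
antisense_covered_bases <- function(anti, s, e) {
  if (nrow(anti) == 0) return(0L)
  iv <- IRanges::reduce(IRanges::IRanges(pmax(anti$start, s),
                                         pmin(anti$end, e)))
  sum(BiocGenerics::width(iv))
}

# index of a same-strand transcript whose accepted intron fully contains
# transcript i, or NA
host_intron <- function(t, i) {
  for (j in seq_len(nrow(t))) {
    if (j == i || t$chrom[j] != t$chrom[i] || t$strand[j] != t$strand[i]) next
    iv <- t$introns[[j]]
    if (!is.null(iv) && nrow(iv) > 0 &&
        any(iv$donor <= t$start[i] & iv$acceptor >= t$end[i])) {
      return(j)
    }
  }
  NA_integer_
}

# gene with minimum boundary distance on either strand; ties toward the
# downstream gene on the transcript's strand
closest_gene <- function(annotation, ch, st, s, e) {
  g <- annotation[annotation$chrom == ch, ]
  if (nrow(g) == 0) return(NA_character_)
  dist <- pmax(g$start - e, s - g$end, 0L)
  best <- which(dist == min(dist))
  if (length(best) > 1) {
    downstream <- if (st == "+") g$start[best] >= s else g$end[best] <= e
    if (any(downstream)) best <- best[downstream]
  }
  g$gene_id[best[1]]
}

#' Per-class summary of transcript counts, coverage and length
#'
#' @param transcripts A classified transcript tibble.
#' @return A tibble of class `tx_class_summary` with one row per class:
#'   count, quartiles of mean coverage and of transcript length.
#' @export
class_summary <- function(transcripts) {
  base <- tibble(class_label = TX_CLASSES)
  if (nrow(transcripts) == 0) {
    out <- mutate(base, n = 0L, cov_q25 = NA_real_, cov_median = NA_real_,
                  cov_q75 = NA_real_, len_q25 = NA_real_,
                  len_median = NA_real_, len_q75 = NA_real_)
    return(structure(out, class = c("tx_class_summary", class(out))))
  }
  stats <- transcripts |>
    mutate(length = .data$end - .data$start + 1L) |>
    group_by(.data$class_label) |>
    summarise(n = n(),
              cov_q25 = quantile(.data$mean_coverage, 0.25, names = FALSE),
              cov_median = median(.data$mean_coverage),
              cov_q75 = quantile(.data$mean_coverage, 0.75, names = FALSE),
              len_q25 = quantile(.data$length, 0.25, names = FALSE),
              len_median = median(as.numeric(.data$length)),
              len_q75 = quantile(.data$length, 0.75, names = FALSE),
              .groups = "drop")
  out <- base |>
    left_join(stats, by = "class_label") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  structure(out, class = c("tx_class_summary", class(out)))
}

#' Write a class summary as a tab-separated table
#'
#' @param summary A `tx_class_summary` from [class_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_class_summary <- function(summary, path) {
  write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
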