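#' Plot strand-specific coverage over a region
#'
#' Draws the total per-base depth (unspliced plus spliced) on both strands of
#' one chromosome, the profile a genome browser would show over the written
#' coverage tracks.
#'
#' @param coverage A coverage tibble from [build_coverage()].
#' @param chrom Chromosome to plot.
#' @param from,to Optional region bounds (defaults: whole chromosome).
#' @param transcripts Optional transcript tibble; spans are overlaid as
#'   segments under each strand's profile.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, chrom, from = NULL, to = NULL,
                          transcripts = NULL) {
  rows <- which(coverage$chrom == chrom)
  if (length(rows) == 0) abort(paste0("no coverage for chromosome ", chrom))
  len <- coverage$length[rows[1]]
  from <- from %||% 1L
  to <- to %||% len
  df <- bind_rows(map(rows, function(i) {
    total <- coverage$depth[[i]] + coverage$spliced_depth[[i]]
    tibble(strand = coverage$strand[i], pos = seq.int(from, to),
           depth = total[from:to])
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey35") +
    ggplot2::facet_wrap(~strand, ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c("+" = "forward strand", "-" = "reverse strand"))) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = "depth") +
    ggplot2::theme_minimal()
  if (!is.null(transcripts)) {
    t <- filter(transcripts, .data$chrom == !!chrom,
                .data$start <= to, .data$end >= from)
    if (nrow(t) > 0) {
      p <- p + ggplot2::geom_segment(
        data = t,
        ggplot2::aes(x = .data$start, xend = .data$end, y = -1, yend = -1,
                     colour = .data$class_label),
        linewidth = 2, inherit.aes = FALSE) +
        ggplot2::labs(colour = "class")
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a transcript class summary
#'
#' Bar chart of transcript counts per class, with median coverage printed
#' above each bar.
#'
#' @param object A `tx_class_summary` from [class_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tx_class_summary <- function(object, ...) {
  df <- mutate(as_tibble(object),
               class_label = factor(.data$class_label, levels = TX_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$cov_median), "",
                     sprintf("cov %.0f", .data$cov_median))),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a UTR variability comparison
#'
#' Histogram of the number of variable pairwise comparisons per gene,
#' coloured by variability class.
#'
#' @param object A `tx_utr_comparison` from [compare_utrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tx_utr_comparison <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n_variable_comparisons,
                               fill = .data$variability_class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "variable pairwise comparisons", y = "genes",
                  fill = "class") +
    ggplot2::theme_minimal()
}
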