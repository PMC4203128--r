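# ggplot2 views of the main result types. All plot functions return the
# ggplot object; nothing is printed as a side effect.

#' Size and 5'-nucleotide distribution of a call set
#'
#' Bar chart of mature lengths, filled by first nucleotide — the standard
#' at-a-glance check that a catalogue is dominated by 21-nt, 5'-U species.
#'
#' @param calls call tibble with a seq column
#' @return a ggplot
#' @export
plot_size_first_nt <- function(calls) {
  df <- tibble::tibble(
    length = nchar(calls$seq),
    first_nt = first_nt(calls$seq)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$length),
                                   fill = .data$first_nt)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "mature length (nt)", y = "miRNAs",
                  fill = "5' nt") +
    ggplot2::theme_minimal()
}

#' Precursor MFE distribution of a call set
#' @param calls call tibble with an mfe column (kcal/mol)
#' @param threshold reference line (kcal/mol)
#' @return a ggplot
#' @export
plot_mfe_distribution <- function(calls, threshold = -20) {
  df <- calls[!is.na(calls$mfe), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mfe)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "precursor MFE (kcal/mol)", y = "precursors") +
    ggplot2::theme_minimal()
}

#' Null-vs-observed view of a shuffle test
#' @param object a `mir_shuffle_test`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mir_shuffle_test <- function(object, ...) {
  df <- tibble::tibble(score = object$null_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = if (object$mode == "energy") "fold energy (kcal/mol)" else
        "base pairs",
      y = "shuffles",
      title = sprintf("shuffle test: p = %.3f", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Per-sample expression distributions of a normalized count table
#' @param object a `mir_counts` object
#' @param ... unused
#' @return a ggplot (log2(x+1) boxplots per sample)
#' @export
autoplot.mir_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"id",
                              names_to = "sample", values_to = "normalized")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                     y = log2(.data$normalized + 1))) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = NULL, y = "log2(normalized + 1)") +
    ggplot2::theme_minimal()
}

#' Specificity category breakdown
#' @param specificity tibble from [rank_tissue_preference()]
#' @return a ggplot
#' @export
plot_specificity <- function(specificity) {
  ggplot2::ggplot(specificity, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "miRNAs") +
    ggplot2::theme_minimal()
}

#' Headline views of a pipeline run
#'
#' Size/5'-nt distribution of the final call set (the catalogue's
#' signature plot).
#'
#' @param object a `mir_run`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mir_run <- function(object, ...) {
  plot_size_first_nt(object$calls)
}
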