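# Expression analysis: median-of-ratios size factors, abundance
# categories, tissue-preferential ranking and specificity calls, qPCR
# delta-delta-CT relative quantification, and cross-platform correlation.

#' Estimate per-sample size factors (median-of-ratios)
#'
#' For rows with positive counts in every sample, each sample's factor is
#' the median ratio of its counts to the row geometric means, with the
#' median taken on the log scale (the DESeq convention; identical to the
#' plain median for an odd number of rows, and reciprocal-consistent for
#' an even number). Rows containing any zero are excluded from the median
#' (standard median-of-ratios convention); `pseudocount` can lift
#' degenerate matrices.
#'
#' @param counts count tibble/data.frame: first column miRNA id (or row
#'   names), remaining columns non-negative integer counts per sample; or
#'   a numeric matrix
#' @param pseudocount added to every count before estimation (default 0)
#' @return named numeric vector of size factors, one per sample
#' @examples
#' estimate_size_factors(tibble::tibble(id = c("a", "b", "c"),
#'                                      A = c(10, 20, 30),
#'                                      B = c(20, 40, 60)))
#' @export
estimate_size_factors <- function(counts, pseudocount = 0) {
  m <- count_matrix(counts)
  if (ncol(m) < 2) stop("need at least two samples", call. = FALSE)
  m <- m + pseudocount
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    stop("no row has positive counts in every sample; ",
         "consider pseudocount = 1", call. = FALSE)
  }
  mp <- m[all_pos, , drop = FALSE]
  loggeo <- rowMeans(log(mp))
  apply(mp, 2, function(col) exp(stats::median(log(col) - loggeo)))
}

#' Normalize a count table by size factors
#'
#' @param counts as in [estimate_size_factors()]
#' @param size_factors optional precomputed factors (estimated when NULL)
#' @param pseudocount passed to the estimator
#' @return a `mir_counts` object: tibble of normalized values (same shape
#'   as input) with `size_factors` and `raw` attributes
#' @export
normalize_counts <- function(counts, size_factors = NULL, pseudocount = 0) {
  m <- count_matrix(counts)
  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(counts, pseudocount = pseudocount)
  }
  norm <- sweep(m, 2, size_factors, "/")
  ids <- rownames(m)
  out <- tibble::as_tibble(norm)
  out <- dplyr::mutate(out, id = ids, .before = 1)
  structure(out, size_factors = size_factors, raw = m,
            class = c("mir_counts", class(out)))
}

#' @export
print.mir_counts <- function(x, ...) {
  sf <- attr(x, "size_factors")
  cat("<mir_counts> ", nrow(x), " miRNAs x ", length(sf), " samples; ",
      "size factors: ", paste(sprintf("%s=%.3f", names(sf), sf),
                              collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' One-row summary of a normalized count table
#' @param x a `mir_counts` object
#' @param ... unused
#' @return tibble: n_mirnas, n_samples, and one size-factor column per
#'   sample
#' @export
glance.mir_counts <- function(x, ...) {
  sf <- attr(x, "size_factors")
  tibble::as_tibble(c(
    list(n_mirnas = nrow(x), n_samples = length(sf)),
    as.list(setNames(sf, paste0("sf_", names(sf))))
  ))
}

count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
    return(m)
  }
  stopifnot(is.data.frame(counts))
  num <- vapply(counts, is.numeric, logical(1))
  if (!num[1] && sum(!num) == 1) {
    m <- as.matrix(counts[, num, drop = FALSE])
    rownames(m) <- as.character(counts[[which(!num)]])
  } else if (all(num)) {
    m <- as.matrix(counts)
    rownames(m) <- rownames(counts) %||% paste0("row", seq_len(nrow(counts)))
  } else {
    stop("counts must be a matrix or a data frame with one id column ",
         "plus numeric sample columns", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Bin a normalized expression value into five abundance categories
#'
#' Half-open binning on ascending breaks: `[0, b1)` very_low, `[b1, b2)`
#' low, `[b2, b3)` moderate, `[b3, b4)` high, `[b4, Inf)` very_high.
#'
#' @param normalized numeric vector of normalized expression values (>= 0)
#' @param breaks four ascending thresholds
#' @return factor with levels very_low < low < moderate < high < very_high
#' @export
categorize_abundance <- function(normalized,
                                 breaks = c(10, 100, 1000, 10000)) {
  if (is.unsorted(breaks, strictly = TRUE) || length(breaks) != 4) {
    stop("breaks must be four strictly ascending thresholds", call. = FALSE)
  }
  if (any(normalized < 0)) stop("normalized values must be >= 0",
                                call. = FALSE)
  labels <- c("very_low", "low", "moderate", "high", "very_high")
  cut(normalized, breaks = c(-Inf, breaks, Inf), labels = labels,
      right = FALSE, ordered_result = TRUE)
}

#' Rank tissue preference and call expression specificity
#'
#' miRNAs below `detection_min` in every tissue are `below_detection`.
#' Otherwise per-tissue fractions of total normalized expression are
#' computed; a miRNA is `specific` when its top fraction is at least
#' `spec_frac` and every other tissue is below `detection_min`;
#' `preferential` when the top tissue is at least `pref_ratio` times the
#' second; `ubiquitous` otherwise. The per-row variance of log2(x+1)
#' expression is reported so ubiquitous low-variance rows (candidate qPCR
#' normalizers) can be short-listed.
#'
#' @param normalized a `mir_counts` object or normalized count tibble
#' @param detection_min normalized-count detection threshold
#' @param pref_ratio top/second ratio declaring preferential expression
#' @param spec_frac top-tissue fraction declaring specificity
#' @return tibble: id, category, preferred_tissue, top_fraction,
#'   log_variance, one `frac_<tissue>` column per tissue
#' @export
rank_tissue_preference <- function(normalized, detection_min = 10,
                                   pref_ratio = 2.0, spec_frac = 0.90) {
  m <- count_matrix(as.data.frame(normalized))
  tissues <- colnames(m)
  total <- rowSums(m)
  fr <- m / ifelse(total > 0, total, 1)
  top_idx <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), top_idx)]
  second <- vapply(seq_len(nrow(m)), function(i) {
    sort(m[i, ], decreasing = TRUE)[2]
  }, numeric(1))
  others_below <- vapply(seq_len(nrow(m)), function(i) {
    all(m[i, -top_idx[i]] < detection_min)
  }, logical(1))
  below <- apply(m, 1, function(r) all(r < detection_min))
  top_frac <- unname(fr[cbind(seq_len(nrow(m)), top_idx)])
  top <- unname(top)
  below <- unname(below)
  category <- dplyr::case_when(
    below ~ "below_detection",
    top_frac >= spec_frac & others_below ~ "specific",
    top >= pref_ratio * second ~ "preferential",
    TRUE ~ "ubiquitous"
  )
  out <- tibble::tibble(
    id = rownames(m),
    category = category,
    preferred_tissue = ifelse(category %in% c("specific", "preferential"),
                              tissues[top_idx], NA_character_),
    top_fraction = ifelse(below, NA_real_, top_frac),
    log_variance = apply(log2(m + 1), 1, stats::var)
  )
  fr_tbl <- tibble::as_tibble(fr)
  names(fr_tbl) <- paste0("frac_", tissues)
  dplyr::bind_cols(out, fr_tbl)
}

#' Short-list ubiquitous low-variance miRNAs as qPCR normalizer candidates
#' @param specificity tibble from [rank_tissue_preference()]
#' @param n number of candidates
#' @return tibble slice, lowest log-variance ubiquitous rows first
#' @export
normalizer_shortlist <- function(specificity, n = 5) {
  ub <- specificity[specificity$category == "ubiquitous", , drop = FALSE]
  head(dplyr::arrange(ub, .data$log_variance), n)
}

#' Relative quantification by the delta-delta-CT method
#'
#' Per (target, sample): mean CT minus mean reference CT gives dCT; dCT
#' minus the calibrator sample's dCT gives ddCT; RQ = 2^(-ddCT).
#' Replicate SD of dCT is propagated as sqrt(sd_target^2 + sd_ref^2).
#'
#' @param ct tibble: target, sample, replicate, ct
#' @param reference_gene internal control target label (e.g. "U6")
#' @param calibrator_sample sample against which ddCT is taken
#' @return tibble: target, sample, dct, ddct, rq, sd_dct
#' @export
delta_delta_ct <- function(ct, reference_gene = "U6", calibrator_sample) {
  stopifnot(all(c("target", "sample", "ct") %in% names(ct)))
  if (!calibrator_sample %in% ct$sample) {
    stop("calibrator sample '", calibrator_sample, "' not in table",
         call. = FALSE)
  }
  ref <- ct[ct$target == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop("reference gene '", reference_gene, "' not in table", call. = FALSE)
  }
  ref_stats <- dplyr::summarise(dplyr::group_by(ref, .data$sample),
                                ref_mean = mean(.data$ct),
                                ref_sd = stats::sd(.data$ct),
                                .groups = "drop")
  missing_ref <- setdiff(unique(ct$sample), ref_stats$sample)
  if (length(missing_ref) > 0) {
    stop("reference gene missing for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  tg <- ct[ct$target != reference_gene, , drop = FALSE]
  st <- dplyr::summarise(dplyr::group_by(tg, .data$target, .data$sample),
                         t_mean = mean(.data$ct),
                         t_sd = stats::sd(.data$ct),
                         .groups = "drop")
  st <- dplyr::left_join(st, ref_stats, by = "sample")
  st <- dplyr::mutate(st,
    dct = .data$t_mean - .data$ref_mean,
    sd_dct = sqrt(dplyr::coalesce(.data$t_sd, 0)^2 +
                    dplyr::coalesce(.data$ref_sd, 0)^2)
  )
  cal <- st[st$sample == calibrator_sample, c("target", "dct")]
  names(cal)[2] <- "dct_cal"
  missing_cal <- setdiff(unique(st$target), cal$target)
  if (length(missing_cal) > 0) {
    stop("calibrator sample missing for target(s): ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  }
  st <- dplyr::left_join(st, cal, by = "target")
  st <- dplyr::mutate(st,
    ddct = .data$dct - .data$dct_cal,
    rq = 2^(-.data$ddct)
  )
  dplyr::select(st, "target", "sample", "dct", "ddct", "rq", "sd_dct")
}

#' Correlate sequencing-based and qPCR-based expression
#'
#' Pearson correlation between log2(normalized + pseudocount) sequencing
#' values and log2(RQ) over matched (miRNA, sample) pairs.
#'
#' @param seq_values tibble: id, sample, normalized
#' @param qpcr_rq tibble: target, sample, rq (targets matched to ids)
#' @param pseudocount added to normalized counts before log2
#' @return list: r (Pearson), n_pairs, data (the matched pair tibble)
#' @export
correlate_platforms <- function(seq_values, qpcr_rq, pseudocount = 1) {
  merged <- dplyr::inner_join(
    seq_values,
    dplyr::rename(qpcr_rq, id = "target"),
    by = c("id", "sample")
  )
  if (nrow(merged) < 3) stop("fewer than 3 matched pairs", call. = FALSE)
  x <- log2(merged$normalized + pseudocount)
  y <- log2(merged$rq)
  list(r = stats::cor(x, y), n_pairs = nrow(merged), data = merged)
}
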