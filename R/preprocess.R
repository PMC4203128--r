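# Raw FASTQ -> unique 18-30 nt tags with per-sample counts: quality rule,
# 3' adapter + poly-A trimming, collapsing, size selection.

#' Quality-filter reads
#'
#' A read is discarded when more than `max_low_frac` of its bases fall
#' below Phred `low_q`, when it contains N, or when it is empty.
#'
#' @param reads tibble with seq and qual columns (Phred+33)
#' @param max_low_frac maximum tolerated fraction of low-quality bases
#' @param low_q Phred threshold defining a low-quality base
#' @return the input tibble with logical `keep` and character `reason`
#'   (`NA` for kept reads) columns appended
#' @export
quality_filter <- function(reads, max_low_frac = 0.30, low_q = 20) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (nrow(reads) > 0 && any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("seq and qual lengths differ for some reads", call. = FALSE)
  }
  low_frac <- vapply(reads$qual, function(q) {
    if (nchar(q) == 0) return(1)
    mean(utf8ToInt(q) - 33L < low_q)
  }, numeric(1), USE.NAMES = FALSE)
  empty <- nchar(reads$seq) == 0
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  lowq <- low_frac > max_low_frac
  reason <- dplyr::case_when(
    empty ~ "empty",
    has_n ~ "contains_N",
    lowq ~ "low_quality",
    TRUE ~ NA_character_
  )
  dplyr::mutate(reads, keep = is.na(reason), reason = reason)
}

#' Trim the 3' adapter and poly-A tail from a read
#'
#' The leftmost occurrence of an adapter prefix of at least `min_overlap`
#' exact bases is removed (together with everything 3' of it); then a
#' trailing run of at least `polya_min` A's is removed. Reads with no
#' adapter match are kept untrimmed and flagged. A read reduced to nothing
#' yields `NA`.
#'
#' @param reads tibble with a seq column (or a character vector)
#' @param adapter 3' adapter sequence (non-empty)
#' @param min_overlap minimum exact adapter prefix length to trigger a trim
#' @param polya_min minimum length of a trailing A-run to strip
#' @return tibble with `insert` (NA when fully trimmed away) and
#'   `adapter_found` columns appended
#' @export
trim_reads <- function(reads, adapter, min_overlap = 6, polya_min = 8) {
  if (is.character(reads)) reads <- tibble::tibble(seq = reads)
  adapter <- as_dna(adapter)
  if (nchar(adapter) == 0) stop("adapter must be non-empty", call. = FALSE)
  probe <- substr(adapter, 1, min_overlap)
  trim_one <- function(s) {
    hit <- regexpr(probe, s, fixed = TRUE)[1]
    found <- hit > 0
    if (found) s <- substr(s, 1, hit - 1)
    s <- sub(sprintf("A{%d,}$", polya_min), "", s)
    c(insert = if (nchar(s) == 0) NA_character_ else s,
      found = as.character(found))
  }
  out <- vapply(reads$seq, trim_one, character(2), USE.NAMES = FALSE)
  dplyr::mutate(reads,
    insert = out[1, ],
    adapter_found = out[2, ] == "TRUE"
  )
}

#' Collapse trimmed inserts into unique tags with size selection
#'
#' Identical sequences are merged with summed counts; sequences outside
#' `[min_len, max_len]` are dropped and tallied. Library statistics (raw
#' totals, size and 5'-nt histograms over retained tags) travel as the
#' `stats` attribute, retrievable with [library_stats()].
#'
#' @param inserts character vector of trimmed insert sequences (NA allowed,
#'   counted as fully-trimmed), or a tibble with an insert column
#' @param sample sample label for the count column
#' @param min_len,max_len retained length bounds (inclusive)
#' @return tibble: seq, count — one row per unique retained tag, sorted by
#'   count desc then seq; attribute `stats` carries a `mir_library_stats`
#'   list
#' @export
collapse_tags <- function(inserts, sample = "sample", min_len = 18,
                          max_len = 30) {
  if (is.data.frame(inserts)) inserts <- inserts$insert
  n_raw <- length(inserts)
  inserts <- inserts[!is.na(inserts)]
  lens <- nchar(inserts)
  in_range <- lens >= min_len & lens <= max_len
  dropped_short <- sum(lens < min_len)
  dropped_long <- sum(lens > max_len)
  kept <- inserts[in_range]
  tab <- table(kept)
  tags <- tibble::tibble(
    seq = if (length(tab) > 0) names(tab) else character(0),
    count = as.integer(tab)
  )
  tags <- dplyr::arrange(tags, desc(.data$count), .data$seq)
  names(tags)[2] <- sample
  stats <- structure(
    list(
      sample = sample,
      raw_reads = n_raw,
      post_qc_reads = sum(in_range),
      unique_tags = nrow(tags),
      dropped_short = dropped_short,
      dropped_long = dropped_long,
      size_histogram = table(factor(nchar(tags$seq),
                                    levels = min_len:max_len)),
      first_nt_histogram = table(factor(first_nt(tags$seq),
                                        levels = c("A", "C", "G", "U")))
    ),
    class = "mir_library_stats"
  )
  attr(tags, "stats") <- stats
  tags
}

#' Retrieve library statistics attached by [collapse_tags()]
#' @param tags a tag tibble from [collapse_tags()]
#' @return a `mir_library_stats` list
#' @export
library_stats <- function(tags) {
  attr(tags, "stats")
}

#' @export
print.mir_library_stats <- function(x, ...) {
  cat("<mir_library_stats> ", x$sample, ": ", x$raw_reads, " reads -> ",
      x$post_qc_reads, " in range -> ", x$unique_tags, " unique tags\n",
      sep = "")
  invisible(x)
}

#' Preprocess one library end to end
#'
#' Quality filter, adapter/poly-A trim, collapse, size-select. The
#' conservation audit (raw = discarded_qc + trimmed_away + out_of_range +
#' retained) is recorded in the stats attribute.
#'
#' @param reads tibble with read_id, seq, qual
#' @param sample sample label
#' @param adapter 3' adapter sequence
#' @param max_low_frac,low_q quality rule, see [quality_filter()]
#' @param min_overlap,polya_min trimming rule, see [trim_reads()]
#' @param min_len,max_len size selection, see [collapse_tags()]
#' @return tag tibble (seq + one count column named after `sample`) with a
#'   `stats` attribute
#' @export
preprocess_library <- function(reads, sample, adapter,
                               max_low_frac = 0.30, low_q = 20,
                               min_overlap = 6, polya_min = 8,
                               min_len = 18, max_len = 30) {
  qc <- quality_filter(reads, max_low_frac = max_low_frac, low_q = low_q)
  kept <- qc[qc$keep, , drop = FALSE]
  trimmed <- trim_reads(kept, adapter, min_overlap = min_overlap,
                        polya_min = polya_min)
  tags <- collapse_tags(trimmed$insert, sample = sample,
                        min_len = min_len, max_len = max_len)
  st <- attr(tags, "stats")
  st$raw_reads <- nrow(reads)
  st$discarded_qc <- sum(!qc$keep)
  st$trimmed_away <- sum(is.na(trimmed$insert))
  st$no_adapter <- sum(!trimmed$adapter_found, na.rm = TRUE)
  attr(tags, "stats") <- st
  tags
}

#' Merge per-sample tag tables into one wide tag table
#' @param tag_tables named list of tag tibbles (one count column each)
#' @return tibble: seq + one count column per sample (0 where absent)
#' @export
merge_tag_tables <- function(tag_tables) {
  out <- Reduce(function(a, b) dplyr::full_join(a, b, by = "seq"),
                tag_tables)
  out <- dplyr::mutate(out, dplyr::across(-"seq", ~ tidyr::replace_na(., 0L)))
  dplyr::arrange(out, desc(rowSums(out[, -1, drop = FALSE])), .data$seq)
}
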