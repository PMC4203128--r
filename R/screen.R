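# Screening tags against structural ncRNA / repeat / organelle references
# (exact substring, either strand) and conserved-miRNA identification by
# mismatch-bounded sliding alignment against a known mature set.

#' Screen tags against reference sequence sets
#'
#' A tag is discarded iff it occurs as an exact substring of any screen
#' sequence on either strand; the tally records the first matching screen
#' label (screens searched in list order).
#'
#' @param tags tag tibble (seq + count columns)
#' @param screens named list of screen sets; each element a tibble with id
#'   + seq columns (or a named character vector). Names are the screen
#'   labels (e.g. rRNA, tRNA, repeat, chloroplast).
#' @param max_mm allowed mismatches for a screen match (0 = exact
#'   substring, the default; mismatch-tolerant screening is opt-in)
#' @return list: `retained` (tag tibble), `discarded` (tag tibble with a
#'   `screen` column), `tally` (tibble: screen, n_tags, n_reads)
#' @export
screen_tags <- function(tags, screens, max_mm = 0) {
  stopifnot("seq" %in% names(tags))
  if (length(screens) == 0) {
    warning("no screen sets provided; all tags retained")
    return(list(retained = tags, discarded = tags[0, ],
                tally = tibble::tibble(screen = character(0),
                                       n_tags = integer(0),
                                       n_reads = integer(0))))
  }
  if (is.null(names(screens)) || any(names(screens) == "")) {
    stop("screens must be a named list", call. = FALSE)
  }
  subjects <- lapply(screens, function(s) {
    if (is.data.frame(s)) s <- setNames(s$seq, s$id)
    Biostrings::DNAStringSet(as_dna(s))
  })
  hit_label <- rep(NA_character_, nrow(tags))
  for (lab in names(subjects)) {
    todo <- which(is.na(hit_label))
    if (length(todo) == 0) break
    subj <- subjects[[lab]]
    for (i in todo) {
      fwd <- Biostrings::vcountPattern(as_dna(tags$seq[i]), subj,
                                       max.mismatch = max_mm)
      if (sum(fwd) > 0) {
        hit_label[i] <- lab
        next
      }
      rev <- Biostrings::vcountPattern(revcomp(tags$seq[i]), subj,
                                       max.mismatch = max_mm)
      if (sum(rev) > 0) hit_label[i] <- lab
    }
  }
  discarded <- dplyr::mutate(tags[!is.na(hit_label), , drop = FALSE],
                             screen = hit_label[!is.na(hit_label)])
  count_cols <- setdiff(names(tags), "seq")
  tally <- if (nrow(discarded) > 0) {
    dplyr::summarise(
      dplyr::group_by(discarded, .data$screen),
      n_tags = dplyr::n(),
      n_reads = sum(rowSums(as.matrix(
        dplyr::pick(dplyr::all_of(count_cols))))),
      .groups = "drop"
    )
  } else {
    tibble::tibble(screen = character(0), n_tags = integer(0),
                   n_reads = integer(0))
  }
  list(
    retained = tags[is.na(hit_label), , drop = FALSE],
    discarded = discarded,
    tally = tally
  )
}

#' Parse a miRNA family label from a reference identifier
#'
#' The family is the leading "miR"+digits token (case-insensitive,
#' "miR156a" and "cme-miR156a-5p" both give "miR156"); identifiers without
#' the token get "unassigned".
#'
#' @param ids character vector of reference identifiers
#' @return character vector of family labels
#' @export
mirna_family <- function(ids) {
  m <- regmatches(ids, regexpr("miR[0-9]+", ids, ignore.case = TRUE))
  out <- rep("unassigned", length(ids))
  hit <- regexpr("miR[0-9]+", ids, ignore.case = TRUE) > 0
  out[hit] <- paste0("miR", sub("^...", "", m))
  out
}

#' Match tags to a known mature miRNA set within a mismatch bound
#'
#' A tag is a conserved hit iff a known mature exists with length within
#' +/-2 of the tag and an ungapped sliding alignment (shorter sequence
#' slid over the longer, overhanging bases counted as mismatches) with at
#' most `max_mm` mismatches. The minimum-mismatch hit is reported, ties
#' broken by lexicographically smallest reference id. Hits are restricted
#' to tags of 20-24 nt.
#'
#' @param tags tag tibble (seq + count columns)
#' @param known known mature set: tibble with id + seq columns
#' @param max_mm maximum mismatches
#' @return list: `hits` (tibble: seq, ref_id, mismatches, family, + count
#'   columns), `unmatched` (tag tibble)
#' @export
match_known_mirnas <- function(tags, known, max_mm = 2) {
  stopifnot("seq" %in% names(tags), all(c("id", "seq") %in% names(known)))
  known <- dplyr::arrange(known, .data$id)
  known_codes <- lapply(as_dna(known$seq), seq_to_codes_dna)
  known_len <- nchar(known$seq)
  n <- nrow(tags)
  ref_id <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  tag_len <- nchar(tags$seq)
  for (i in seq_len(n)) {
    if (tag_len[i] < 20 || tag_len[i] > 24) next
    tc <- seq_to_codes_dna(as_dna(tags$seq[i]))
    best <- max_mm + 1L
    best_ref <- NA_character_
    cand <- which(abs(known_len - tag_len[i]) <= 2)
    for (j in cand) {
      mm <- .slide_mismatch_cpp(tc, known_codes[[j]])$mismatches
      if (mm < best) {
        best <- mm
        best_ref <- known$id[j]
      }
    }
    if (best <= max_mm) {
      ref_id[i] <- best_ref
      mism[i] <- best
    }
  }
  hit <- !is.na(ref_id)
  hit_ref <- ref_id[hit]
  hit_mm <- mism[hit]
  hit_fam <- mirna_family(hit_ref)
  hits <- tags[hit, , drop = FALSE]
  hits <- dplyr::mutate(hits,
    ref_id = hit_ref,
    mismatches = hit_mm,
    family = hit_fam,
    .after = "seq"
  )
  list(hits = hits, unmatched = tags[!hit, , drop = FALSE])
}

# DNA integer codes for the C++ mismatch scan (A=0,C=1,G=2,T=3)
seq_to_codes_dna <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], NT_DNA) - 1L
}
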