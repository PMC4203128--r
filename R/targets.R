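# miRNA target prediction by complementarity penalty scoring. A hit is an
# ungapped (or single-1-nt-gap) alignment of the miRNA against the
# transcript's reverse complement whose summed penalty is at most the
# cutoff; mismatches in the duplex core (positions 10-11 from the miRNA
# 5' end) switch the predicted mode from cleavage to translational
# repression.

#' Default target-scoring weights
#'
#' Penalty per alignment state, doubled inside the seed-proximal region
#' (positions 2-13 from the miRNA 5' end). The defaults mirror common
#' plant-target-server conventions; the whole table is a configuration.
#'
#' @param w_mismatch penalty per mismatch
#' @param w_gu penalty per G:U wobble
#' @param w_gap penalty per 1-nt gap
#' @param seed_region positions (from miRNA 5') where weights double
#' @param seed_mult multiplier inside `seed_region`
#' @return named list of weights
#' @export
target_weights <- function(w_mismatch = 1.0, w_gu = 0.5, w_gap = 2.0,
                           seed_region = c(2, 13), seed_mult = 2.0) {
  list(w_mismatch = w_mismatch, w_gu = w_gu, w_gap = w_gap,
       seed_region = seed_region, seed_mult = seed_mult)
}

#' Score a pairing-state vector
#'
#' States are indexed from the miRNA 5' end; a target-side 1-nt gap
#' appears as one extra `"gap"` element. Penalty = sum over positions of
#' the state weight, multiplied by `seed_mult` when the position lies in
#' `seed_region`. At most one `"gap"` state is allowed.
#'
#' @param pairing character vector of states in
#'   `c("match", "GU", "mismatch", "gap")`
#' @param weights list from [target_weights()]
#' @return penalty score (>= 0)
#' @export
score_pairing <- function(pairing, weights = target_weights()) {
  bad <- setdiff(unique(pairing), c("match", "GU", "mismatch", "gap"))
  if (length(bad) > 0) {
    stop("unknown pairing state(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (sum(pairing == "gap") > 1) {
    stop("invalid alignment: more than one gap", call. = FALSE)
  }
  w <- c(match = 0, GU = weights$w_gu, mismatch = weights$w_mismatch,
         gap = weights$w_gap)
  pos <- seq_along(pairing)
  mult <- ifelse(pos >= weights$seed_region[1] &
                   pos <= weights$seed_region[2], weights$seed_mult, 1)
  sum(w[pairing] * mult)
}

#' Classify the predicted inhibition mode of an alignment
#'
#' Translational repression iff any state at positions 10-11 (from the
#' miRNA 5' end) is not a match; cleavage otherwise.
#'
#' @param pairing character vector of states (length >= 11)
#' @return `"cleavage"` or `"translation"`
#' @export
classify_mode <- function(pairing) {
  if (length(pairing) < 11) {
    stop("miRNA shorter than 11 nt: mode undefined", call. = FALSE)
  }
  if (any(pairing[10:11] != "match")) "translation" else "cleavage"
}

# pairing states of miRNA bases vs reverse-complemented target bases:
# equal -> match; miRNA G vs rc A (target U) or miRNA U vs rc C (target G)
# -> GU wobble; otherwise mismatch. Inputs are RNA character vectors.
pair_states <- function(mi_ch, rc_ch) {
  st <- ifelse(mi_ch == rc_ch, "match", "mismatch")
  gu <- (mi_ch == "G" & rc_ch == "A") | (mi_ch == "U" & rc_ch == "C")
  st[gu & st == "mismatch"] <- "GU"
  st
}

#' Find miRNA target sites in a transcript set
#'
#' Slides the miRNA along the reverse complement of each transcript at
#' every offset, with and without a single 1-nt gap (an unpaired miRNA
#' base, or one extra target base), scores each alignment with
#' [score_pairing()], and reports hits with penalty at most
#' `max_penalty` — best per transcript first, ties broken by smaller
#' target start.
#'
#' @param mirna miRNA sequence (DNA or RNA), >= 11 nt
#' @param transcripts tibble with transcript_id + seq columns
#' @param max_penalty report hits with penalty <= this cutoff
#' @param weights list from [target_weights()]
#' @param mirna_id label for the output
#' @return tibble: mirna_id, transcript_id, target_start (0-based on the
#'   transcript), penalty, mode, pairing (compact string: `|` match,
#'   `o` G:U, `x` mismatch, `-` gap)
#' @export
find_targets <- function(mirna, transcripts, max_penalty = 2.5,
                         weights = target_weights(), mirna_id = "miRNA",
                         gap = TRUE) {
  stopifnot(all(c("transcript_id", "seq") %in% names(transcripts)))
  mi <- strsplit(as_rna(mirna), "", fixed = TRUE)[[1]]
  m <- length(mi)
  if (m < 11) stop("miRNA shorter than 11 nt", call. = FALSE)
  sr <- weights$seed_region
  mult <- function(pos) ifelse(pos >= sr[1] & pos <= sr[2],
                               weights$seed_mult, 1)
  rows <- list()
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts$seq[t]
    L <- nchar(tx)
    if (L < m - 1) next
    rc <- strsplit(as_rna(revcomp(tx)), "", fixed = TRUE)[[1]]
    # base penalties P[k, j]: miRNA position k vs rc base j, no multiplier
    P <- matrix(0, nrow = m, ncol = L)
    for (k in seq_len(m)) {
      st <- pair_states(rep(mi[k], L), rc)
      P[k, ] <- c(match = 0, GU = weights$w_gu,
                  mismatch = weights$w_mismatch)[st]
    }
    best <- NULL
    # ungapped, offsets 0..L-m: total(off) = sum_k mult(k) P[k, off+k]
    if (L >= m) {
      n_off <- L - m + 1
      tot <- numeric(n_off)
      for (k in seq_len(m)) tot <- tot + mult(k) * P[k, k:(k + n_off - 1)]
      # tie-break: larger off (=> smaller target_start)
      off <- order(tot, -seq_len(n_off))[1]
      best <- consider(best, tot[off], off - 1L, m, NULL, max_penalty)
    }
    if (gap) {
      # prefix/suffix sums for the two single-gap families
      # A_k(off) = mult(k) P[k, off+k]            (positions before the gap)
      # B_k(off) = mult(k) P[k, off+k-1]          (miRNA-gap: after the gap)
      # C_k(off) = mult(k+1) P[k, off+k+1]        (target-gap: after the gap)
      if (L >= m - 1) {
        n_off <- L - (m - 1) + 1
        offs <- seq_len(n_off)  # off = offs - 1
        A <- matrix(0, m, n_off)
        B <- matrix(0, m, n_off)
        for (k in seq_len(m)) {
          idxA <- (offs - 1) + k
          okA <- idxA <= L
          A[k, okA] <- mult(k) * P[k, idxA[okA]]
          A[k, !okA] <- Inf
          idxB <- (offs - 1) + k - 1
          okB <- idxB >= 1 & idxB <= L
          B[k, okB] <- mult(k) * P[k, idxB[okB]]
          B[k, !okB] <- Inf
        }
        cumA <- apply(A, 2, cumsum)                   # cumA[k,] = sum_{i<=k}
        sufB <- apply(B[m:1, , drop = FALSE], 2, cumsum)[m:1, , drop = FALSE]
        for (g in 2:(m - 1)) {
          tot <- cumA[g - 1, ] + mult(g) * weights$w_gap + sufB[g + 1, ]
          off <- order(tot, -offs)[1]
          if (is.finite(tot[off])) {
            best <- consider(best, tot[off], off - 1L, m - 1L, g,
                             max_penalty, gap_kind = "mi")
          }
        }
      }
      if (L >= m + 1) {
        n_off <- L - (m + 1) + 1
        offs <- seq_len(n_off)
        A2 <- matrix(0, m, n_off)
        C <- matrix(0, m, n_off)
        for (k in seq_len(m)) {
          A2[k, ] <- mult(k) * P[k, (offs - 1) + k]
          C[k, ] <- mult(k + 1) * P[k, (offs - 1) + k + 1]
        }
        cumA2 <- apply(A2, 2, cumsum)
        sufC <- apply(C[m:1, , drop = FALSE], 2, cumsum)[m:1, , drop = FALSE]
        for (g in 1:(m - 1)) {
          tot <- cumA2[g, ] + mult(g + 1) * weights$w_gap + sufC[g + 1, ]
          off <- order(tot, -offs)[1]
          best <- consider(best, tot[off], off - 1L, m + 1L, g,
                           max_penalty, gap_kind = "tx")
        }
      }
    }
    if (!is.null(best)) {
      states <- rebuild_states(mi, rc, best)
      target_start <- L - (best$off + best$span)
      rows[[length(rows) + 1]] <- tibble::tibble(
        mirna_id = mirna_id,
        transcript_id = transcripts$transcript_id[t],
        target_start = as.integer(target_start),
        penalty = best$penalty,
        mode = classify_mode(states),
        pairing = pairing_string(states)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(mirna_id = character(0),
                          transcript_id = character(0),
                          target_start = integer(0), penalty = numeric(0),
                          mode = character(0), pairing = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$penalty, .data$target_start)
}

# keep the better of the running best and a candidate alignment: lower
# penalty wins, ties broken by smaller target_start (= larger off + span)
consider <- function(best, penalty, off, span, g, max_penalty,
                     gap_kind = NULL) {
  if (!is.finite(penalty) || penalty > max_penalty + 1e-12) return(best)
  cand <- list(penalty = penalty, off = off, span = span, g = g,
               gap_kind = gap_kind)
  if (is.null(best)) return(cand)
  if (penalty < best$penalty - 1e-12) return(cand)
  if (abs(penalty - best$penalty) <= 1e-12 &&
      (off + span) > (best$off + best$span)) {
    return(cand)
  }
  best
}

rebuild_states <- function(mi, rc, best) {
  m <- length(mi)
  off <- best$off
  if (is.null(best$gap_kind)) {
    return(pair_states(mi, rc[(off + 1):(off + m)]))
  }
  if (best$gap_kind == "mi") {
    g <- best$g
    states <- pair_states(mi[-g], rc[(off + 1):(off + m - 1)])
    return(append(states, "gap", after = g - 1))
  }
  g <- best$g
  seg <- rc[c((off + 1):(off + g), (off + g + 2):(off + m + 1))]
  states <- pair_states(mi, seg)
  append(states, "gap", after = g)
}

pairing_string <- function(states) {
  paste(c("match" = "|", "GU" = "o", "mismatch" = "x",
          "gap" = "-")[states], collapse = "")
}

#' Crude target-site accessibility proxy
#'
#' Fraction of unpaired bases in the max-pair fold of a local window
#' around a target site. A rough stand-in for opening-energy
#' accessibility scoring: reported separately, never used for filtering.
#'
#' @param transcript transcript sequence
#' @param target_start 0-based site start on the transcript
#' @param site_len site length, nt
#' @param flank window extension on each side, nt
#' @return fraction of unpaired site bases in `[0, 1]`
#' @export
site_accessibility <- function(transcript, target_start, site_len,
                               flank = 40) {
  L <- nchar(transcript)
  lo <- max(1L, target_start + 1L - flank)
  hi <- min(L, target_start + site_len + flank)
  f <- fold_maxpair(substr(transcript, lo, hi))
  site_pos <- (target_start + 1L - lo + 1L):(target_start + site_len - lo + 1L)
  mean(is.na(f$partner[site_pos]))
}

#' Predict targets for a set of miRNA calls
#'
#' @param calls call tibble with id + seq columns
#' @param transcripts tibble with transcript_id + seq columns
#' @param max_penalty penalty cutoff
#' @param weights scoring weights
#' @return tibble of target hits across all calls
#' @export
predict_targets <- function(calls, transcripts, max_penalty = 2.5,
                            weights = target_weights()) {
  hits <- lapply(seq_len(nrow(calls)), function(i) {
    find_targets(calls$seq[i], transcripts, max_penalty = max_penalty,
                 weights = weights, mirna_id = calls$id[i])
  })
  dplyr::bind_rows(hits)
}
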