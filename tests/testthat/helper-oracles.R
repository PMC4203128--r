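# Independent brute-force oracles used to pin down the dynamic programs
# and search routines, plus hand-built fixtures shared across test files.

# --- exhaustive nested-structure enumeration ---------------------------
# maximum pair count over all nested structures with canonical pairs and
# the minimum-loop constraint, by direct recursion over the structure
# space (no tabulation): the independent check for the Nussinov DP.
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(toupper(chartr("T", "U", seq)), "", fixed = TRUE)[[1]]
  ok <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (ok(ch[i], ch[k])) {
        inner <- if (k - i - 1 > min_loop) rec(i + 1, k - 1) else 0L
        rest <- if (k < j) rec(k + 1, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    best
  }
  if (length(ch) < min_loop + 2) return(0L)
  rec(1L, length(ch))
}

# --- sliding-Hamming scan ----------------------------------------------
# minimum mismatch count of tag vs ref over every ungapped offset, the
# shorter slid along the longer, overhang counted as mismatch.
oracle_slide_mm <- function(tag, ref) {
  a <- strsplit(tag, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  s <- if (length(a) <= length(b)) a else b
  l <- if (length(a) <= length(b)) b else a
  ns <- length(s)
  nl <- length(l)
  best <- ns + 1L
  for (off in (-(ns - 1)):(nl - 1)) {
    mm <- 0L
    for (k in seq_len(ns)) {
      p <- off + k
      if (p < 1 || p > nl || s[k] != l[p]) mm <- mm + 1L
    }
    best <- min(best, mm)
  }
  best
}

# reverse complement without the package helper
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# --- exhaustive target-alignment enumeration ---------------------------
# best alignment (penalty, 0-based target_start) of a miRNA against one
# transcript over all offsets, ungapped plus every single-gap placement,
# scored with score_pairing(); ties broken by smaller target_start.
# Returns NULL when nothing scores <= max_penalty.
oracle_best_target <- function(mirna, tx, max_penalty = 2.5,
                               weights = target_weights()) {
  mi <- strsplit(chartr("T", "U", toupper(mirna)), "", fixed = TRUE)[[1]]
  m <- length(mi)
  rc <- strsplit(chartr("T", "U", toupper(oracle_revcomp(toupper(tx)))),
                 "", fixed = TRUE)[[1]]
  L <- length(rc)
  states_of <- function(mseg, tseg) {
    st <- ifelse(mseg == tseg, "match", "mismatch")
    gu <- (mseg == "G" & tseg == "A") | (mseg == "U" & tseg == "C")
    st[gu & st == "mismatch"] <- "GU"
    st
  }
  best <- NULL
  push <- function(states, off, span) {
    p <- score_pairing(states, weights)
    if (p > max_penalty + 1e-12) return()
    ts <- L - (off + span)
    if (is.null(best) || p < best$penalty - 1e-12 ||
        (abs(p - best$penalty) <= 1e-12 && ts < best$target_start)) {
      best <<- list(penalty = p, target_start = ts, states = states)
    }
  }
  if (L >= m) {
    for (off in 0:(L - m)) {
      push(states_of(mi, rc[(off + 1):(off + m)]), off, m)
    }
  }
  if (L >= m - 1) {
    for (off in 0:(L - (m - 1))) {
      for (g in 2:(m - 1)) {
        st <- states_of(mi[-g], rc[(off + 1):(off + m - 1)])
        push(append(st, "gap", after = g - 1), off, m - 1)
      }
    }
  }
  if (L >= m + 1) {
    for (off in 0:(L - (m + 1))) {
      for (g in 1:(m - 1)) {
        seg <- rc[c((off + 1):(off + g), (off + g + 2):(off + m + 1))]
        st <- states_of(mi, seg)
        push(append(st, "gap", after = g), off, m + 1)
      }
    }
  }
  best
}

# --- hand-built rejection-control precursors ---------------------------
# each returns list(genome, tag, locus) with the control planted in a
# small random genome so it maps exactly once.

random_genome_with <- function(insert, n = 3000, seed = 99) {
  set.seed(seed)
  repeat {
    g <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    pos <- 1500L
    substr(g, pos, pos + nchar(insert) - 1L) <- insert
    # insert must occur exactly once for a clean single-locus fixture
    if (length(gregexpr(insert, g, fixed = TRUE)[[1]]) == 1) return(
      list(genome = c(chr1 = g), insert_start0 = pos - 1L))
  }
}

# a mature whose arm pairs only its first 13 bases: 13-bp duplex
control_duplex13 <- function() {
  mature <- "TGGAGCTCCCTTCATTCCAAT"           # 21 nt
  arm <- oracle_revcomp(substr(mature, 1, 13)) # pairs positions 1..13
  pre <- paste0(mature, strrep("A", 8), arm, "CC")
  g <- random_genome_with(pre, seed = 101)
  list(genome = g$genome, tag = mature,
       locus = list(chrom = "chr1", start = g$insert_start0,
                    end = g$insert_start0 + nchar(mature), strand = "+"))
}

# star arm carrying a 7-nt internal insertion: derived star is 28 nt,
# mature/star length difference 7
control_lendiff7 <- function() {
  mature <- "TGGAGCTCCCTTCATTCCAAT"
  rc <- oracle_revcomp(mature)
  arm <- paste0(substr(rc, 1, 10), "TTTTTTT", substr(rc, 11, 21))
  pre <- paste0(mature, strrep("A", 8), arm, "CC")
  g <- random_genome_with(pre, seed = 102)
  list(genome = g$genome, tag = mature,
       locus = list(chrom = "chr1", start = g$insert_start0,
                    end = g$insert_start0 + nchar(mature), strand = "+"))
}

# a strong extra stem-loop inserted between the two halves of the star
# arm: the mature-to-star span folds with two hairpin loops
control_bifurcated <- function() {
  mature <- "TGGAGCTCCCTTCATTCCAAT"
  rc <- oracle_revcomp(mature)
  extra <- "GGGGGGGCAAAAGCCCCCCC"             # independent hairpin
  arm <- paste0(substr(rc, 1, 10), extra, substr(rc, 11, 21))
  pre <- paste0(mature, strrep("A", 8), arm, "CC")
  g <- random_genome_with(pre, seed = 103)
  list(genome = g$genome, tag = mature,
       locus = list(chrom = "chr1", start = g$insert_start0,
                    end = g$insert_start0 + nchar(mature), strand = "+"))
}

# evaluate one hand-built control: excise + evaluate with the given read
# support, returning the candidate closest to acceptance
evaluate_control <- function(ctl, total_count = 50,
                             thresholds = discovery_thresholds(seed = 11)) {
  seeds <- excise_precursors(ctl$locus, ctl$genome,
                             window = thresholds$window,
                             margin = thresholds$margin)
  lt <- tibble::tibble(seq = ctl$tag, start = integer(0), count = integer(0))
  cands <- lapply(seeds, function(s) {
    lt2 <- tibble::tibble(seq = ctl$tag, start = s$tag_start,
                          count = as.integer(total_count))
    evaluate_candidate(s, lt2, total_count, thresholds)
  })
  n_pass <- vapply(cands, function(cc) sum(cc$verdicts), numeric(1))
  cands[[which.max(n_pass)]]
}

# --- shared zero-noise reference run -----------------------------------
# generated once per test session and reused: the canonical study
# conditions (100 kb genome, 20 planted hairpins, 3 tissues).
.run_cache <- new.env(parent = emptyenv())

reference_run <- function() {
  if (is.null(.run_cache$run)) {
    .run_cache$run <- run_pipeline(pipeline_config(seed = 1))
  }
  .run_cache$run
}
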