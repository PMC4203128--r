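# Reference screens (exact substring, both strands) and conserved
# matching (mismatch-bounded sliding alignment).

test_that("screens discard exact-substring matches on either strand", {
  rrna <- paste0(strrep("GC", 50), "TGACAGAAGAGAGTGAGCACA", strrep("AT", 50))
  trna <- paste0(strrep("CT", 30), "GGGTTTCCCAAAGGGTTTCCCAA", strrep("GA", 30))
  tags <- tibble::tibble(
    seq = c("TGACAGAAGAGAGTGAGCACA",                  # inside rRNA
            revcomp("GGGTTTCCCAAAGGGTTTCCC"),          # revcomp of tRNA region
            "ACACACACACACACACACACA"),                  # nowhere
    shoot = c(5L, 3L, 2L)
  )
  out <- screen_tags(tags, list(rRNA = c(r1 = rrna), tRNA = c(t1 = trna)))
  expect_equal(nrow(out$retained), 1)
  expect_equal(out$retained$seq, "ACACACACACACACACACACA")
  expect_equal(sort(out$discarded$screen), c("rRNA", "tRNA"))
  expect_equal(out$tally$n_reads[out$tally$screen == "rRNA"], 5)

  expect_warning(res <- screen_tags(tags, list()), "retained")
  expect_equal(nrow(res$retained), 3)
})

test_that("every tag lands in exactly one of screen/conserved/unmatched", {
  set.seed(31)
  known <- tibble::tibble(
    id = sprintf("cme-miR%03da", 1:10),
    seq = replicate(10, paste(sample(c("A", "C", "G", "T"), 21,
                                     replace = TRUE), collapse = ""))
  )
  screen_seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                      collapse = "")
  tags <- tibble::tibble(
    seq = c(known$seq[1],                              # conserved, 0 mm
            substr(screen_seq, 10, 30),                # screened
            replicate(20, paste(sample(c("A", "C", "G", "T"), 21,
                                       replace = TRUE), collapse = ""))),
    shoot = 1L
  )
  sc <- screen_tags(tags, list(rRNA = c(r = screen_seq)))
  mk <- match_known_mirnas(sc$retained, known)
  expect_equal(nrow(sc$discarded) + nrow(mk$hits) + nrow(mk$unmatched),
               nrow(tags))
  expect_length(
    intersect(mk$hits$seq, c(sc$discarded$seq, mk$unmatched$seq)), 0
  )
})

test_that("conserved matching obeys the 2-mismatch bound", {
  base <- "TGACAGAAGAGAGTGAGCACA"
  known <- tibble::tibble(id = "cme-miR156a", seq = base)
  mutate_at <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  tags <- tibble::tibble(
    seq = c(base, mutate_at(base, c(3, 9)), mutate_at(base, c(3, 9, 15))),
    shoot = 1L
  )
  mk <- match_known_mirnas(tags, known)
  expect_equal(nrow(mk$hits), 2)
  expect_equal(mk$hits$mismatches, c(0L, 2L))
  expect_equal(mk$hits$family, rep("miR156", 2))
  expect_equal(mk$unmatched$seq, tags$seq[3])
})

test_that("length slop and the 20-24 nt window are respected", {
  base <- "TGACAGAAGAGAGTGAGCACA"                      # 21 nt
  known <- tibble::tibble(id = "cme-miR156a", seq = base)
  # 23-nt tag containing the known: the shorter slides fully inside, 0 mm
  ext2 <- paste0(base, "GG")
  # 24-nt tag: length difference 3 excludes it outright
  ext3 <- paste0(base, "GGG")
  # 19-nt tag: inside the known, 0 positional mm, but below the 20 nt floor
  sub19 <- substr(base, 1, 19)
  # 20-nt tag hanging 2 nt off the known's end: overhang counts as 2 mm
  hang <- paste0(substr(base, 4, 21), "GG")
  stopifnot(oracle_slide_mm(hang, base) == 2)
  mk <- match_known_mirnas(tibble::tibble(seq = c(ext2, ext3, sub19, hang),
                                          shoot = 1L), known)
  expect_setequal(mk$hits$seq, c(ext2, hang))
  expect_equal(mk$hits$mismatches[mk$hits$seq == ext2], 0L)
  expect_equal(mk$hits$mismatches[mk$hits$seq == hang], 2L)
})

test_that("matcher agrees with the brute-force sliding-Hamming oracle", {
  set.seed(77)
  known <- tibble::tibble(
    id = sprintf("ref-miR%03d", 1:50),
    seq = replicate(50, paste(sample(c("A", "C", "G", "T"),
                                     sample(19:25, 1), replace = TRUE),
                              collapse = ""))
  )
  tags <- tibble::tibble(
    seq = replicate(120, paste(sample(c("A", "C", "G", "T"),
                                      sample(20:24, 1), replace = TRUE),
                               collapse = "")),
    shoot = 1L
  )
  # seed a few near-misses so hits exist
  for (k in 1:6) {
    s <- known$seq[k]
    p <- 4 + k
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, p, p))[1]
    if (nchar(s) >= 20 && nchar(s) <= 24) tags$seq[k] <- s
  }
  mk <- match_known_mirnas(tags, known, max_mm = 2)
  for (i in seq_len(nrow(tags))) {
    tl <- nchar(tags$seq[i])
    if (tl < 20 || tl > 24) next
    cand <- known[abs(nchar(known$seq) - tl) <= 2, ]
    mms <- vapply(cand$seq, function(r) oracle_slide_mm(tags$seq[i], r),
                  integer(1))
    best <- if (length(mms) > 0) min(mms) else Inf
    in_hits <- tags$seq[i] %in% mk$hits$seq
    expect_equal(in_hits, is.finite(best) && best <= 2, info = tags$seq[i])
    if (in_hits) {
      hit <- mk$hits[mk$hits$seq == tags$seq[i], ]
      expect_equal(hit$mismatches, as.integer(best))
      # tie-break: lexicographically smallest reference id
      expect_equal(hit$ref_id, min(cand$id[mms == best]))
    }
  }
})

test_that("mismatch-tolerant screening is opt-in", {
  ref <- paste0(strrep("GC", 30), "TGACAGAAGAGAGTGAGCACA", strrep("AT", 30))
  near <- "TGACAGAAGAGAGTGAGCACA"
  substr(near, 10, 10) <- "C"   # one mismatch vs the embedded region
  tags <- tibble::tibble(seq = near, shoot = 1L)
  exact <- screen_tags(tags, list(rRNA = c(r = ref)))
  expect_equal(nrow(exact$retained), 1)            # exact mode keeps it
  tol <- screen_tags(tags, list(rRNA = c(r = ref)), max_mm = 1)
  expect_equal(nrow(tol$retained), 0)              # tolerant mode drops it
})

test_that("family parsing extracts the miR-number token", {
  expect_equal(mirna_family(c("cme-miR156a", "ath-MIR172b-3p", "weird")),
               c("miR156", "miR172", "unassigned"))
})
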