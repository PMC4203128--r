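# Complementarity penalty scoring and target-site search.

test_that("pairing scores follow the weight table and seed multiplier", {
  all_match <- rep("match", 21)
  expect_equal(score_pairing(all_match), 0)

  gu15 <- replace(all_match, 15, "GU")       # outside seed region
  expect_equal(score_pairing(gu15), 0.5)

  mm5 <- replace(all_match, 5, "mismatch")   # inside positions 2-13
  expect_equal(score_pairing(mm5), 2.0)

  gap3 <- replace(all_match, 3, "gap")
  expect_equal(score_pairing(gap3), 4.0)     # 2.0 doubled in seed

  expect_error(score_pairing(replace(replace(all_match, 3, "gap"),
                                     17, "gap")), "one gap")
  expect_error(score_pairing(c("match", "oops")), "unknown")
})

test_that("penalty is monotone under added non-matches", {
  set.seed(14)
  for (i in 1:30) {
    st <- sample(c("match", "GU", "mismatch"), 21, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
    base <- score_pairing(st)
    pos <- sample(which(st == "match"), 1)
    for (worse in c("GU", "mismatch")) {
      expect_gte(score_pairing(replace(st, pos, worse)), base)
    }
  }
})

test_that("inhibition mode is decided at positions 10-11", {
  perfect <- rep("match", 21)
  expect_equal(classify_mode(perfect), "cleavage")
  expect_equal(classify_mode(replace(perfect, 10, "mismatch")),
               "translation")
  expect_equal(classify_mode(replace(perfect, 11, "GU")), "translation")
  expect_equal(classify_mode(replace(perfect, 3, "mismatch")), "cleavage")
  expect_error(classify_mode(rep("match", 9)), "11")
})

test_that("perfect-complement sites are found with penalty 0, cleavage", {
  set.seed(23)
  mirna <- "TGACAGAAGAGAGTGAGCACA"
  bg <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  tx <- bg
  substr(tx, 80, 100) <- revcomp(mirna)
  hits <- find_targets(mirna, tibble::tibble(transcript_id = "t1",
                                             seq = tx))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$penalty, 0)
  expect_equal(hits$mode, "cleavage")
  expect_equal(hits$target_start, 79L)
  expect_equal(hits$pairing, strrep("|", 21))
})

test_that("a central mismatch flips the mode; 3.0 alignments are not hits", {
  mirna <- "TGACAGAAGAGAGTGAGCACA"
  site <- revcomp(mirna)
  # mismatch opposite miRNA position 10: site position 21-10+1 = 12
  substr(site, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                  substr(site, 12, 12))[2]
  tx <- paste0(strrep("C", 50), site, strrep("C", 50))
  hits <- find_targets(mirna, tibble::tibble(transcript_id = "t", seq = tx),
                       max_penalty = 2.5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mode, "translation")

  # three non-seed mismatches -> penalty 3.0 -> no hit at 2.5
  site3 <- revcomp(mirna)
  for (p in c(2, 4, 6)) {  # opposite miRNA positions 20, 18, 16
    repl <- setdiff(c("A", "C", "G", "T"), substr(site3, p, p))
    # avoid creating a G:U wobble (weight 0.5) instead of a mismatch
    mi_pos <- nchar(mirna) - p + 1
    mi_base <- substr(mirna, mi_pos, mi_pos)
    bad <- c(G = "C", C = "G", A = "T", T = "A")[[mi_base]]  # complement
    wob <- c(G = "T", T = "G")[mi_base]
    choice <- setdiff(repl, c(bad, wob))[1]
    substr(site3, p, p) <- choice
  }
  tx3 <- paste0(strrep("C", 30), site3, strrep("C", 30))
  states <- strsplit(find_targets(mirna,
                                  tibble::tibble(transcript_id = "t",
                                                 seq = tx3),
                                  max_penalty = 10)$pairing, "")[[1]]
  expect_equal(sum(states == "x"), 3)
  expect_equal(nrow(find_targets(mirna,
                                 tibble::tibble(transcript_id = "t",
                                                seq = tx3),
                                 max_penalty = 2.5)), 0)
})

test_that("search agrees with exhaustive offset + gap enumeration", {
  set.seed(61)
  for (rep in 1:3) {
    mirna <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                   collapse = "")
    txs <- tibble::tibble(
      transcript_id = sprintf("t%d", 1:3),
      seq = replicate(3, paste(sample(c("A", "C", "G", "T"), 200,
                                      replace = TRUE), collapse = ""))
    )
    # plant a near-perfect site so some hits exist
    site <- oracle_revcomp(mirna)
    substr(site, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                  substr(site, 7, 7))[1]
    substr(txs$seq[2], 100, 120) <- site

    hits <- find_targets(mirna, txs, max_penalty = 6)
    for (t in seq_len(nrow(txs))) {
      oracle <- oracle_best_target(mirna, txs$seq[t], max_penalty = 6)
      mine <- hits[hits$transcript_id == txs$transcript_id[t], ]
      if (is.null(oracle)) {
        expect_equal(nrow(mine), 0)
      } else {
        expect_equal(nrow(mine), 1)
        expect_equal(mine$penalty, oracle$penalty, tolerance = 1e-9)
        expect_equal(mine$target_start, oracle$target_start)
      }
    }
  }
})

test_that("accessibility proxy is 1 on unstructured sites, low on stems", {
  open_tx <- paste0(strrep("A", 60), strrep("C", 21), strrep("A", 60))
  expect_equal(site_accessibility(open_tx, 60, 21), 1.0)
  stem <- paste0(strrep("G", 30), strrep("A", 5), strrep("C", 30))
  buried <- paste0(strrep("A", 40), stem, strrep("A", 40))
  expect_lt(site_accessibility(buried, 42, 21), 0.5)
})

test_that("planted perfect sites are all recovered across a call set", {
  cfg <- sim_config(genome_length = 30000, n_loci = 6, n_conserved = 0,
                    n_isoform = 0, seed = 33)
  sim <- plant_genome(cfg)
  tx <- simulate_transcripts(sim, n_decoys = 3, transcript_len = 250)
  calls <- tibble::tibble(id = sim$truth$id, seq = sim$truth$mature_seq)
  hits <- predict_targets(calls, tx$transcripts)
  planted <- dplyr::inner_join(tx$sites, hits,
                               by = c("mirna_id", "transcript_id"))
  expect_equal(nrow(planted), nrow(tx$sites))      # recall 1.0
  expect_true(all(planted$penalty == 0))
  expect_equal(planted$target_start, planted$site_start)
})
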