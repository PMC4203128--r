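# Genome mapping, precursor excision, the criteria checklist, family
# clustering, genomic-context annotation.

test_that("tag mapping reports exact placements on both strands", {
  set.seed(55)
  bg <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
              collapse = "")
  tag <- "TGACAGAAGAGAGTGAGCACA"
  g <- bg
  substr(g, 11, 31) <- tag                       # forward at 0-based 10
  substr(g, 51, 71) <- revcomp(tag)              # minus-strand at 50
  genome <- c(chr1 = g)
  hits <- map_tags(tibble::tibble(seq = tag, shoot = 1L), genome)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_true(any(fwd$start == 10 & fwd$end == 31))
  expect_true(any(rev$start == 50 & rev$end == 71))

  # agreement with a naive full scan of both strands
  naive_fwd <- as.integer(gregexpr(tag, g, fixed = TRUE)[[1]]) - 1L
  naive_rev <- as.integer(gregexpr(revcomp(tag), g, fixed = TRUE)[[1]]) - 1L
  naive_fwd <- naive_fwd[naive_fwd >= 0]
  naive_rev <- naive_rev[naive_rev >= 0]
  expect_setequal(fwd$start, naive_fwd)
  expect_setequal(rev$start, naive_rev)
})

test_that("multi-mapping tags beyond the cutoff are flagged", {
  unit <- "TGACAGAAGAGAGTGAGCACA"
  g <- paste(rep(paste0(unit, strrep("C", 30)), 20), collapse = "")
  hits <- map_tags(tibble::tibble(seq = unit, shoot = 1L),
                   c(chr1 = g), max_loci = 15)
  expect_true(all(hits$multi_mapped))
  expect_equal(unique(hits$n_loci), 20L)
})

test_that("excision windows follow the stated arithmetic and clipping", {
  genome <- c(chr1 = paste(rep("ACGT", 2500), collapse = ""))
  locus <- list(chrom = "chr1", start = 1000L, end = 1021L, strand = "+")
  seeds <- excise_precursors(locus, genome, window = 250, margin = 20)
  expect_equal(length(seeds), 2)
  expect_equal(c(seeds[[1]]$window_start, seeds[[1]]$window_end),
               c(980L, 1230L))
  expect_equal(c(seeds[[2]]$window_start, seeds[[2]]$window_end),
               c(791L, 1041L))
  expect_equal(seeds[[1]]$tag_start, 21L)
  # tag sequence is recoverable from the window
  expect_equal(seeds[[1]]$tag_seq,
               substr(genome[[1]], 1001, 1021))

  # near the chromosome start the upstream window clips to 0
  near <- list(chrom = "chr1", start = 5L, end = 26L, strand = "+")
  s2 <- excise_precursors(near, genome)
  expect_equal(s2[[1]]$window_start, 0L)

  # minus strand: window sequence is the reverse complement
  minus <- list(chrom = "chr1", start = 1000L, end = 1021L, strand = "-")
  s3 <- excise_precursors(minus, genome)
  expect_equal(s3[[1]]$window_seq,
               revcomp(substr(genome[[1]],
                              s3[[1]]$window_start + 1,
                              s3[[1]]$window_end)))
  expect_equal(s3[[1]]$tag_seq, revcomp(substr(genome[[1]], 1001, 1021)))
})

test_that("a compliant planted hairpin passes every criterion", {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  hp <- build_hairpin(mature)
  g <- random_genome_with(hp$precursor, seed = 100)
  locus <- list(chrom = "chr1", start = g$insert_start0,
                end = g$insert_start0 + nchar(mature), strand = "+")
  seeds <- excise_precursors(locus, g$genome)
  lt <- tibble::tibble(seq = mature, start = seeds[[1]]$tag_start,
                       count = 50L)
  cand <- evaluate_candidate(seeds[[1]], lt, 50,
                             discovery_thresholds(seed = 11))
  expect_true(all(cand$verdicts))
  expect_true(cand$accepted)
  expect_gte(cand$duplex_pairs, 14)
  expect_equal(cand$len_diff, 0L)
  expect_equal(cand$star_seq, hp$star)
})

test_that("rejection-injected controls fail on the matching verdict", {
  th <- discovery_thresholds(seed = 11)

  c13 <- evaluate_control(control_duplex13(), total_count = 50, th)
  expect_false(c13$verdicts[["duplex14"]])
  expect_false(c13$accepted)
  expect_lt(c13$duplex_pairs, 14)

  c7 <- evaluate_control(control_lendiff7(), total_count = 50, th)
  expect_false(c7$verdicts[["len_diff6"]])
  expect_false(c7$accepted)
  expect_gt(c7$len_diff, 6)

  cb <- evaluate_control(control_bifurcated(), total_count = 50, th)
  expect_false(cb$verdicts[["no_bifurcation"]])
  expect_false(cb$accepted)

  # read-support boundary: 9 reads fail, 10 pass (all else compliant)
  mature <- "TGACAGAAGAGAGTGAGCACA"
  hp <- build_hairpin(mature)
  g <- random_genome_with(hp$precursor, seed = 104)
  locus <- list(chrom = "chr1", start = g$insert_start0,
                end = g$insert_start0 + nchar(mature), strand = "+")
  seeds <- excise_precursors(locus, g$genome)
  lt <- tibble::tibble(seq = mature, start = seeds[[1]]$tag_start,
                       count = 9L)
  c9 <- evaluate_candidate(seeds[[1]], lt, 9, th)
  expect_false(c9$verdicts[["min_reads"]])
  expect_false(c9$accepted)
  lt$count <- 10L
  c10 <- evaluate_candidate(seeds[[1]], lt, 10, th)
  expect_true(c10$verdicts[["min_reads"]])
  expect_true(c10$accepted)
})

test_that("Dicer consistency gates candidates without a dominant 5' end", {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  hp <- build_hairpin(mature)
  g <- random_genome_with(hp$precursor, seed = 105)
  locus <- list(chrom = "chr1", start = g$insert_start0,
                end = g$insert_start0 + nchar(mature), strand = "+")
  seeds <- excise_precursors(locus, g$genome)
  a <- seeds[[1]]$tag_start
  # another tag at the locus with a different 5' start and more reads
  lt <- tibble::tibble(seq = c(mature, "other"),
                       start = c(a, a + 5L), count = c(20L, 30L))
  cand <- evaluate_candidate(seeds[[1]], lt, 20,
                             discovery_thresholds(seed = 11))
  expect_false(cand$verdicts[["dicer"]])
  expect_equal(cand$dicer_consistency, 0.4)
})

test_that("family clustering follows identity, naming, and isoform rules", {
  s <- "TGACAGAAGAGAGTGAGCACA"
  mutate_at <- function(x, pos) {
    for (p in pos) {
      substr(x, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(x, p, p))[1]
    }
    x
  }
  calls <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    seq = c(s, s, mutate_at(s, c(2, 6, 10, 14, 18)), mutate_at(s, 5)),
    class = c("novel", "novel", "novel", "conserved"),
    family = c(NA, NA, NA, "miR156"),
    shoot = c(10L, 10L, 50L, 100L)
  )
  fam <- cluster_families(calls, identity = 0.90)
  # identical pair clusters together; 5/21 differences (identity 0.762)
  # keep c separate
  fa <- fam$calls$family
  expect_equal(fa[1], fa[2])
  expect_false(fa[3] == fa[1])
  # d (conserved) differs from s by one base: identity 20/21 = 0.952,
  # same family; family keeps the conserved name and a/b become isoforms
  expect_equal(fa[4], "miR156")
  expect_equal(fa[1], "miR156")
  expect_equal(fam$calls$class[1], "novel_isoform")
  expect_equal(fam$calls$class[3], "novel")
  # every call is in exactly one family and the clustering is
  # deterministic
  expect_false(anyNA(fa))
  fam2 <- cluster_families(calls, identity = 0.90)
  expect_identical(fam$calls, fam2$calls)
})

test_that("genomic context classification applies CDS > UTR > intron", {
  features <- tibble::tibble(
    chrom = "chr1", source = "t", strand = "+",
    type = c("gene", "five_prime_UTR", "CDS", "CDS"),
    start = c(1000L, 1000L, 1200L, 2000L),
    end = c(3000L, 1200L, 1700L, 2500L),
    gene_id = "G1"
  )
  calls <- tibble::tibble(
    id = sprintf("m%d", 1:4),
    seq = strrep("A", 21),
    family = "f",
    chrom = "chr1",
    start = c(1800L, 1100L, 1650L, 5000L),
    end = c(1821L, 1121L, 1750L, 5021L)
  )
  ctx <- annotate_context(calls, features)
  expect_equal(ctx$calls$context,
               c("intron", "UTR", "CDS", "intergenic"))
})

test_that("tandem clusters respect the gap window", {
  calls <- tibble::tibble(
    id = sprintf("m%d", 1:3),
    seq = strrep("A", 21),
    family = c("miR156", "miR156", "miR156"),
    chrom = "chr1",
    start = c(1000L, 6000L, 30000L),
    end = c(1021L, 6021L, 30021L)
  )
  ctx <- annotate_context(calls, tibble::tibble(
    chrom = character(0), type = character(0),
    start = integer(0), end = integer(0)
  ), cluster_window = 10000)
  expect_equal(nrow(ctx$clusters), 1)
  expect_equal(ctx$clusters$n_loci, 2)
  expect_true(ctx$clusters$same_family)
  expect_true(all(ctx$calls$context == "intergenic"))
})
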