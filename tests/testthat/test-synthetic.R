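# Synthetic genome / library generator: hairpin geometry, planting
# self-consistency, determinism, read emission.

test_that("constructed hairpins fold into a single clean stem-loop", {
  mature <- "TGACAGAAGAGAGTGAGCACA"       # generic 21-nt mature
  hp <- build_hairpin(mature, loop_len = 8, mutation_rate = 0)
  f <- fold_maxpair(hp$precursor)
  expect_equal(f$score, 21)              # every mature base paired
  a <- parse_hairpin(f)
  expect_equal(a$n_hairpin_loops, 1)
  expect_false(a$has_bifurcation)
  expect_equal(nchar(hp$star), 21)

  # a self-complementary repeat mature still reaches the full pair count
  # (its max-pair optimum is degenerate, so loop topology is not asserted)
  rep_m <- paste0(strrep("ACGU", 5), "A")
  expect_equal(fold_maxpair(build_hairpin(rep_m)$precursor)$score, 21)

  # 3p-arm construction mirrors the geometry
  hp3 <- build_hairpin("TGACAGAAGAGAGTGAGCACA", arm = "3p")
  f3 <- fold_maxpair(hp3$precursor)
  expect_equal(f3$score, 21)
  expect_equal(nchar(hp3$star), 21)
  expect_equal(parse_hairpin(f3)$n_hairpin_loops, 1)
})

test_that("hairpin construction is deterministic and validates inputs", {
  mature <- paste0(strrep("ACGU", 5), "A")
  a <- build_hairpin(mature, mutation_rate = 0.1, rng_seed = 5)
  b <- build_hairpin(mature, mutation_rate = 0.1, rng_seed = 5)
  expect_identical(a, b)

  expect_error(build_hairpin("ACGTACGTACGTACGT"), "20-24")        # 16 nt
  expect_error(build_hairpin(strrep("ACGTA", 5)), "20-24")        # 25 nt
  expect_error(build_hairpin(mature, loop_len = 2), "loop")
})

test_that("stem mutations never destroy more than 20% of pairs", {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  for (seed in 1:5) {
    hp <- build_hairpin(mature, mutation_rate = 0.5, rng_seed = seed)
    f <- fold_maxpair(hp$precursor)
    # wobbles still pair; only mismatches reduce the count, capped at 20%
    expect_gte(f$score, ceiling(0.8 * nchar(mature)))
  }
})

test_that("planted loci are recoverable from the genome verbatim", {
  sim <- plant_genome(sim_config(genome_length = 50000, n_loci = 10,
                                 seed = 3))
  expect_equal(nrow(sim$truth), 10)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    slice <- substr(sim$genome[[tr$chrom]], tr$start + 1, tr$end)
    planted <- if (tr$strand == "+") slice else revcomp(slice)
    expect_equal(planted, tr$precursor_seq)
    expect_equal(substr(tr$precursor_seq, tr$mature_start, tr$mature_end),
                 tr$mature_seq)
    expect_equal(substr(tr$precursor_seq, tr$star_start, tr$star_end),
                 tr$star_seq)
  }
  # loci non-overlapping
  o <- order(sim$truth$start)
  expect_true(all(sim$truth$end[o][-10] <= sim$truth$start[o][-1]))
})

test_that("generation is deterministic and n_loci = 0 gives empty truth", {
  cfg <- sim_config(genome_length = 20000, n_loci = 4, seed = 8)
  a <- plant_genome(cfg)
  b <- plant_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)

  empty <- plant_genome(sim_config(genome_length = 5000, n_loci = 0,
                                   n_conserved = 0, seed = 1))
  expect_equal(nrow(empty$truth), 0)
  expect_equal(nchar(empty$genome[[1]]), 5000)

  expect_error(sim_config(genome_length = 1000, n_loci = 50), "fit")
})

test_that("background base composition matches the uniform model", {
  sim <- plant_genome(sim_config(genome_length = 80000, n_loci = 0,
                                 n_conserved = 0, seed = 21))
  counts <- table(strsplit(sim$genome[[1]], "")[[1]])
  n <- sum(counts)
  # each base ~ Binomial(n, 1/4); allow 5 sigma
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) < 5 * sigma))
})

test_that("read libraries carry exact configured counts at zero noise", {
  cfg <- sim_config(genome_length = 30000, n_loci = 4, n_conserved = 0,
                    n_isoform = 0, tissues = c("shoot", "root"),
                    star_fraction = 0.1, seed = 5)
  sim <- plant_genome(cfg)
  sim$truth$shoot <- c(50L, 0L, 20L, 10L)
  sim$truth$root <- c(0L, 30L, 20L, 10L)
  reads <- simulate_libraries(sim)

  shoot <- reads[reads$tissue == "shoot", ]
  # inserts = read minus adapter; compare against planted sequences
  n_mat1 <- sum(startsWith(shoot$seq, sim$truth$mature_seq[1]))
  expect_equal(n_mat1, 50)
  n_star1 <- sum(startsWith(shoot$seq, sim$truth$star_seq[1]))
  expect_equal(n_star1, 5)  # 50 * 0.1
  expect_equal(sum(startsWith(shoot$seq, sim$truth$mature_seq[2])), 0)

  # every insert is a planted mature or star followed by the adapter
  all_known <- c(sim$truth$mature_seq, sim$truth$star_seq)
  expect_true(all(vapply(reads$seq, function(s) {
    any(startsWith(s, all_known))
  }, logical(1))))

  # adapter present right after the insert
  first <- sim$truth$mature_seq[1]
  with_adapter <- shoot$seq[startsWith(shoot$seq, first)][1]
  expect_true(startsWith(substr(with_adapter, nchar(first) + 1, 100),
                         substr(cfg$adapter_seq, 1, 6)))
})

test_that("FASTQ round-trip preserves reads and qualities", {
  cfg <- sim_config(genome_length = 20000, n_loci = 3, n_conserved = 0,
                    n_isoform = 0, tissues = "shoot", seed = 12)
  sim <- plant_genome(cfg)
  reads <- simulate_libraries(sim)
  dir <- withr::local_tempdir()
  paths <- write_libraries_fastq(reads, dir)
  back <- read_fastq(paths[["shoot"]])
  expect_equal(nrow(back), nrow(reads))
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
  # 4-line grammar
  lines <- readLines(paths[["shoot"]])
  expect_equal(length(lines) %% 4, 0)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  expect_true(all(startsWith(lines[seq(3, length(lines), 4)], "+")))
})

test_that("library simulation is reproducible, including under jitter", {
  cfg <- sim_config(genome_length = 20000, n_loci = 3, n_conserved = 0,
                    n_isoform = 0, end_jitter_prob = 0.2, seed = 9)
  sim <- plant_genome(cfg)
  a <- simulate_libraries(sim)
  b <- simulate_libraries(sim)
  expect_identical(a, b)
})

test_that("lognormal count mode samples reproducibly", {
  cfg <- sim_config(genome_length = 20000, n_loci = 4, n_conserved = 0,
                    n_isoform = 0, count_mode = "lognormal", seed = 6)
  a <- plant_genome(cfg)
  b <- plant_genome(cfg)
  expect_identical(a$truth, b$truth)
  cm <- as.matrix(a$truth[, cfg$tissues])
  expect_true(all(cm >= 0))
  expect_gt(stats::sd(cm), 0)   # actually sampled, not a fixed pattern
})

test_that("config YAML round-trips", {
  cfg <- sim_config(genome_length = 30000, n_loci = 6, seed = 4,
                    mutation_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
})

test_that("unknown tissue labels in truth are rejected", {
  cfg <- sim_config(genome_length = 20000, n_loci = 2, n_conserved = 0,
                    n_isoform = 0, seed = 2)
  sim <- plant_genome(cfg)
  sim$config$tissues <- c("shoot", "root", "flower", "nodule")
  expect_error(simulate_libraries(sim), "nodule")
})
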