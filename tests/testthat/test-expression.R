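# Size factors, abundance categories, specificity calls, ddCT, platform
# correlation.

test_that("size factors reproduce the hand-derived median-of-ratios", {
  tbl <- tibble::tibble(id = c("a", "b", "c"),
                        A = c(10, 20, 30), B = c(20, 40, 60))
  sf <- estimate_size_factors(tbl)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  # normalized values equal across samples
  norm <- normalize_counts(tbl)
  expect_equal(norm$A, norm$B, tolerance = 1e-9)

  same <- tibble::tibble(id = c("a", "b"), A = c(5, 9), B = c(5, 9))
  expect_equal(unname(estimate_size_factors(same)), c(1, 1))

  # permuting rows leaves factors unchanged
  perm <- tbl[c(3, 1, 2), ]
  expect_equal(estimate_size_factors(perm), sf)

  zeros <- tibble::tibble(id = c("a", "b"), A = c(0, 3), B = c(2, 0))
  expect_error(estimate_size_factors(zeros), "pseudocount")
  expect_silent(estimate_size_factors(zeros, pseudocount = 1))
})

test_that("size factors agree with the DESeq reference implementation", {
  set.seed(19)
  m <- matrix(rpois(60, lambda = 50), nrow = 12,
              dimnames = list(sprintf("g%02d", 1:12), LETTERS[1:5]))
  m[, 3] <- m[, 3] * 3L
  expect_equal(unname(estimate_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("exact library scaling is recovered in the factors", {
  set.seed(9)
  a <- rpois(20, 100) + 1
  for (c_scale in c(2, 0.5, 7)) {
    m <- cbind(A = a, B = a * c_scale)
    rownames(m) <- sprintf("g%d", 1:20)
    sf <- estimate_size_factors(m)
    expect_equal(unname(sf[2] / sf[1]), c_scale, tolerance = 1e-9)
  }
})

test_that("normalization equalizes the between-sample median ratio", {
  # exact for sample pairs with an odd row count: per-row ratios to the
  # geometric mean are reciprocal and the median is a single row, so the
  # normalized median ratio is exactly 1 (an even count averages the two
  # middle rows arithmetically, leaving a sub-1e-4 residual)
  set.seed(29)
  for (rep in 1:5) {
    n <- sample(c(11, 15, 19, 21, 25), 1)
    m <- matrix(rpois(2 * n, 60) + 1, nrow = n,
                dimnames = list(sprintf("g%d", seq_len(n)), c("A", "B")))
    m[, 2] <- m[, 2] * sample(2:5, 1)
    norm <- normalize_counts(m)
    nm <- as.matrix(tibble::as_tibble(norm)[, -1])
    expect_equal(stats::median(nm[, 1] / nm[, 2]), 1, tolerance = 1e-9)
  }
})

test_that("abundance binning is half-open, labeled, and monotone", {
  x <- c(5, 50, 500, 10, 50000, 0, 9999.9, 10000)
  got <- categorize_abundance(x)
  expect_equal(as.character(got),
               c("very_low", "low", "moderate", "low", "very_high",
                 "very_low", "high", "very_high"))
  xs <- sort(runif(50, 0, 20000))
  expect_false(is.unsorted(categorize_abundance(xs)))
  expect_error(categorize_abundance(5, breaks = c(10, 5, 100, 1000)),
               "ascending")
})

test_that("specificity calls cover the four categories", {
  m <- matrix(c(100, 0, 0, 0, 0, 0, 0,
                10, 10, 10, 10, 10, 10, 10,
                80, 10, 5, 5, 0, 0, 0,
                3, 2, 1, 0, 0, 0, 0),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("spec", "ubiq", "pref", "low"),
                              paste0("t", 1:7)))
  calls <- rank_tissue_preference(m)
  expect_equal(calls$category,
               c("specific", "ubiquitous", "preferential",
                 "below_detection"))
  expect_equal(calls$top_fraction[1], 1.0)
  expect_equal(calls$preferred_tissue[3], "t1")
  # fractions sum to one where the total is positive
  frs <- as.matrix(calls[1:3, grep("^frac_", names(calls))])
  expect_equal(unname(rowSums(frs)), rep(1, 3), tolerance = 1e-12)

  short <- normalizer_shortlist(calls, n = 2)
  expect_true(all(short$category == "ubiquitous"))
})

test_that("delta-delta-CT matches the closed form", {
  ct <- tibble::tibble(
    target = rep(c("miR1", "U6"), each = 6),
    sample = rep(rep(c("A", "B"), each = 3), 2),
    replicate = rep(1:3, 4),
    ct = c(rep(25, 3), rep(24, 3), rep(20, 6))
  )
  rq <- delta_delta_ct(ct, reference_gene = "U6", calibrator_sample = "A")
  expect_equal(rq$rq[rq$sample == "A"], 1.0)
  expect_equal(rq$rq[rq$sample == "B"], 2.0)

  # ddCT of -3 gives RQ 8
  ct3 <- ct
  ct3$ct[ct3$target == "miR1" & ct3$sample == "B"] <- 22
  rq3 <- delta_delta_ct(ct3, "U6", "A")
  expect_equal(rq3$ddct[rq3$sample == "B"], -3)
  expect_equal(rq3$rq[rq3$sample == "B"], 8.0)

  expect_error(delta_delta_ct(ct, "U6", "Z"), "calibrator")
  expect_error(delta_delta_ct(ct, "U5", "A"), "reference")
})

test_that("platform correlation reproduces hand Pearson values", {
  # proportional on the log scale -> r = 1
  seq_vals <- tibble::tibble(id = "m", sample = c("a", "b", "c"),
                             normalized = c(1, 3, 7))  # +1 -> 2,4,8
  rq <- tibble::tibble(target = "m", sample = c("a", "b", "c"),
                       rq = c(1, 2, 4))
  expect_equal(correlate_platforms(seq_vals, rq)$r, 1.0, tolerance = 1e-12)

  rq_rev <- tibble::tibble(target = "m", sample = c("a", "b", "c"),
                           rq = c(4, 2, 1))
  expect_equal(correlate_platforms(seq_vals, rq_rev)$r, -1.0,
               tolerance = 1e-12)

  # hand Pearson on pairs (1,2),(2,4),(3,6) in log2 space
  sv <- tibble::tibble(id = "m", sample = c("a", "b", "c"),
                       normalized = c(1, 3, 7))
  rq2 <- tibble::tibble(target = "m", sample = c("a", "b", "c"),
                        rq = c(2, 4, 8))
  x <- log2(c(2, 4, 8)); y <- log2(c(2, 4, 8))
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_platforms(sv, rq2)$r, hand, tolerance = 1e-12)

  expect_error(
    correlate_platforms(sv[1:2, ], rq2[1:2, ]),
    "3"
  )
})
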