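# Synthetic genomes with planted miRNA hairpins and tissue-specific
# small-RNA libraries with known truth. Everything is deterministic under
# the config master seed; each stage draws from its own derived stream.
#
# On-disk alphabet is DNA (T); folding happens on RNA (U) downstream.

#' Synthetic study configuration
#'
#' Defaults describe the reference synthetic study: a 100 kb random genome
#' with 20 planted hairpin loci, three tissue libraries, exact per-tissue
#' counts (no sampling noise), Q30 qualities, and no contaminant or jitter
#' noise. All knobs are explicit so noisy stress configurations are one
#' call away.
#'
#' @param genome_length background genome length in bp
#' @param n_loci number of planted hairpin loci
#' @param tissues character vector of tissue labels
#' @param loop_len hairpin loop length, nt (>= 3)
#' @param flank_len genomic flank kept clear around each planted locus, bp
#' @param mutation_rate per-base probability of a stem imperfection
#'   (G:U wobble where possible, else a single mismatch), capped so that
#'   no more than 20% of stem pairs are disrupted
#' @param star_fraction star read count as a fraction of mature count
#' @param contaminant_fraction contaminant reads as a fraction of total
#'   real reads
#' @param adapter_seq 3' sequencing adapter appended to every insert
#' @param end_jitter_prob probability that a read is shifted by 1 nt at the
#'   5' or 3' end (isomiR-style imprecision)
#' @param lowq_read_fraction fraction of reads emitted with low-quality
#'   bases (to exercise the quality filter)
#' @param read_len sequenced read length; insert + adapter truncated to it
#' @param n_conserved number of planted loci mirrored into the synthetic
#'   known-miRNA set (the "conserved" loci)
#' @param n_isoform number of planted loci carrying a length variant of a
#'   conserved mature (3 nt longer: outside the 2-mismatch conserved
#'   match, inside the 90% family-identity radius), so the
#'   novel-isoform path is exercised
#' @param count_mode `"exact"` (per-tissue integers from a fixed pattern
#'   cycle, truth exact) or `"lognormal"` (sampled, stress tests only)
#' @param seed master seed; all stage seeds derive from it
#' @return a `mir_sim_config` list
#' @export
sim_config <- function(genome_length = 100000,
                       n_loci = 20,
                       tissues = c("shoot", "root", "flower"),
                       loop_len = 8,
                       flank_len = 20,
                       mutation_rate = 0,
                       star_fraction = 0.1,
                       contaminant_fraction = 0,
                       adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                       end_jitter_prob = 0,
                       lowq_read_fraction = 0,
                       read_len = 36,
                       n_conserved = 5,
                       n_isoform = 2,
                       count_mode = c("exact", "lognormal"),
                       seed = 1L) {
  count_mode <- match.arg(count_mode)
  probs <- c(mutation_rate, star_fraction, contaminant_fraction,
             end_jitter_prob, lowq_read_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all rate/probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  span <- 2 * 24 + loop_len + 2 + 2 * flank_len  # worst-case locus footprint
  if (n_loci * span > genome_length) {
    stop("n_loci loci of footprint ", span, " bp cannot fit in ",
         genome_length, " bp", call. = FALSE)
  }
  structure(
    list(
      genome_length = genome_length, n_loci = n_loci, tissues = tissues,
      loop_len = loop_len, flank_len = flank_len,
      mutation_rate = mutation_rate, star_fraction = star_fraction,
      contaminant_fraction = contaminant_fraction,
      adapter_seq = as_dna(adapter_seq),
      end_jitter_prob = end_jitter_prob,
      lowq_read_fraction = lowq_read_fraction,
      read_len = read_len, n_conserved = min(n_conserved, n_loci),
      n_isoform = min(n_isoform, max(0L, n_loci - n_conserved),
                      n_conserved),
      count_mode = count_mode, seed = as.integer(seed)
    ),
    class = "mir_sim_config"
  )
}

#' Build a hairpin precursor around a mature sequence
#'
#' Constructs a stem-loop precursor whose mature/star duplex leaves the
#' canonical 2-nt 3' overhang on both strands. With `mutation_rate = 0` the
#' stem is perfectly Watson-Crick paired; mutations hit the non-mature arm
#' as G:U wobbles where the facing mature base allows one, else single
#' mismatches, never disrupting more than 20% of stem pairs.
#'
#' For a 5p-arm mature the precursor is
#' `mature + loop + revcomp(mature) + 2 nt pad` (the pad realizes the star
#' 3' overhang); for a 3p-arm mature it is `revcomp(mature) + loop + mature`
#' and the star 3' overhang extends into the loop.
#'
#' @param mature mature miRNA sequence, 20-24 nt (DNA or RNA)
#' @param arm which arm carries the mature: `"5p"` or `"3p"`
#' @param loop_len loop length, nt (>= 3)
#' @param mutation_rate per-base stem imperfection probability
#' @param rng_seed integer seed (only consulted when `mutation_rate > 0`)
#' @return list: precursor, star (DNA strings), mature_start/mature_end and
#'   star_start/star_end (1-based inclusive within the precursor), arm
#' @examples
#' hp <- build_hairpin("TGACAGAAGAGAGTGAGCACA")
#' nchar(hp$precursor)
#' @export
build_hairpin <- function(mature, arm = c("5p", "3p"), loop_len = 8,
                          mutation_rate = 0, rng_seed = 1L) {
  arm <- match.arg(arm)
  mature <- as_dna(mature)
  m <- nchar(mature)
  if (m < 20 || m > 24) {
    stop("mature length must be 20-24 nt, got ", m, call. = FALSE)
  }
  if (loop_len < 3) {
    stop("loop_len must be >= 3 (folding cannot close the loop)",
         call. = FALSE)
  }
  loop <- strrep("A", loop_len)
  rc <- revcomp(mature)
  rc_ch <- strsplit(rc, "", fixed = TRUE)[[1]]
  if (mutation_rate > 0) {
    mat_ch <- strsplit(mature, "", fixed = TRUE)[[1]]
    rc_ch <- with_seed(rng_seed, {
      hit <- which(runif(m) < mutation_rate)
      cap <- floor(0.2 * m)
      if (length(hit) > cap) hit <- hit[seq_len(cap)]
      for (k in hit) {
        facing <- mat_ch[m + 1 - k]  # mature base paired with rc position k
        rc_ch[k] <- switch(facing,
          G = "T",  # G:U wobble
          T = "G",  # U:G wobble
          A = "C",  # mismatch (A:C)
          C = "A"   # mismatch (C:A)
        )
      }
      rc_ch
    })
  }
  rc_mut <- paste(rc_ch, collapse = "")
  if (arm == "5p") {
    # pad that cannot pair with the adjacent stem end
    pad <- if (substr(mature, 1, 1) %in% c("G", "T")) "AA" else "CC"
    precursor <- paste0(mature, loop, rc_mut, pad)
    mature_start <- 1L
    star_start <- m + loop_len + 3L
    star_end <- star_start + m - 1L
  } else {
    precursor <- paste0(rc_mut, loop, mature)
    mature_start <- m + loop_len + 1L
    star_start <- 3L
    star_end <- star_start + m - 1L
  }
  list(
    precursor = precursor,
    star = substr(precursor, star_start, star_end),
    mature_start = mature_start,
    mature_end = mature_start + m - 1L,
    star_start = star_start,
    star_end = star_end,
    arm = arm
  )
}

# fixed cycle of per-tissue expression patterns so truth is exact and
# covers both the specificity categories and a realistic dynamic range
# (small-RNA counts span orders of magnitude): uniform-ubiquitous,
# single-tissue specific (high), preferential, low-ubiquitous
count_pattern <- function(i, tissues) {
  nt <- length(tissues)
  sel <- (i - 1) %/% 4 %% nt + 1
  base <- switch((i - 1) %% 4 + 1,
    rep(40L, nt),
    {
      v <- rep(0L, nt)
      v[sel] <- 5000L
      v
    },
    {
      v <- rep(20L, nt)
      v[sel] <- 800L
      v
    },
    rep(15L, nt)
  )
  setNames(base, tissues)
}

random_mature <- function(len) {
  first <- sample(c("T", NT_DNA), 1, prob = c(0.6, rep(0.1, 4)))
  paste0(first, paste(sample(NT_DNA, len - 1, replace = TRUE), collapse = ""))
}

MIR_FAMILIES <- c(156, 159, 160, 164, 166, 167, 169, 171, 172, 319)

#' Plant hairpin loci in a random genome
#'
#' Generates an i.i.d.-uniform ACGT background genome and plants
#' `config$n_loci` non-overlapping hairpin precursors (random strand),
#' recording exact truth: sequences, loci (0-based half-open), per-tissue
#' counts, and which loci are mirrored into the synthetic known-miRNA set.
#'
#' @param config a [sim_config()] object
#' @return list of class `mir_sim`: `genome` (named character, DNA),
#'   `truth` (tibble: one row per planted miRNA), `known` (tibble of
#'   synthetic known mature miRNAs: id, family, seq), `contaminants`
#'   (tibble: label, seq), `config`
#' @export
plant_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "mir_sim_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    chrom <- "chr1"
    n <- config$genome_length
    genome_ch <- sample(NT_DNA, n, replace = TRUE)

    truth <- NULL
    if (config$n_loci > 0) {
      lens <- sample(c(20L, 21L, 22L, 24L), config$n_loci, replace = TRUE,
                     prob = c(0.15, 0.55, 0.1, 0.2))
      # conserved loci fixed at 21 nt so their isoform variants (3 nt
      # longer) stay within the 20-24 nt mature range
      lens[seq_len(config$n_conserved)] <- 21L
      matures <- vapply(lens, random_mature, character(1))
      iso_of <- rep(NA_character_, config$n_loci)
      if (config$n_isoform > 0) {
        for (k in seq_len(config$n_isoform)) {
          i <- config$n_conserved + k
          matures[i] <- paste0(
            matures[k], paste(sample(NT_DNA, 3, replace = TRUE),
                              collapse = "")
          )
          iso_of[i] <- sprintf("syn-mir-%03d", k)
        }
      }
      hairpins <- lapply(seq_len(config$n_loci), function(i) {
        hp <- build_hairpin(
          matures[i],
          arm = if (i %% 2 == 1) "5p" else "3p",
          loop_len = config$loop_len,
          mutation_rate = config$mutation_rate,
          rng_seed = derive_seed(config$seed, paste0("stem", i))
        )
        hp$strand <- sample(c("+", "-"), 1)
        hp
      })
      # non-overlapping placement with flank_len clearance
      foot <- vapply(hairpins, function(h) nchar(h$precursor), integer(1)) +
        2L * config$flank_len
      slots <- place_nonoverlapping(n, foot, max_tries = 200)
      if (is.null(slots)) {
        stop("could not place ", config$n_loci, " loci without overlap; ",
             "only ", length(attr(slots, "placed") %||% 0), " fit",
             call. = FALSE)
      }
      rows <- lapply(seq_len(config$n_loci), function(i) {
        hp <- hairpins[[i]]
        plen <- nchar(hp$precursor)
        start0 <- slots[i] + config$flank_len  # 0-based precursor start
        insert <- if (hp$strand == "+") hp$precursor else revcomp(hp$precursor)
        genome_ch[(start0 + 1):(start0 + plen)] <<-
          strsplit(insert, "", fixed = TRUE)[[1]]
        mature <- substr(hp$precursor, hp$mature_start, hp$mature_end)
        counts <- if (config$count_mode == "lognormal") {
          # stress mode: lognormal abundances (median ~50, sdlog 1.5)
          setNames(as.integer(round(rlnorm(length(config$tissues),
                                           log(50), 1.5))),
                   config$tissues)
        } else {
          count_pattern(i, config$tissues)
        }
        tibble::tibble(
          id = sprintf("syn-mir-%03d", i),
          mature_seq = mature,
          star_seq = hp$star,
          arm = hp$arm,
          chrom = chrom,
          start = start0,
          end = start0 + plen,
          strand = hp$strand,
          precursor_seq = hp$precursor,
          mature_start = hp$mature_start,
          mature_end = hp$mature_end,
          star_start = hp$star_start,
          star_end = hp$star_end,
          class = if (i <= config$n_conserved) "conserved" else "novel",
          isoform_of = iso_of[i],
          !!!as.list(counts)
        )
      })
      truth <- dplyr::bind_rows(rows)
    } else {
      truth <- tibble::tibble(
        id = character(0), mature_seq = character(0), star_seq = character(0),
        arm = character(0), chrom = character(0),
        start = integer(0), end = integer(0), strand = character(0),
        precursor_seq = character(0),
        mature_start = integer(0), mature_end = integer(0),
        star_start = integer(0), star_end = integer(0),
        class = character(0), isoform_of = character(0)
      )
      for (t in config$tissues) truth[[t]] <- integer(0)
    }

    # synthetic known-miRNA set: conserved loci mirrored in, every other
    # one with a single substitution so mismatch-tolerant matching is
    # exercised; family names cycle through common plant families
    known <- tibble::tibble(id = character(0), family = character(0),
                            seq = character(0))
    if (config$n_conserved > 0 && nrow(truth) > 0) {
      ks <- lapply(seq_len(config$n_conserved), function(i) {
        fam <- paste0("miR", MIR_FAMILIES[(i - 1) %% length(MIR_FAMILIES) + 1])
        s <- truth$mature_seq[i]
        if (i %% 2 == 0) {
          # one substitution at an interior position
          pos <- 5 + (i %% 10)
          old <- substr(s, pos, pos)
          substr(s, pos, pos) <- setdiff(NT_DNA, old)[1]
        }
        tibble::tibble(
          id = sprintf("cme-%s%s", fam, letters[(i - 1) %/%
                                                  length(MIR_FAMILIES) + 1]),
          family = fam, seq = s
        )
      })
      known <- dplyr::bind_rows(ks)
    }

    contaminants <- tibble::tibble(
      label = c("rRNA_5.8S", "tRNA_Gly", "chloroplast_frag"),
      seq = vapply(c(400L, 300L, 800L),
                   function(L) paste(sample(NT_DNA, L, replace = TRUE),
                                     collapse = ""),
                   character(1))
    )

    structure(
      list(
        genome = setNames(paste(genome_ch, collapse = ""), chrom),
        truth = truth, known = known, contaminants = contaminants,
        config = config
      ),
      class = "mir_sim"
    )
  })
}

# choose non-overlapping 0-based start slots for footprints `foot` on a
# chromosome of length n; NULL if a placement cannot be found
place_nonoverlapping <- function(n, foot, max_tries = 200) {
  k <- length(foot)
  for (try in seq_len(max_tries)) {
    starts <- sort(sample.int(n - max(foot), k)) - 1L
    ok <- TRUE
    for (i in seq_len(k - 1)) {
      if (starts[i] + foot[i] > starts[i + 1]) {
        ok <- FALSE
        break
      }
    }
    if (k == 1) ok <- TRUE
    if (ok) return(starts)
  }
  NULL
}

#' @export
print.mir_sim <- function(x, ...) {
  cat("<mir_sim> genome ", sum(nchar(x$genome)), " bp, ",
      nrow(x$truth), " planted loci, ",
      length(x$config$tissues), " tissues\n", sep = "")
  invisible(x)
}

#' Simulate per-tissue small-RNA read libraries
#'
#' Emits one set of reads per tissue: each planted mature sequence at its
#' configured per-tissue count, star reads at `star_fraction`, contaminant
#' reads as random 18-30 nt substrings of the contaminant sources, each
#' insert with the 3' adapter appended and the whole read truncated to
#' `read_len`. Qualities are constant Q30 except for the injectable
#' low-quality fraction. With all noise parameters 0 the insert multiset
#' equals the truth counts exactly.
#'
#' @param sim a `mir_sim` object from [plant_genome()]
#' @return tibble: read_id, tissue, seq, qual (Phred+33)
#' @export
simulate_libraries <- function(sim) {
  stopifnot(inherits(sim, "mir_sim"))
  config <- sim$config
  truth <- sim$truth
  if (nrow(truth) == 0 && config$contaminant_fraction == 0) {
    stop("nothing to simulate: empty truth and no contaminants",
         call. = FALSE)
  }
  missing_t <- setdiff(config$tissues, names(truth))
  if (length(missing_t) > 0 && nrow(truth) > 0) {
    stop("unknown tissue label(s) in truth counts: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "reads"), {
    all_rows <- list()
    for (tissue in config$tissues) {
      inserts <- character(0)
      for (i in seq_len(nrow(truth))) {
        cnt <- truth[[tissue]][i]
        if (cnt > 0) {
          inserts <- c(inserts, rep(truth$mature_seq[i], cnt))
          star_n <- round(cnt * config$star_fraction)
          if (star_n > 0) inserts <- c(inserts, rep(truth$star_seq[i], star_n))
        }
      }
      if (config$end_jitter_prob > 0 && length(inserts) > 0) {
        jit <- runif(length(inserts)) < config$end_jitter_prob
        inserts[jit] <- vapply(inserts[jit], jitter_insert, character(1),
                               truth = truth)
      }
      if (config$contaminant_fraction > 0) {
        n_cont <- round(length(inserts) * config$contaminant_fraction)
        if (n_cont > 0) {
          src <- sample.int(nrow(sim$contaminants), n_cont, replace = TRUE)
          lens <- sample(18:30, n_cont, replace = TRUE)
          starts <- vapply(seq_len(n_cont), function(k) {
            sample.int(nchar(sim$contaminants$seq[src[k]]) - lens[k] + 1, 1)
          }, integer(1))
          inserts <- c(inserts, substr(sim$contaminants$seq[src], starts,
                                       starts + lens - 1))
        }
      }
      if (length(inserts) == 0) next
      reads <- substr(paste0(inserts, config$adapter_seq), 1, config$read_len)
      qual <- strrep("?", nchar(reads))  # Q30 flat
      if (config$lowq_read_fraction > 0) {
        low <- runif(length(reads)) < config$lowq_read_fraction
        qual[low] <- vapply(nchar(reads[low]), function(L) {
          nbad <- ceiling(0.4 * L)
          paste0(strrep("+", nbad), strrep("?", L - nbad))  # Q10 run
        }, character(1))
      }
      all_rows[[tissue]] <- tibble::tibble(
        read_id = sprintf("%s_read_%06d", tissue, seq_along(reads)),
        tissue = tissue, seq = reads, qual = qual
      )
    }
    dplyr::bind_rows(all_rows)
  })
}

# shift an insert by 1 nt at a random end, using precursor context where
# the insert is a planted mature/star, else trimming
jitter_insert <- function(s, truth) {
  i <- match(s, truth$mature_seq)
  end5 <- sample(c(TRUE, FALSE), 1)
  if (!is.na(i)) {
    p <- truth$precursor_seq[i]
    a <- truth$mature_start[i]
    b <- truth$mature_end[i]
    if (end5 && a > 1) return(substr(p, a - 1, b))
    if (!end5 && b < nchar(p)) return(substr(p, a, b + 1))
  }
  if (end5) substr(s, 2, nchar(s)) else substr(s, 1, nchar(s) - 1)
}

#' Simulate a transcript set with planted miRNA target sites
#'
#' One transcript per selected planted miRNA carries the exact reverse
#' complement of the mature sequence at a recorded position; decoy
#' transcripts carry no planted site.
#'
#' @param sim a `mir_sim` object
#' @param n_decoys number of random decoy transcripts
#' @param transcript_len transcript length, nt
#' @return list: `transcripts` (tibble: transcript_id, seq),
#'   `sites` (tibble: mirna_id, transcript_id, site_start 0-based)
#' @export
simulate_transcripts <- function(sim, n_decoys = 5, transcript_len = 300) {
  stopifnot(inherits(sim, "mir_sim"))
  truth <- sim$truth
  with_seed(derive_seed(sim$config$seed, "transcripts"), {
    tx <- list()
    sites <- list()
    for (i in seq_len(nrow(truth))) {
      site <- revcomp(truth$mature_seq[i])
      pos0 <- sample.int(transcript_len - nchar(site) - 20, 1) + 10L
      s <- paste(sample(NT_DNA, transcript_len, replace = TRUE), collapse = "")
      substr(s, pos0 + 1, pos0 + nchar(site)) <- site
      id <- sprintf("TXN%03d", i)
      tx[[length(tx) + 1]] <- tibble::tibble(transcript_id = id, seq = s)
      sites[[length(sites) + 1]] <- tibble::tibble(
        mirna_id = truth$id[i], transcript_id = id, site_start = pos0
      )
    }
    for (d in seq_len(n_decoys)) {
      tx[[length(tx) + 1]] <- tibble::tibble(
        transcript_id = sprintf("DECOY%03d", d),
        seq = paste(sample(NT_DNA, transcript_len, replace = TRUE),
                    collapse = "")
      )
    }
    list(transcripts = dplyr::bind_rows(tx), sites = dplyr::bind_rows(sites))
  })
}

#' Simulate a simple gene annotation over the synthetic genome
#'
#' Places non-overlapping two-exon genes (UTRs at the ends, CDS in the
#' middle, an intron between the exons) independently of the planted miRNA
#' loci, so genomic-context classification has all four outcomes available.
#'
#' @param sim a `mir_sim` object
#' @param n_genes number of genes to place
#' @param gene_len gene span, bp
#' @return tibble of features: chrom, source, type, start, end (0-based
#'   half-open), strand, gene_id
#' @export
simulate_annotation <- function(sim, n_genes = 10, gene_len = 2000) {
  stopifnot(inherits(sim, "mir_sim"))
  n <- sum(nchar(sim$genome))
  chrom <- names(sim$genome)[1]
  # cap gene count so placement stays feasible on small genomes
  n_genes <- max(1L, min(n_genes, n %/% (2L * (gene_len + 200L))))
  with_seed(derive_seed(sim$config$seed, "annotation"), {
    starts <- place_nonoverlapping(n, rep(gene_len + 200L, n_genes))
    if (is.null(starts)) stop("cannot place genes", call. = FALSE)
    feats <- lapply(seq_len(n_genes), function(g) {
      s <- starts[g]
      # layout within the gene: 5'UTR(200) exon1-CDS(500) intron(600)
      #                         exon2-CDS(500) 3'UTR(200)
      tibble::tibble(
        chrom = chrom, source = "mirforge_sim",
        type = c("gene", "five_prime_UTR", "CDS", "CDS", "three_prime_UTR"),
        start = c(s, s, s + 200L, s + 1300L, s + 1800L),
        end = c(s + gene_len, s + 200L, s + 700L, s + 1800L, s + 2000L),
        strand = "+",
        gene_id = sprintf("GENE%03d", g)
      )
    })
    dplyr::bind_rows(feats)
  })
}

#' Simulate a qPCR CT table consistent with planted expression
#'
#' CT values are derived from true per-tissue counts on the standard
#' exponential scale (one cycle per doubling), with the reference gene at a
#' constant CT, so sequencing-based and qPCR-based quantification agree by
#' construction up to replicate jitter. The default assay panel is the
#' loci whose expression varies across tissues — the candidates a
#' validation experiment would target.
#'
#' @param sim a `mir_sim` object
#' @param mirna_ids planted ids to assay (default: up to 8
#'   variable-expression loci)
#' @param reference_gene reference label (constant CT 20)
#' @param n_replicates technical replicates per (target, sample)
#' @param jitter_sd replicate CT standard deviation, cycles
#' @return tibble: target, sample, replicate, ct
#' @export
simulate_qpcr <- function(sim, mirna_ids = NULL,
                          reference_gene = "U6", n_replicates = 3,
                          jitter_sd = 0.05) {
  if (is.null(mirna_ids)) {
    cm <- as.matrix(sim$truth[, sim$config$tissues, drop = FALSE])
    varying <- apply(cm, 1, function(r) stats::sd(r) > 0)
    mirna_ids <- head(sim$truth$id[varying], 8)
  }
  stopifnot(inherits(sim, "mir_sim"))
  truth <- sim$truth
  tissues <- sim$config$tissues
  with_seed(derive_seed(sim$config$seed, "qpcr"), {
    rows <- list()
    for (id in mirna_ids) {
      i <- match(id, truth$id)
      for (tis in tissues) {
        cnt <- truth[[tis]][i]
        ct0 <- 30 - log2(cnt + 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          target = id, sample = tis, replicate = seq_len(n_replicates),
          ct = ct0 + rnorm(n_replicates, 0, jitter_sd)
        )
      }
    }
    for (tis in tissues) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        target = reference_gene, sample = tis,
        replicate = seq_len(n_replicates),
        ct = 20 + rnorm(n_replicates, 0, jitter_sd)
      )
    }
    dplyr::bind_rows(rows)
  })
}
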