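# End-to-end orchestration: simulate (or load) inputs, preprocess each
# tissue library, screen, split conserved vs candidate-novel, discover,
# cluster, annotate, predict targets, normalize expression, validate
# in silico against qPCR — with one master seed driving every stochastic
# stage and a manifest that makes reruns comparable byte for byte.

#' Assemble a pipeline configuration
#'
#' @param sim a [sim_config()]; its seed is overridden by `seed`
#' @param thresholds a [discovery_thresholds()]; its seed is derived from
#'   `seed`
#' @param detection_min,pref_ratio,spec_frac specificity parameters, see
#'   [rank_tissue_preference()]
#' @param abundance_breaks thresholds for [categorize_abundance()]
#' @param max_penalty target-prediction cutoff
#' @param n_decoys,transcript_len synthetic transcript set shape
#' @param n_genes annotation size for genomic-context classification
#' @param inputs optional named list of external input paths (genome,
#'   reads_dir, known, annotation, transcripts); any path given must
#'   exist (pre-flight check) and replaces the corresponding simulated
#'   input
#' @param seed master seed
#' @return a `mir_pipeline_config` list
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = discovery_thresholds(),
                            detection_min = 10, pref_ratio = 2.0,
                            spec_frac = 0.90,
                            abundance_breaks = c(10, 100, 1000, 10000),
                            max_penalty = 2.5,
                            n_decoys = 5, transcript_len = 300,
                            n_genes = 10,
                            inputs = NULL,
                            seed = 1L) {
  seed <- as.integer(seed)
  sim$seed <- seed
  thresholds$seed <- derive_seed(seed, "shuffle")
  structure(
    list(
      sim = sim, thresholds = thresholds,
      detection_min = detection_min, pref_ratio = pref_ratio,
      spec_frac = spec_frac, abundance_breaks = abundance_breaks,
      max_penalty = max_penalty, n_decoys = n_decoys,
      transcript_len = transcript_len, n_genes = n_genes,
      inputs = inputs, seed = seed
    ),
    class = "mir_pipeline_config"
  )
}

#' Run the full discovery pipeline
#'
#' Stages run in order: simulation (or external input loading),
#' per-tissue preprocessing, ncRNA/contaminant screening, conserved
#' matching, novel discovery, family clustering, genomic-context
#' annotation, target prediction, expression normalization and
#' specificity calls, and in-silico qPCR validation. Identical
#' config + seed reproduce identical outputs; the manifest records
#' seeds, thresholds, and content hashes of every major table.
#'
#' @param config a [pipeline_config()]
#' @param verbose emit per-stage progress messages
#' @return a `mir_run` list: sim, tags, screen, conserved, discovery,
#'   calls, families, clusters, counts, specificity, targets, qpcr,
#'   platform_cor, truth_eval, summary, manifest
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "mir_pipeline_config"))
  say <- function(...) if (verbose) message("[mirforge] ", ...)

  # pre-flight: any external input must exist before anything runs
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs)
    gone <- paths[!file.exists(paths)]
    if (length(gone) > 0) {
      stop("input path(s) not found: ", paste(gone, collapse = ", "),
           call. = FALSE)
    }
  }

  say("simulate")
  sim <- plant_genome(config$sim)
  if (!is.null(config$inputs$genome)) {
    g <- read_fasta(config$inputs$genome)
    sim$genome <- setNames(g$seq, g$id)
    sim$truth <- sim$truth[0, ]
  }
  reads <- simulate_libraries(sim)

  say("preprocess")
  tissues <- unique(reads$tissue)
  tag_tables <- lapply(tissues, function(t) {
    preprocess_library(reads[reads$tissue == t, , drop = FALSE],
                       sample = t, adapter = config$sim$adapter_seq)
  })
  names(tag_tables) <- tissues
  pre_stats <- lapply(tag_tables, library_stats)
  tags <- merge_tag_tables(tag_tables)

  say("screen")
  screens <- split(setNames(sim$contaminants$seq, sim$contaminants$label),
                   sub("_.*$", "", sim$contaminants$label))
  sc <- screen_tags(tags, screens)

  say("conserved matching")
  known <- if (!is.null(config$inputs$known)) {
    read_fasta(config$inputs$known)
  } else {
    sim$known[, c("id", "seq")]
  }
  mk <- if (nrow(known) > 0) {
    match_known_mirnas(sc$retained, known)
  } else {
    list(hits = sc$retained[0, ], unmatched = sc$retained)
  }
  count_cols <- setdiff(names(tags), "seq")
  conserved_calls <- conserved_to_calls(mk$hits, sim$genome, count_cols)

  say("novel discovery")
  disc <- discover_mirnas(mk$unmatched, sim$genome, config$thresholds,
                          context_tags = mk$hits[, names(tags)])

  say("family clustering")
  calls <- dplyr::bind_rows(conserved_calls, disc$calls)
  fam <- cluster_families(calls)
  calls <- fam$calls

  say("genomic context")
  annotation <- if (!is.null(config$inputs$annotation)) {
    read_annotation_gff3(config$inputs$annotation)
  } else {
    simulate_annotation(sim, n_genes = config$n_genes)
  }
  ctx <- annotate_context(calls, annotation)
  calls <- ctx$calls

  say("targets")
  tx <- if (!is.null(config$inputs$transcripts)) {
    list(transcripts = dplyr::rename(read_fasta(config$inputs$transcripts),
                                     transcript_id = "id"),
         sites = NULL)
  } else {
    simulate_transcripts(sim, n_decoys = config$n_decoys,
                         transcript_len = config$transcript_len)
  }
  target_hits <- if (nrow(calls) > 0) {
    predict_targets(calls, tx$transcripts, max_penalty = config$max_penalty)
  } else {
    tibble::tibble()
  }

  say("expression")
  counts_tbl <- dplyr::bind_cols(
    tibble::tibble(id = calls$id),
    calls[, count_cols, drop = FALSE]
  )
  expr <- NULL
  spec <- NULL
  if (nrow(counts_tbl) >= 1 && length(count_cols) >= 2) {
    expr <- tryCatch(normalize_counts(counts_tbl),
                     error = function(e) normalize_counts(counts_tbl,
                                                          pseudocount = 1))
    spec <- rank_tissue_preference(expr,
                                   detection_min = config$detection_min,
                                   pref_ratio = config$pref_ratio,
                                   spec_frac = config$spec_frac)
    # peak abundance category per miRNA (five standard bins)
    nm <- count_matrix(as.data.frame(expr))
    spec$abundance <- categorize_abundance(
      apply(nm, 1, max)[match(spec$id, rownames(nm))],
      breaks = config$abundance_breaks
    )
  }

  say("qPCR validation")
  qp <- NULL
  platform_cor <- NULL
  if (nrow(sim$truth) > 0 && !is.null(expr)) {
    ct_tab <- simulate_qpcr(sim)
    calibrator <- config$sim$tissues[1]
    rq <- delta_delta_ct(ct_tab, reference_gene = "U6",
                         calibrator_sample = calibrator)
    seq_vals <- seq_values_for(sim, calls, expr, count_cols)
    platform_cor <- tryCatch(
      correlate_platforms(seq_vals, rq[, c("target", "sample", "rq")]),
      error = function(e) NULL
    )
    qp <- list(ct = ct_tab, rq = rq)
  }

  truth_eval <- evaluate_against_truth(sim$truth, calls)
  summary <- summarize_run(pre_stats, sc, calls, disc, expr, spec,
                           ctx$clusters, platform_cor, truth_eval,
                           config)
  manifest <- build_manifest(config, sim, calls, counts_tbl, target_hits,
                             summary)

  structure(
    list(
      sim = sim, tags = tags, screen = sc,
      conserved = conserved_calls, discovery = disc,
      calls = calls, families = fam$families, clusters = ctx$clusters,
      counts = expr, specificity = spec,
      targets = target_hits, target_truth = tx$sites,
      qpcr = qp, platform_cor = platform_cor,
      truth_eval = truth_eval,
      summary = summary, manifest = manifest,
      config = config
    ),
    class = "mir_run"
  )
}

conserved_to_calls <- function(hits, genome, count_cols) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(id = character(0), seq = character(0),
                          class = character(0), family = character(0)))
  }
  mapped <- map_tags(hits, genome)
  first_locus <- dplyr::slice_head(dplyr::group_by(mapped, .data$seq), n = 1)
  first_locus <- dplyr::ungroup(first_locus)
  out <- dplyr::left_join(hits, first_locus, by = "seq")
  out <- dplyr::arrange(out, .data$ref_id, .data$seq)
  dplyr::mutate(out,
    id = sprintf("cons-%s-%02d", .data$ref_id, dplyr::row_number()),
    class = "conserved",
    .before = "seq"
  )
}

seq_values_for <- function(sim, calls, expr, count_cols) {
  norm <- as.data.frame(expr)
  rows <- list()
  for (i in seq_len(nrow(sim$truth))) {
    call_idx <- match(sim$truth$mature_seq[i], calls$seq)
    if (is.na(call_idx)) next
    call_id <- calls$id[call_idx]
    for (tis in count_cols) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sim$truth$id[i], sample = tis,
        normalized = norm[[tis]][norm$id == call_id]
      )
    }
  }
  dplyr::bind_rows(rows)
}

evaluate_against_truth <- function(truth, calls) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_, precision = NA_real_,
                n_truth = 0L, n_calls = nrow(calls)))
  }
  recovered <- truth$mature_seq %in% calls$seq
  true_call <- calls$seq %in% truth$mature_seq
  list(
    recall = mean(recovered),
    precision = if (nrow(calls) > 0) mean(true_call) else NA_real_,
    n_truth = nrow(truth), n_calls = nrow(calls),
    missed = truth$id[!recovered]
  )
}

#' Summarize a call set and its expression matrix
#'
#' Computes the descriptive statistics reported for a miRNA catalogue:
#' size and 5'-nucleotide histograms, GC%, the precursor MFE distribution
#' with the fraction below -20 kcal/mol, and the tissue-sharing breakdown
#' (present in all / several / one tissue at the detection threshold).
#'
#' @param calls call tibble (seq, class, mfe where available)
#' @param normalized `mir_counts` object or NULL
#' @param detection_min presence threshold on normalized counts
#' @return list of class `mir_call_summary`
#' @export
summarize_calls <- function(calls, normalized = NULL, detection_min = 10) {
  sizes <- table(factor(nchar(calls$seq), levels = 18:30))
  first <- table(factor(first_nt(calls$seq), levels = c("A", "C", "G", "U")))
  gc <- gc_content(calls$seq)
  mfe <- if ("mfe" %in% names(calls)) calls$mfe[!is.na(calls$mfe)] else numeric(0)
  sharing <- c(all = 0L, multi = 0L, single = 0L, none = 0L)
  if (!is.null(normalized)) {
    m <- count_matrix(as.data.frame(normalized))
    m <- m[match(calls$id, rownames(m)), , drop = FALSE]
    present <- m >= detection_min
    n_present <- rowSums(present)
    sharing <- c(
      all = sum(n_present == ncol(m)),
      multi = sum(n_present > 1 & n_present < ncol(m)),
      single = sum(n_present == 1),
      none = sum(n_present == 0)
    )
  }
  structure(
    list(
      n_calls = nrow(calls),
      by_class = table(calls$class),
      size_histogram = sizes,
      first_nt_histogram = first,
      gc_mean = mean(gc),
      mfe_mean = if (length(mfe) > 0) mean(mfe) else NA_real_,
      mfe_frac_below_20 = if (length(mfe) > 0) mean(mfe < -20) else NA_real_,
      tissue_sharing = sharing
    ),
    class = "mir_call_summary"
  )
}

#' @export
print.mir_call_summary <- function(x, ...) {
  cat("<mir_call_summary> ", x$n_calls, " calls (",
      paste(names(x$by_class), as.integer(x$by_class), sep = ":",
            collapse = ", "), ")\n", sep = "")
  cat("  GC mean ", sprintf("%.1f%%", 100 * x$gc_mean),
      "; MFE mean ", sprintf("%.1f", x$mfe_mean), " kcal/mol, ",
      sprintf("%.0f%%", 100 * x$mfe_frac_below_20), " below -20\n",
      sep = "")
  cat("  tissue sharing: ", paste(names(x$tissue_sharing),
                                  x$tissue_sharing, sep = "=",
                                  collapse = " "), "\n", sep = "")
  invisible(x)
}

summarize_run <- function(pre_stats, sc, calls, disc, expr, spec, clusters,
                          platform_cor, truth_eval, config) {
  per_sample <- lapply(pre_stats, function(s) {
    tibble::tibble(
      sample = s$sample, raw_reads = s$raw_reads,
      discarded_qc = s$discarded_qc %||% 0L,
      trimmed_away = s$trimmed_away %||% 0L,
      out_of_range = s$dropped_short + s$dropped_long,
      unique_tags = s$unique_tags
    )
  })
  rejections <- if (nrow(disc$candidates) > 0) {
    table(disc$candidates$rejection_reason[!disc$candidates$accepted])
  } else {
    table(character(0))
  }
  call_summary <- summarize_calls(calls, expr,
                                  detection_min = config$detection_min)
  spec_tab <- if (!is.null(spec)) table(spec$category) else table(character(0))
  intergenic_frac <- if ("context" %in% names(calls) && nrow(calls) > 0) {
    mean(calls$context == "intergenic")
  } else {
    NA_real_
  }
  structure(
    list(
      per_sample = dplyr::bind_rows(per_sample),
      screen_tally = sc$tally,
      n_conserved = sum(calls$class == "conserved"),
      n_novel = sum(calls$class %in% c("novel", "novel_isoform")),
      n_novel_isoform = sum(calls$class == "novel_isoform"),
      candidate_rejections = rejections,
      calls = call_summary,
      specificity_breakdown = spec_tab,
      n_tandem_clusters = nrow(clusters),
      intergenic_fraction = intergenic_frac,
      platform_r = if (!is.null(platform_cor)) platform_cor$r else NA_real_,
      recall = truth_eval$recall,
      precision = truth_eval$precision
    ),
    class = "mir_run_summary"
  )
}

#' @export
print.mir_run_summary <- function(x, ...) {
  cat("<mir_run_summary>\n")
  cat("  conserved: ", x$n_conserved, "  novel: ", x$n_novel,
      " (isoforms: ", x$n_novel_isoform, ")\n", sep = "")
  if (!is.na(x$recall)) {
    cat(sprintf("  truth recall %.3f, precision %.3f\n",
                x$recall, x$precision))
  }
  if (!is.na(x$intergenic_fraction)) {
    cat(sprintf("  intergenic fraction %.1f%%\n",
                100 * x$intergenic_fraction))
  }
  if (!is.na(x$platform_r)) {
    cat(sprintf("  seq/qPCR correlation r = %.3f\n", x$platform_r))
  }
  invisible(x)
}

build_manifest <- function(config, sim, calls, counts_tbl, target_hits,
                           summary) {
  cfg <- config
  cfg$inputs <- NULL
  list(
    package = "mirforge",
    version = as.character(utils::packageVersion("mirforge")),
    seed = config$seed,
    thresholds = config$thresholds,
    sim = unclass(config$sim),
    digests = list(
      genome = rlang::hash(sim$genome),
      truth = rlang::hash(sim$truth),
      calls = rlang::hash(calls),
      counts = rlang::hash(counts_tbl),
      targets = rlang::hash(target_hits)
    )
  )
}

#' @export
print.mir_run <- function(x, ...) {
  cat("<mir_run> seed ", x$config$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x a `mir_run` object
#' @param ... unused
#' @return tibble with the headline run statistics
#' @export
glance.mir_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_calls = s$calls$n_calls,
    n_conserved = s$n_conserved,
    n_novel = s$n_novel,
    n_novel_isoform = s$n_novel_isoform,
    recall = s$recall,
    precision = s$precision,
    intergenic_fraction = s$intergenic_fraction,
    mfe_frac_below_20 = s$calls$mfe_frac_below_20,
    platform_r = s$platform_r
  )
}

#' Write the principal tables and sequences of a run to a directory
#'
#' Emits plain-text outputs: calls and candidate tables (TSV), normalized
#' counts and specificity (TSV), target hits (TSV), mature/precursor
#' FASTA, mature-locus BED6, genome FASTA, and JSON summary + manifest.
#'
#' @param run a `mir_run` object
#' @param dir output directory (created)
#' @return named character vector of written paths, invisibly
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c()
  wtsv <- function(x, f) {
    if (is.null(x) || nrow(x) == 0) return(invisible(NULL))
    readr::write_tsv(tibble::as_tibble(x), p(f))
    paths[[f]] <<- p(f)
  }
  wtsv(run$calls, "calls.tsv")
  wtsv(run$discovery$candidates, "candidates.tsv")
  wtsv(run$families, "families.tsv")
  wtsv(run$clusters, "clusters.tsv")
  if (!is.null(run$counts)) wtsv(as.data.frame(run$counts),
                                 "counts_normalized.tsv")
  wtsv(run$specificity, "specificity.tsv")
  wtsv(run$targets, "targets.tsv")
  write_fasta(run$sim$genome, p("genome.fa"))
  paths[["genome.fa"]] <- p("genome.fa")
  if (nrow(run$calls) > 0) {
    write_fasta(setNames(run$calls$seq, run$calls$id), p("mature.fa"))
    paths[["mature.fa"]] <- p("mature.fa")
    write_calls_gff3(run$calls, p("mirnas.gff3"))
    paths[["mirnas.gff3"]] <- p("mirnas.gff3")
    bed <- run$calls[!is.na(run$calls$start), , drop = FALSE]
    if (nrow(bed) > 0) {
      readr::write_tsv(
        tibble::tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
                       name = bed$id, score = 0L, strand = bed$strand),
        p("mature.bed"), col_names = FALSE
      )
      paths[["mature.bed"]] <- p("mature.bed")
    }
  }
  s <- run$summary
  json_summary <- list(
    n_conserved = s$n_conserved, n_novel = s$n_novel,
    n_novel_isoform = s$n_novel_isoform,
    recall = s$recall, precision = s$precision,
    intergenic_fraction = s$intergenic_fraction,
    mfe_frac_below_20 = s$calls$mfe_frac_below_20,
    platform_r = s$platform_r,
    tissue_sharing = as.list(s$calls$tissue_sharing)
  )
  jsonlite::write_json(json_summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths[["summary.json"]] <- p("summary.json")
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  paths[["manifest.json"]] <- p("manifest.json")
  invisible(unlist(paths))
}
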