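# File-format boundaries: FASTQ/FASTA through Biostrings, GFF3 through
# rtracklayer. Tabular outputs are plain TSV via readr.

#' Read a FASTQ file into a tibble
#' @param path FASTQ file (Phred+33)
#' @return tibble: read_id, seq, qual
#' @export
read_fastq <- function(path) {
  recs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  tibble::tibble(
    read_id = names(recs),
    seq = unname(as.character(recs)),
    qual = unname(as.character(S4Vectors::mcols(recs)$qualities))
  )
}

#' Write reads to FASTQ (Phred+33)
#' @param reads tibble with read_id, seq, qual
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

#' Write per-tissue FASTQ libraries
#' @param reads tibble from [simulate_libraries()] (has a tissue column)
#' @param dir output directory (created if absent)
#' @return named character vector of written paths
#' @export
write_libraries_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tissues <- unique(reads$tissue)
  paths <- setNames(file.path(dir, paste0(tissues, ".fastq")), tissues)
  for (t in tissues) {
    write_fastq(reads[reads$tissue == t, , drop = FALSE], paths[[t]])
  }
  paths
}

#' Read a FASTA file into a tibble
#' @param path FASTA file
#' @return tibble: id (first word of header), seq (uppercase DNA)
#' @export
read_fasta <- function(path) {
  recs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    id = sub("\\s.*$", "", names(recs)),
    seq = as_dna(as.character(recs))
  )
}

#' Write named sequences to FASTA
#' @param seqs named character vector, or tibble with id + seq columns
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  x <- Biostrings::DNAStringSet(as_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export planted-truth loci as GFF3
#'
#' Truth coordinates are 0-based half-open internally; GFF3 is 1-based
#' inclusive, so start becomes `start + 1`.
#'
#' @param sim a `mir_sim` object
#' @param path output GFF3 path
#' @return `path`, invisibly
#' @export
write_truth_gff3 <- function(sim, path) {
  truth <- sim$truth
  gr <- GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = truth$strand,
    type = "miRNA_primary_transcript",
    ID = truth$id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export an annotation feature table as GFF3
#' @param features tibble from [simulate_annotation()]
#' @param path output GFF3 path
#' @return `path`, invisibly
#' @export
write_annotation_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand,
    type = features$type,
    ID = paste0(features$gene_id, "_", features$type,
                seq_len(nrow(features))),
    Parent = ifelse(features$type == "gene", NA_character_,
                    features$gene_id)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export miRNA calls as GFF3 (precursor with child mature feature)
#'
#' Calls with precursor coordinates (novel calls) get a
#' `miRNA_primary_transcript` parent spanning the precursor and a `miRNA`
#' child at the mature locus; calls without one (conserved calls located
#' by mapping only) get a bare `miRNA` feature.
#'
#' @param calls call tibble from a pipeline run
#' @param path output GFF3 path
#' @return `path`, invisibly
#' @export
write_calls_gff3 <- function(calls, path) {
  calls <- calls[!is.na(calls$start), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (!is.null(cl$pre_start) && !is.na(cl$pre_start)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = cl$chrom, start = cl$pre_start + 1L, end = cl$pre_end,
        strand = cl$strand, type = "miRNA_primary_transcript",
        ID = paste0(cl$id, "_pre"), Parent = NA_character_
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = cl$chrom, start = cl$start + 1L, end = cl$end,
        strand = cl$strand, type = "miRNA",
        ID = cl$id, Parent = paste0(cl$id, "_pre")
      )
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = cl$chrom, start = cl$start + 1L, end = cl$end,
        strand = cl$strand, type = "miRNA",
        ID = cl$id, Parent = NA_character_
      )
    }
  }
  df <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type, ID = df$ID,
    Parent = df$Parent
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a simulation configuration to YAML
#' @param config a [sim_config()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "mir_sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Fields mirror the [sim_config()] arguments; missing fields fall back
#' to the defaults and the result is re-validated.
#'
#' @param path YAML path
#' @return a `mir_sim_config` object
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  do.call(sim_config, vals[intersect(names(vals), known)])
}

#' Read an annotation GFF3 into the internal feature table
#' @param path GFF3 path
#' @return tibble: chrom, type, start, end (0-based half-open), strand
#' @export
read_annotation_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
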