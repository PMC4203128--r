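# Sequence plumbing shared across modules. Sequences live on disk as DNA
# (T); folding and anything duplex-related works on RNA (U). Conversion
# happens at module boundaries, never silently inside an algorithm.

NT_DNA <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to uppercase DNA (U -> T)
#' @param x character vector of sequences
#' @return character vector, uppercase, T alphabet
#' @export
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Normalize a nucleotide string to uppercase RNA (T -> U)
#' @param x character vector of sequences
#' @return character vector, uppercase, U alphabet
#' @export
as_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Reverse complement (DNA alphabet)
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

#' GC content of sequences
#' @param x character vector of sequences (DNA or RNA)
#' @return numeric vector, fraction of G+C in `[0, 1]`
#' @export
gc_content <- function(x) {
  x <- as_dna(x)
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    if (length(ch) == 0) return(NA_real_)
    mean(ch %in% c("G", "C"))
  }, numeric(1))
}

#' First (5') nucleotide of each sequence, RNA alphabet
#' @param x character vector of sequences
#' @return character vector of single letters in A/C/G/U
#' @export
first_nt <- function(x) {
  substr(as_rna(x), 1, 1)
}

# integer codes for the C++ folders: A=0, C=1, G=2, U=3
seq_to_codes <- function(x) {
  stopifnot(length(x) == 1)
  codes <- match(strsplit(as_rna(x), "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) {
    stop("sequence contains characters outside ACGU/ACGT: ", x, call. = FALSE)
  }
  codes
}

# Deterministic child seeds from one master seed, so each stochastic stage
# has its own stream. Kept below 2^31.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) * 69069 + sum(utf8ToInt(as.character(salt)))) %% 2147483629L
}

random_dna <- function(n, rng = NULL) {
  paste(sample(NT_DNA, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
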