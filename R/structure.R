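# RNA secondary structure: max-pair and reduced-thermodynamic folding,
# hairpin anatomy, and dinucleotide-shuffle significance testing.
#
# Both folders restrict structures to nested canonical pairs
# (AU/UA/GC/CG/GU/UG) with hairpin loops of at least `min_loop` unpaired
# bases. The energy model is a reduced nearest-neighbor scheme: stack free
# energies, hairpin/bulge/internal loop penalties by length
# (Jacobson-Stockmayer extrapolated beyond the table), and a linear
# multiloop cost. The open chain is the 0 kcal/mol reference state.

PAIR_CODES <- c("AU", "UA", "GC", "CG", "GU", "UG")

new_fold <- function(seq, partner, score, mode) {
  db <- rep(".", nchar(seq))
  paired <- which(!is.na(partner))
  db[paired[partner[paired] > paired]] <- "("
  db[paired[partner[paired] < paired]] <- ")"
  structure(
    list(
      seq = seq, partner = partner, dotbracket = paste(db, collapse = ""),
      score = score, n_pairs = sum(!is.na(partner)) / 2, mode = mode
    ),
    class = "mir_fold"
  )
}

#' @export
print.mir_fold <- function(x, ...) {
  cat("<mir_fold> mode=", x$mode, " score=", format(x$score), "\n", sep = "")
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Per-position view of a folded structure
#' @param x a `mir_fold` object
#' @param ... unused
#' @return tibble with position, base, partner (NA if unpaired)
#' @export
tidy.mir_fold <- function(x, ...) {
  tibble::tibble(
    position = seq_len(nchar(x$seq)),
    base = strsplit(x$seq, "", fixed = TRUE)[[1]],
    partner = x$partner
  )
}

#' One-row summary of a folded structure
#' @param x a `mir_fold` object
#' @param ... unused
#' @return tibble with mode, score, n_pairs, length
#' @export
glance.mir_fold <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, score = x$score, n_pairs = x$n_pairs,
    length = nchar(x$seq)
  )
}

#' Maximum base-pair fold (Nussinov dynamic program)
#'
#' Finds a maximum-cardinality set of nested canonical base pairs with the
#' steric hairpin-loop constraint. Traceback is deterministic: each 5' base
#' pairs with the smallest admissible partner, so dot-bracket strings are
#' reproducible across runs.
#'
#' @param seq a nucleotide string (DNA or RNA; normalized to RNA internally)
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#' @return a `mir_fold` object; `score` is the pair count
#' @examples
#' fold_maxpair("GGGAAACCC")
#' @export
fold_maxpair <- function(seq, min_loop = 3) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  rna <- as_rna(seq)
  codes <- seq_to_codes(rna)
  res <- .nussinov_fold_cpp(codes, as.integer(min_loop))
  partner <- ifelse(res < 0, NA_integer_, as.integer(res) + 1L)
  new_fold(rna, partner, as.numeric(attr(res, "score")), "maxpair")
}

#' Free-energy fold (reduced nearest-neighbor model)
#'
#' Minimizes the sum of stack free energies and loop penalties over nested
#' structures (Zuker-style recursion with a linear multiloop cost). Scores
#' are in kcal/mol; more negative is more stable; an unpairable sequence
#' scores 0 (open chain). The parameter table ships with the package and is
#' editable (`energy_params()`).
#'
#' @inheritParams fold_maxpair
#' @param params energy parameter list from [energy_params()]
#' @return a `mir_fold` object; `score` is the free energy in kcal/mol
#' @examples
#' fold_energy("GGGGGAAAACCCCC")
#' @export
fold_energy <- function(seq, params = energy_params(), min_loop = 3) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  rna <- as_rna(seq)
  codes <- seq_to_codes(rna)
  res <- .zuker_fold_cpp(
    codes, as.integer(min_loop),
    params$stack, params$hairpin, params$bulge, params$internal,
    params$ml_close, params$ml_branch, as.integer(params$max_interior)
  )
  partner <- ifelse(res$partner < 0, NA_integer_, as.integer(res$partner) + 1L)
  new_fold(rna, partner, res$energy, "energy")
}

#' Load a nearest-neighbor energy parameter table
#'
#' The TSV has rows of three kinds: `stack` (key "XY:ZW", closing pair then
#' inner pair, kcal/mol), `hairpin`/`bulge`/`internal` (key = unpaired loop
#' length), and `multiloop` (`close` and `branch` linear costs). The shipped
#' default is a reduced Turner-style table with a flat -1.0 kcal/mol for
#' wobble-containing stacks.
#'
#' @param path TSV path; default = table shipped with the package
#' @return list with stack matrix (6x6, pair order AU,UA,GC,CG,GU,UG),
#'   hairpin/bulge/internal penalty vectors (index = loop length), and
#'   multiloop costs
#' @export
energy_params <- function(path = system.file("extdata", "energy_params.tsv",
                                             package = "mirforge")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("stack", "hairpin", "multiloop")
  missing <- setdiff(need, unique(tab$type))
  if (length(missing) > 0) {
    stop("energy parameter table missing rows of type: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  st <- tab[tab$type == "stack", ]
  parts <- strsplit(st$key, ":", fixed = TRUE)
  for (i in seq_along(parts)) {
    stack[parts[[i]][1], parts[[i]][2]] <- st$value[i]
  }
  if (anyNA(stack)) stop("incomplete stack table", call. = FALSE)
  len_tab <- function(kind, fallback) {
    rows <- tab[tab$type == kind, ]
    if (nrow(rows) == 0) return(fallback)
    lens <- as.integer(rows$key)
    out <- rep(NA_real_, max(lens))
    out[lens] <- rows$value
    # leading entries below the smallest tabulated length are forbidden;
    # interior gaps carry the previous value forward
    out[seq_len(min(lens) - 1)] <- 1e9
    for (k in seq_along(out)) if (is.na(out[k])) out[k] <- out[k - 1]
    out
  }
  ml <- tab[tab$type == "multiloop", ]
  meta <- tab[tab$type == "meta", ]
  list(
    stack = stack,
    hairpin = len_tab("hairpin", c(NA, NA, 5.4)),
    bulge = len_tab("bulge", 3.8),
    internal = len_tab("internal", c(NA, 1.5)),
    ml_close = ml$value[ml$key == "close"],
    ml_branch = ml$value[ml$key == "branch"],
    max_interior = if (any(meta$key == "max_interior")) {
      as.integer(meta$value[meta$key == "max_interior"])
    } else 30L
  )
}

#' Hairpin anatomy of a folded span
#'
#' Counts hairpin loops whose closing pair lies inside `span`; a hairpin
#' loop is a pair enclosing no other pair. When the span holds exactly one
#' loop, the 5' and 3' arms flanking it are reported. More than one loop in
#' the span is a bifurcation (disqualifying for a miRNA precursor).
#'
#' @param fold a `mir_fold` object
#' @param span integer length-2 vector, 1-based inclusive interval (default:
#'   whole sequence)
#' @return list: n_hairpin_loops, has_bifurcation, loop (1-based interval of
#'   unpaired loop bases or NULL), arm5p / arm3p intervals (NULL unless
#'   exactly one loop), unstructured flag
#' @export
parse_hairpin <- function(fold, span = NULL) {
  stopifnot(inherits(fold, "mir_fold"))
  n <- nchar(fold$seq)
  if (is.null(span)) span <- c(1L, n)
  span <- as.integer(span)
  if (length(span) != 2 || span[1] > span[2] || span[1] < 1 || span[2] > n) {
    stop("span must be a non-empty 1-based interval within the sequence",
         call. = FALSE)
  }
  partner <- fold$partner
  loops <- list()
  for (i in span[1]:span[2]) {
    j <- partner[i]
    if (is.na(j) || j <= i || j > span[2]) next
    inner <- (i + 1):(j - 1)
    if (all(is.na(partner[inner]))) loops[[length(loops) + 1]] <- c(i, j)
  }
  n_loops <- length(loops)
  out <- list(
    n_hairpin_loops = n_loops,
    has_bifurcation = n_loops > 1,
    loop = NULL, arm5p = NULL, arm3p = NULL,
    unstructured = n_loops == 0
  )
  if (n_loops == 1) {
    cl <- loops[[1]]
    out$loop <- c(cl[1] + 1L, cl[2] - 1L)
    out$arm5p <- c(span[1], cl[1])
    out$arm3p <- c(cl[2], span[2])
  }
  out
}

#' Dinucleotide-preserving shuffle (Altschul-Erickson)
#'
#' Returns a random permutation of `seq` with exactly the same dinucleotide
#' count vector (and hence the same first and last base and mononucleotide
#' counts). Used to build the null distribution of the folding score.
#'
#' @param seq nucleotide string
#' @return shuffled string on the same alphabet as the input
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3 || length(unique(ch)) == 1) return(seq)
  last <- ch[n]
  verts <- unique(ch)
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  # choose a random last edge per vertex (except the terminal one) such
  # that the chosen edges form an arborescence into the terminal vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) return(NA_character_)
      sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || length(edges[[v]]) == 0) next
      cur <- v
      steps <- 0
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        steps <- steps + 1
        if (is.na(cur)) break
      }
      if (is.na(cur) || cur != last) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  ordered <- lapply(verts, function(v) {
    ev <- edges[[v]]
    if (length(ev) == 0) return(character(0))
    if (v == last) return(sample(ev, length(ev)))
    le <- last_edge[[v]]
    ev <- ev[-match(le, ev)]
    c(if (length(ev) > 0) sample(ev, length(ev)) else character(0), le)
  })
  names(ordered) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (k in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Shuffle-based significance of a folding score
#'
#' Empirical randomization test in the RANDfold style: the sequence is
#' shuffled `n_shuffles` times preserving dinucleotide composition, each
#' shuffle is folded, and the add-one p-value counts null scores at least
#' as stable as the observed one (in energy mode: free energy less than or
#' equal to the observed; in maxpair mode: at least as many pairs).
#'
#' @param seq nucleotide string, length >= 3
#' @param n_shuffles number of shuffles; at least 19 so that p <= 0.05 is
#'   attainable
#' @param mode `"energy"` (default) or `"maxpair"`
#' @param rng_seed integer seed for reproducible shuffles
#' @param params energy parameters (energy mode only)
#' @return list of class `mir_shuffle_test`: observed, null_scores, p_value,
#'   n_shuffles, mode
#' @export
shuffle_pvalue <- function(seq, n_shuffles = 99, mode = c("energy", "maxpair"),
                           rng_seed = 1L, params = energy_params()) {
  mode <- match.arg(mode)
  if (nchar(seq) < 3) stop("sequence shorter than 3", call. = FALSE)
  if (n_shuffles < 19) {
    stop("n_shuffles must be >= 19 for the 0.05 threshold to be attainable",
         call. = FALSE)
  }
  fold1 <- function(s) {
    if (mode == "energy") fold_energy(s, params)$score else fold_maxpair(s)$score
  }
  observed <- fold1(seq)
  null_scores <- with_seed(rng_seed, {
    vapply(seq_len(n_shuffles), function(i) fold1(dinuc_shuffle(seq)),
           numeric(1))
  })
  as_extreme <- if (mode == "energy") {
    sum(null_scores <= observed + 1e-12)
  } else {
    sum(null_scores >= observed - 1e-12)
  }
  structure(
    list(
      observed = observed, null_scores = null_scores,
      p_value = (1 + as_extreme) / (n_shuffles + 1),
      n_shuffles = n_shuffles, mode = mode
    ),
    class = "mir_shuffle_test"
  )
}

#' @export
print.mir_shuffle_test <- function(x, ...) {
  cat("<mir_shuffle_test> mode=", x$mode, " observed=", format(x$observed),
      " p=", format(x$p_value), " (", x$n_shuffles, " shuffles)\n", sep = "")
  invisible(x)
}

#' Dinucleotide count vector of a sequence
#' @param seq nucleotide string
#' @return named integer vector of overlapping dinucleotide counts
#' @export
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) return(integer(0))
  table(paste0(ch[-length(ch)], ch[-1]))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}
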