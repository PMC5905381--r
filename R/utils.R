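#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` strings (delegates to
#' [Biostrings::reverseComplement()]).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform random nucleotide sequence; callers control the RNG state.
random_seq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Generate a random locus (truth) sequence
#'
#' Convenience generator for a synthetic amplicon insert: uniform random
#' nucleotides, which at typical lengths naturally contains the short
#' homopolymer runs (3-6 bp) the error model and polisher care about.
#'
#' @param length insert length in bases.
#' @param seed optional integer; if given, the draw is made reproducible
#'   without disturbing the caller's RNG state.
#' @return a single nucleotide string.
#' @export
random_locus <- function(length, seed = NULL) {
  if (is.null(seed)) return(random_seq(length))
  withr::with_seed(seed, random_seq(length))
}

# validate a nucleotide string-ish input and return it as one uppercase string
as_seq <- function(x, what = "sequence") {
  if (is.list(x) && !is.null(x$seq)) x <- x$seq
  if (inherits(x, "nanobar_contig")) x <- x$seq
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("%s must be a single character string", what))
  }
  toupper(x)
}

# largest-remainder apportionment of `total` into parts proportional to w
largest_remainder <- function(total, w) {
  if (total == 0 || sum(w) == 0) return(rep(0L, length(w)))
  raw <- total * w / sum(w)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# union length of integer intervals given as a 2-column matrix [start, end)
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= ce) {
      ce <- max(ce, ends[k])
    } else {
      tot <- tot + (ce - cs)
      cs <- starts[k]; ce <- ends[k]
    }
  }
  tot + (ce - cs)
}
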