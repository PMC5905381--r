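# Sequence I/O: strict 4-line FASTQ (phred+33) in, FASTA in/out, and
# quality arithmetic on the error-probability scale.

#' Read a FASTQ file into a reads tibble
#'
#' Parses strict 4-line FASTQ records with phred+33 quality encoding
#' (`!` = 0, `I` = 40). Sequences are uppercased; characters outside
#' `{A,C,G,T,N}` are rejected. Gzip-compressed files are accepted by `.gz`
#' extension. Malformed records raise a parse error naming the offending
#' line, which is why this parser is strict rather than permissive.
#'
#' @param path path to a FASTQ (optionally `.gz`) file.
#' @return a tibble with columns `id` (character), `seq` (character) and
#'   `qual` (list of integer vectors, one phred score per base).
#' @seealso [write_fastq()], [mean_quality()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nl <- length(lines)
  if (nl == 0) {
    return(tibble(id = character(0), seq = character(0), qual = list()))
  }
  if (nl %% 4 != 0) {
    abort(sprintf("FASTQ parse error: truncated record starting at line %d",
                  (nl %/% 4) * 4 + 1))
  }
  nrec <- nl %/% 4
  hdr <- lines[seq(1, nl, by = 4)]
  seqs <- toupper(lines[seq(2, nl, by = 4)])
  plus <- lines[seq(3, nl, by = 4)]
  quals <- lines[seq(4, nl, by = 4)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(sprintf("FASTQ parse error: missing '@' at line %d", (bad[1] - 1) * 4 + 1))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("FASTQ parse error: missing '+' at line %d", (bad[1] - 1) * 4 + 3))
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    abort(sprintf(
      "FASTQ parse error: sequence/quality length mismatch at line %d",
      (bad[1] - 1) * 4 + 4))
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    abort(sprintf("FASTQ parse error: non-nucleotide character at line %d",
                  (bad[1] - 1) * 4 + 2))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  if (any(ids == "")) abort("FASTQ parse error: empty read identifier")
  qual <- lapply(seq_len(nrec), function(i) {
    if (nchar(quals[i]) == 0) return(integer(0))
    q <- utf8ToInt(quals[i]) - 33L
    if (any(q < 0)) {
      abort(sprintf("FASTQ parse error: quality below phred+33 range at line %d",
                    (i - 1) * 4 + 4))
    }
    q
  })
  tibble(id = ids, seq = seqs, qual = qual)
}

#' Write a reads tibble as FASTQ (phred+33)
#'
#' @param reads tibble with columns `id`, `seq`, `qual` (as from
#'   [read_fastq()]).
#' @param path output path; `.gz` extension triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (anyDuplicated(reads$id)) abort("duplicate read ids")
  qstr <- vapply(reads$qual, function(q) {
    if (length(q) == 0) "" else intToUtf8(as.integer(q) + 33L)
  }, character(1))
  out <- character(4L * nrow(reads))
  if (nrow(reads) > 0) {
    out[seq(1, length(out), 4)] <- paste0("@", reads$id)
    out[seq(2, length(out), 4)] <- reads$seq
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- qstr
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path path to a FASTA (optionally `.gz`) file.
#' @return a tibble with columns `id` and `seq` (uppercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)),
         seq = unname(toupper(as.character(ss))))
}

#' Write sequences as 80-column wrapped FASTA
#'
#' @param records a tibble/data frame with columns `id` and `seq`, or a named
#'   character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- tibble(id = names(records), seq = unname(records))
  }
  if (nrow(records) > 0 && anyDuplicated(records$id)) {
    abort("duplicate sequence ids")
  }
  ss <- Biostrings::DNAStringSet(setNames(as.character(records$seq), records$id))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Mean read quality on the error-probability scale
#'
#' Averages per-base phred scores the way long-read quality filters do:
#' the scores are converted to error probabilities, averaged, and converted
#' back, i.e. \eqn{-10 \log_{10}( \mathrm{mean}_b\, 10^{-q_b/10} )}. This is
#' lower than the arithmetic mean of the scores whenever qualities vary,
#' because low-quality bases dominate the error mass.
#'
#' @param qual an integer vector of phred scores, or a list of such vectors
#'   (e.g. the `qual` column of a reads tibble).
#' @return a numeric vector of phred-scale mean qualities.
#' @export
#' @examples
#' mean_quality(c(10, 30)) # 12.97, not 20
mean_quality <- function(qual) {
  one <- function(q) {
    if (length(q) == 0) abort("mean_quality: empty quality vector")
    -10 * log10(mean(10^(-as.numeric(q) / 10)))
  }
  if (is.list(qual)) vapply(qual, one, numeric(1)) else one(qual)
}
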