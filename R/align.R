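# Thin R layer over the compiled aligner: scoring defaults, band doubling,
# strand handling, and CIGAR construction.

default_scores <- function() {
  c(match = 1L, mismatch = -1L, gap_open = 2L, gap_ext = 1L)
}

# One banded alignment with automatic band doubling when the optimal path
# touches the band boundary. band = -1 disables banding; double_band = FALSE
# accepts the in-band optimum as-is (appropriate for yes/no overlap tests,
# where an out-of-band path would fail the thresholds anyway).
align_pair <- function(q, r, free_q = TRUE, free_r = TRUE, band = -1L,
                       scores = default_scores(), double_band = TRUE,
                       band_center = NULL) {
  nq <- nchar(q); nr <- nchar(r)
  b <- as.integer(band)
  repeat {
    a <- cpp_align(q, r, scores[["match"]], scores[["mismatch"]],
                   scores[["gap_open"]], scores[["gap_ext"]],
                   free_q, free_r, b,
                   centered = !is.null(band_center),
                   band_center = if (is.null(band_center)) 0L else
                     as.integer(band_center))
    if (b < 0L || !double_band || !isTRUE(a$band_hit) || b >= nq + nr) break
    b <- b * 2L
  }
  cols <- a$matches + a$mismatches + a$insertions + a$deletions
  a$columns <- cols
  a$identity <- if (cols > 0) a$matches / cols else 0
  a
}

cigar_from_gapped <- function(aln_q, aln_r) {
  if (nchar(aln_q) == 0) return("")
  qc <- strsplit(aln_q, "", fixed = TRUE)[[1]]
  rc <- strsplit(aln_r, "", fixed = TRUE)[[1]]
  op <- ifelse(rc == "-", "I", ifelse(qc == "-", "D", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Semi-global alignment of a read against a reference
#'
#' Banded, affine-gap, semi-global alignment (free end gaps on both
#' sequences, so read and reference overhangs are soft-clipped rather than
#' penalised). Both the read and its reverse complement are tried and the
#' better-scoring strand is returned. The band is doubled automatically
#' whenever the optimal path touches the band boundary, so indel drift larger
#' than the initial band is still found.
#'
#' @param read a read: either a nucleotide string or a one-row reads tibble
#'   (see [read_fastq()]).
#' @param ref the reference: nucleotide string, or a list/one-row tibble with
#'   a `seq` field.
#' @param band initial band half-width in bases (default 100); `-1` disables
#'   banding.
#' @param min_identity alignments with identity (matches / alignment columns)
#'   below this are rejected (default 0.6).
#' @param scores named integer vector `match, mismatch, gap_open, gap_ext`.
#' @return a list of class `nanobar_alignment` with elements `strand`
#'   (`"+"`/`"-"`), `identity`, `score`, `cigar`, `columns`, per-class counts,
#'   1-based aligned intervals `qstart:qend`, `rstart:rend`, and the gapped
#'   strings `aln_q`, `aln_r`; or `NULL` if no strand reaches `min_identity`.
#' @export
semiglobal_align <- function(read, ref, band = 100L, min_identity = 0.6,
                             scores = default_scores()) {
  q <- as_seq(read, "read")
  r <- as_seq(ref, "ref")
  if (nchar(r) == 0) abort("reference sequence is empty")
  if (nchar(q) == 0) return(NULL)
  fwd <- align_pair(q, r, TRUE, TRUE, band, scores)
  rev <- align_pair(revcomp(q), r, TRUE, TRUE, band, scores)
  best <- if (rev$score > fwd$score) rev else fwd
  strand <- if (rev$score > fwd$score) "-" else "+"
  if (best$identity < min_identity) return(NULL)
  structure(
    list(strand = strand, identity = best$identity, score = best$score,
         cigar = cigar_from_gapped(best$aln_q, best$aln_r),
         columns = best$columns, matches = best$matches,
         mismatches = best$mismatches, insertions = best$insertions,
         deletions = best$deletions,
         qstart = best$qstart, qend = best$qend,
         rstart = best$rstart, rend = best$rend,
         aln_q = best$aln_q, aln_r = best$aln_r),
    class = "nanobar_alignment")
}

#' @export
print.nanobar_alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment> strand %s  identity %.3f  ref %d-%d  cigar %s\n",
    x$strand, x$identity, x$rstart, x$rend,
    if (nchar(x$cigar) > 40) paste0(substr(x$cigar, 1, 40), "...") else x$cigar))
  invisible(x)
}
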