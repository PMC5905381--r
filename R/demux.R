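# Demultiplexing: end-windowed semi-global edit-distance search of each
# barcode (and its reverse complement), adapter-only junk detection by
# coverage of near-exact adapter hits, and the quality/length read filter.

#' Example barcode and primer sets
#'
#' Deterministic synthetic barcode/primer sequences for simulations and
#' examples. These are *not* any vendor's kit sequences (kit barcodes are
#' proprietary and treated as user-supplied input); they are random but fixed
#' 24-mers with a shared 20 bp adapter flank, mirroring the geometry of a
#' 12-plex PCR barcoding kit.
#'
#' @param n number of barcodes (1-12).
#' @return `example_barcodes()`: a tibble with columns `barcode_id`, `seq`,
#'   `flank`. `example_primers()`: a list with elements `primer_f`,
#'   `primer_r` (22-mers).
#' @export
example_barcodes <- function(n = 12) {
  stopifnot(n >= 1, n <= 12)
  withr::with_seed(80421, {
    flank <- random_seq(20)
    tibble(
      barcode_id = sprintf("BC%02d", seq_len(12)),
      seq = vapply(seq_len(12), function(i) random_seq(24), character(1)),
      flank = flank
    )[seq_len(n), ]
  })
}

#' @rdname example_barcodes
#' @export
example_primers <- function() {
  withr::with_seed(80422, list(primer_f = random_seq(22),
                               primer_r = random_seq(22)))
}

#' Read a barcode set from FASTA or TSV
#'
#' FASTA: record id becomes `barcode_id`, sequence becomes `seq`, empty
#' `flank`. TSV: columns `barcode_id`, `seq` and optionally `flank`.
#'
#' @param path input file.
#' @return a barcode tibble (`barcode_id`, `seq`, `flank`).
#' @export
read_barcodes <- function(path) {
  bc <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) {
    fa <- read_fasta(path)
    tibble(barcode_id = fa$id, seq = fa$seq, flank = "")
  } else {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    if (is.null(tb$flank)) tb$flank <- ""
    tibble(barcode_id = as.character(tb$barcode_id),
           seq = toupper(tb$seq), flank = toupper(ifelse(is.na(tb$flank), "", tb$flank)))
  }
  validate_barcodes(bc)
  bc
}

validate_barcodes <- function(barcodes) {
  if (is.null(barcodes) || nrow(barcodes) == 0) abort("empty barcode set")
  if (anyDuplicated(barcodes$barcode_id)) abort("duplicate barcode ids")
  if (any(nchar(barcodes$seq) < 8)) abort("barcode sequences must be >= 8 bp")
  invisible(barcodes)
}

# minimal-edit hit of `pattern` inside `text`; returns list(edits, start, end)
# (1-based, end inclusive) or NULL for empty text. Ties prefer the earliest
# end position (deterministic).
edit_locate <- function(pattern, text) {
  if (nchar(text) == 0 || nchar(pattern) == 0) return(NULL)
  row <- cpp_edit_row(pattern, text)
  j <- which.min(row$dist) # first minimum: earliest end
  list(edits = row$dist[j], start = row$start[j] + 1L, end = j - 1L)
}

#' Assign one read to a barcode
#'
#' Semi-global (free end-gap) edit-distance search of every barcode and its
#' reverse complement within the first and last `window` bases of the read.
#' The barcode with the minimal edit distance is returned if that distance is
#' at most `max_edits`; otherwise the read is `unassigned`. Strand is `"+"`
#' when the barcode matched in its given orientation and `"-"` when its
#' reverse complement matched. Ties are broken by lower edit distance, then a
#' 5'-end hit over a 3'-end hit, then lexicographic barcode id.
#'
#' @param read a nucleotide string or one-row reads tibble.
#' @param barcodes barcode tibble (`barcode_id`, `seq`, optional `flank`).
#' @param max_edits maximum acceptable edit distance; default
#'   `floor(0.25 * nchar(seq))` per barcode.
#' @param window number of bases searched at each read end (default 150).
#' @return a one-row tibble: `barcode_id` (or `"unassigned"`), `strand`,
#'   `edits` (NA when unassigned).
#' @export
locate_barcode <- function(read, barcodes, max_edits = NULL, window = 150L) {
  validate_barcodes(barcodes)
  seq <- as_seq(read, "read")
  L <- nchar(seq)
  head_w <- substr(seq, 1L, min(window, L))
  tail_w <- substr(seq, max(1L, L - window + 1L), L)
  best <- NULL
  ids <- barcodes$barcode_id
  ord <- order(ids) # lexicographic scan makes the final tie-break implicit
  for (k in ord) {
    b <- barcodes$seq[k]
    lim <- if (is.null(max_edits)) floor(0.25 * nchar(b)) else max_edits
    cands <- list(
      list(pat = b, win = head_w, strand = "+", end5 = TRUE),
      list(pat = b, win = tail_w, strand = "+", end5 = FALSE),
      list(pat = revcomp(b), win = head_w, strand = "-", end5 = TRUE),
      list(pat = revcomp(b), win = tail_w, strand = "-", end5 = FALSE))
    for (cc in cands) {
      h <- edit_locate(cc$pat, cc$win)
      if (is.null(h) || h$edits > lim) next
      better <- is.null(best) || h$edits < best$edits ||
        (h$edits == best$edits && cc$end5 && !best$end5)
      if (better) {
        best <- list(id = ids[k], strand = cc$strand, edits = h$edits,
                     end5 = cc$end5)
      }
    }
  }
  if (is.null(best)) {
    tibble(barcode_id = "unassigned", strand = NA_character_, edits = NA_integer_)
  } else {
    tibble(barcode_id = best$id, strand = best$strand, edits = best$edits)
  }
}

#' Flag adapter-only (failed-ligation) reads
#'
#' A read is adapter-only when near-exact hits (at most 10% edits) of the
#' barcode+flank sequences, in either orientation, together cover more than
#' `min_fraction` of the read. This separates junk reads that are pure
#' adapter/barcode concatemers from genuine amplicons that merely carry an
#' adapter at one end.
#'
#' @param read a nucleotide string or one-row reads tibble.
#' @param barcodes barcode tibble (`flank` is prepended to `seq` to form the
#'   adapter unit).
#' @param min_fraction coverage threshold (default 0.8).
#' @return a list: `adapter_only` (logical), `covered_fraction`.
#' @export
classify_adapter_only <- function(read, barcodes, min_fraction = 0.8) {
  validate_barcodes(barcodes)
  seq <- as_seq(read, "read")
  L <- nchar(seq)
  if (L == 0) return(list(adapter_only = FALSE, covered_fraction = 0))
  starts <- integer(0); ends <- integer(0)
  flank <- if (is.null(barcodes$flank)) rep("", nrow(barcodes)) else barcodes$flank
  units <- unique(paste0(ifelse(is.na(flank), "", flank), barcodes$seq))
  for (u in c(units, revcomp(units))) {
    n <- nchar(u)
    thr <- floor(0.1 * n)
    row <- cpp_edit_row(u, seq)
    hit <- which(row$dist <= thr) # end positions (1-based j+1 offset: index j -> end j-1)
    if (length(hit) == 0) next
    s <- row$start[hit]          # 0-based starts
    e <- hit - 1L                # 0-based exclusive ends
    keep <- e > s
    starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
  }
  cov <- interval_union_length(starts, ends) / L
  list(adapter_only = cov > min_fraction, covered_fraction = cov)
}

#' Demultiplex a reads table
#'
#' Runs [locate_barcode()] (and optionally [classify_adapter_only()]) on
#' every read.
#'
#' @param reads reads tibble.
#' @inheritParams locate_barcode
#' @inheritParams classify_adapter_only
#' @param classify_adapter also compute the adapter-only flag (default TRUE).
#' @return a tibble of assignments: `read_id`, `barcode_id`, `strand`,
#'   `edits`, `adapter_only`, `adapter_covered_fraction`.
#' @export
demultiplex <- function(reads, barcodes, max_edits = NULL, window = 150L,
                        min_fraction = 0.8, classify_adapter = TRUE) {
  validate_barcodes(barcodes)
  n <- nrow(reads)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- locate_barcode(reads$seq[i], barcodes, max_edits, window)
    if (classify_adapter) {
      ad <- classify_adapter_only(reads$seq[i], barcodes, min_fraction)
    } else {
      ad <- list(adapter_only = NA, covered_fraction = NA_real_)
    }
    out[[i]] <- tibble(read_id = reads$id[i], barcode_id = a$barcode_id,
                       strand = a$strand, edits = a$edits,
                       adapter_only = ad$adapter_only,
                       adapter_covered_fraction = ad$covered_fraction)
  }
  if (n == 0) {
    return(tibble(read_id = character(0), barcode_id = character(0),
                  strand = character(0), edits = integer(0),
                  adapter_only = logical(0),
                  adapter_covered_fraction = numeric(0)))
  }
  bind_rows(out)
}

#' Filter reads by mean quality and length
#'
#' Keeps exactly the reads with [mean_quality()] strictly greater than
#' `min_mean_q` *and* length strictly greater than `min_length` (the
#' long-read convention of "quality > 13 and length > 200 bp"); order is
#' preserved. Counts are attached as the `filter_stats` attribute (a read
#' failing quality is counted as `dropped_q` whether or not it also fails
#' length).
#'
#' @param reads reads tibble.
#' @param min_mean_q phred threshold, strict (default 13).
#' @param min_length length threshold in bases, strict (default 200).
#' @return the kept subset of `reads`, with attribute `filter_stats`
#'   (a one-row tibble: `kept`, `dropped_q`, `dropped_len`).
#' @seealso [filter_stats()]
#' @export
filter_reads <- function(reads, min_mean_q = 13, min_length = 200) {
  if (nrow(reads) == 0) {
    out <- reads
    attr(out, "filter_stats") <- tibble(kept = 0L, dropped_q = 0L, dropped_len = 0L)
    return(out)
  }
  mq <- mean_quality(reads$qual)
  len <- nchar(reads$seq)
  ok_q <- mq > min_mean_q
  ok_l <- len > min_length
  keep <- ok_q & ok_l
  out <- reads[keep, , drop = FALSE]
  attr(out, "filter_stats") <- tibble(
    kept = sum(keep),
    dropped_q = sum(!ok_q),
    dropped_len = sum(ok_q & !ok_l))
  out
}

#' @rdname filter_reads
#' @param x a tibble returned by [filter_reads()].
#' @export
filter_stats <- function(x) attr(x, "filter_stats")

#' Rescue unassigned reads by mapping them to the consensi
#'
#' Aligns every unassigned read (semi-globally, both strands) to every
#' consensus; a read is rescued for the best-identity consensus when the
#' alignment identity is at least `min_identity` over at least half the read
#' length.
#'
#' @param unassigned reads tibble of unassigned reads.
#' @param consensi tibble with columns `id`, `seq` (nonempty).
#' @param min_identity identity threshold (default 0.75).
#' @param band alignment band (see [semiglobal_align()]).
#' @return a list of class `nanobar_rescue`: `counts` (tibble `consensus_id`,
#'   `n_rescued`, one row per consensus), `assignments` (tibble `read_id`,
#'   `consensus_id`, `identity`), `total_rescued`.
#' @export
rescue_unassigned <- function(unassigned, consensi, min_identity = 0.75,
                              band = 100L) {
  if (is.null(consensi) || nrow(consensi) == 0) abort("consensi must be nonempty")
  rows <- list()
  for (i in seq_len(nrow(unassigned))) {
    rd <- unassigned$seq[i]
    best_id <- NA_character_; best_ident <- -1
    for (k in seq_len(nrow(consensi))) {
      a <- semiglobal_align(rd, consensi$seq[k], band = band,
                            min_identity = 0)
      if (is.null(a)) next
      if (a$columns >= 0.5 * nchar(rd) && a$identity >= min_identity &&
          a$identity > best_ident) {
        best_ident <- a$identity; best_id <- consensi$id[k]
      }
    }
    if (!is.na(best_id)) {
      rows[[length(rows) + 1L]] <- tibble(read_id = unassigned$id[i],
                                          consensus_id = best_id,
                                          identity = best_ident)
    }
  }
  asg <- if (length(rows)) bind_rows(rows) else
    tibble(read_id = character(0), consensus_id = character(0),
           identity = numeric(0))
  counts <- tibble(consensus_id = consensi$id) %>%
    dplyr::left_join(dplyr::count(asg, .data$consensus_id, name = "n_rescued"),
                     by = "consensus_id") %>%
    mutate(n_rescued = ifelse(is.na(.data$n_rescued), 0L, .data$n_rescued))
  structure(list(counts = counts, assignments = asg,
                 total_rescued = nrow(asg)),
            class = "nanobar_rescue")
}
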