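# Column pileup over a set of read-to-reference alignments: per-position
# tallies of A/C/G/T/deletion plus per-junction insertion tallies. This is
# the shared engine behind reference-guided consensus calling, center-star
# de novo consensus, and polishing.

# alns: list of nanobar_alignment (all against the same reference)
# ref_len: reference length
# Returns list(counts [5 x L], depth, ins tibble(junction, seq, n_reads),
#              n_ins_reads per junction, span per junction, rstart, rend)
pileup_build <- function(alns, ref_len) {
  counts <- matrix(0L, nrow = 5L, ncol = ref_len,
                   dimnames = list(.BASES5, NULL))
  ins_j <- integer(0); ins_s <- character(0)
  rstart <- integer(length(alns)); rend <- integer(length(alns))
  per_read <- vector("list", length(alns))
  for (k in seq_along(alns)) {
    a <- alns[[k]]
    qc <- strsplit(a$aln_q, "", fixed = TRUE)[[1]]
    rc <- strsplit(a$aln_r, "", fixed = TRUE)[[1]]
    isref <- rc != "-"
    refpos <- a$rstart - 1L + cumsum(isref)
    mpos <- refpos[isref]
    mchar <- qc[isref]
    idx <- match(mchar, .BASES5)
    ok <- !is.na(idx) # N bases are ignored in tallies
    counts[cbind(idx[ok], mpos[ok])] <- counts[cbind(idx[ok], mpos[ok])] + 1L
    rstart[k] <- a$rstart; rend[k] <- a$rend
    g_j <- integer(0); g_s <- character(0)
    if (any(!isref)) {
      iidx <- which(!isref)
      grp <- cumsum(c(TRUE, diff(iidx) != 1L))
      g_j <- vapply(split(iidx, grp), function(ii) refpos[ii[1]], integer(1))
      g_s <- vapply(split(iidx, grp),
                    function(ii) paste(qc[ii], collapse = ""), character(1))
      keep <- g_j >= 1L & g_j < ref_len # interior junctions only
      g_j <- unname(g_j[keep]); g_s <- unname(g_s[keep])
      ins_j <- c(ins_j, g_j); ins_s <- c(ins_s, g_s)
    }
    per_read[[k]] <- list(mpos = mpos, mchar = mchar, ins_j = g_j, ins_s = g_s)
  }
  ins <- if (length(ins_j)) {
    tibble(junction = ins_j, seq = ins_s) %>%
      dplyr::count(.data$junction, .data$seq, name = "n_reads")
  } else {
    tibble(junction = integer(0), seq = character(0), n_reads = integer(0))
  }
  # reads spanning junction j (between columns j and j+1)
  span <- integer(max(ref_len - 1L, 0L))
  for (k in seq_along(alns)) {
    if (rend[k] > rstart[k]) {
      span[rstart[k]:(rend[k] - 1L)] <- span[rstart[k]:(rend[k] - 1L)] + 1L
    }
  }
  n_ins_reads <- integer(max(ref_len - 1L, 0L))
  if (nrow(ins)) {
    agg <- ins %>% group_by(.data$junction) %>%
      summarise(n = sum(.data$n_reads), .groups = "drop")
    n_ins_reads[agg$junction] <- agg$n
  }
  list(counts = counts, depth = colSums(counts), ins = ins,
       n_ins_reads = n_ins_reads, span = span,
       rstart = rstart, rend = rend, per_read = per_read,
       n_reads = length(alns))
}

# Per-column emissions from a pileup.
#   tie = "precedence": exact ties resolved by base order A<C<G<T over gap.
#   tie = "ref": ties resolved toward the reference/draft base when supplied.
# ref_fill: when TRUE, columns with depth < min_depth emit the reference base.
# Returns list(em = character per-column emissions ("" = deletion),
#              ins_after = character per-junction insertions)
pileup_emissions <- function(pl, ref_seq = NULL, min_depth = 1L,
                             tie = c("precedence", "ref"), ref_fill = FALSE) {
  tie <- match.arg(tie)
  L <- ncol(pl$counts)
  sc <- pl$counts + 0 # numeric copy for tie nudging
  ref_chars <- NULL
  if (!is.null(ref_seq)) ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  if (tie == "ref" && !is.null(ref_chars)) {
    ridx <- match(ref_chars, .BASES5)
    ok <- !is.na(ridx)
    sc[cbind(ridx[ok], which(ok))] <- sc[cbind(ridx[ok], which(ok))] + 0.25
  }
  maj <- max.col(t(sc), ties.method = "first") # A<C<G<T<'-' precedence
  em <- c(.BASES, "")[maj]
  if (ref_fill && !is.null(ref_chars)) {
    low <- pl$depth < min_depth
    em[low] <- ref_chars[low]
  }
  ins_after <- character(max(L - 1L, 0L))
  if (nrow(pl$ins)) {
    for (j in unique(pl$ins$junction)) {
      tot <- pl$n_ins_reads[j]
      if (pl$span[j] > 0 && tot > 0.5 * pl$span[j]) {
        cand <- pl$ins[pl$ins$junction == j, ]
        cand <- cand[order(-cand$n_reads, nchar(cand$seq), cand$seq), ]
        ins_after[j] <- cand$seq[1]
      }
    }
  }
  list(em = em, ins_after = ins_after)
}

emissions_to_seq <- function(emm) {
  L <- length(emm$em)
  pieces <- character(2L * L)
  pieces[seq(1, 2L * L, 2)] <- emm$em
  if (L > 1) pieces[seq(2, 2L * L - 2, 2)] <- emm$ins_after
  paste(pieces, collapse = "")
}

#' Majority consensus from a pileup of alignments
#'
#' Per reference column, emits the majority of `{A,C,G,T,deletion}`;
#' insertions are emitted when supported by more than half of the reads
#' spanning the junction (the most-supported inserted sequence is used).
#' Columns with depth below `min_depth` emit the reference base, so sparse
#' regions inherit reference content -- the mechanism by which
#' reference-guided consensi acquire reference bias. Exact ties are resolved
#' toward the reference base.
#'
#' @param alignments list of alignments from [semiglobal_align()], all
#'   against `ref`.
#' @param ref reference: nucleotide string or list/tibble row with `seq`
#'   and optionally `id`.
#' @param min_depth minimum depth below which the reference base is emitted
#'   (default 1).
#' @return a [contig][new_contig] with `support = length(alignments)`.
#' @export
pileup_consensus <- function(alignments, ref, min_depth = 1L) {
  if (length(alignments) == 0) abort("no alignments")
  ref_seq <- as_seq(ref, "ref")
  pl <- pileup_build(alignments, nchar(ref_seq))
  emm <- pileup_emissions(pl, ref_seq, min_depth, tie = "ref", ref_fill = TRUE)
  new_contig(emissions_to_seq(emm), support = length(alignments),
             read_ids = character(0))
}

#' Per-column pileup table
#'
#' Human-readable dump of a pileup: per reference position, the depth and
#' the A/C/G/T/deletion tallies plus the most common insertion (if any)
#' after that position. Positions are 1-based here (internal computation is
#' 0-based half-open).
#'
#' @inheritParams pileup_consensus
#' @return a tibble: `pos`, `ref`, `depth`, `A`, `C`, `G`, `T`, `del`,
#'   `top_insertion`.
#' @export
pileup_table <- function(alignments, ref) {
  ref_seq <- as_seq(ref, "ref")
  L <- nchar(ref_seq)
  pl <- pileup_build(alignments, L)
  top_ins <- rep("", L)
  if (nrow(pl$ins)) {
    agg <- pl$ins %>% group_by(.data$junction) %>%
      dplyr::slice_max(.data$n_reads, n = 1, with_ties = FALSE) %>% ungroup()
    top_ins[agg$junction] <- agg$seq
  }
  tibble(pos = seq_len(L),
         ref = strsplit(ref_seq, "", fixed = TRUE)[[1]],
         depth = as.integer(pl$depth),
         A = pl$counts["A", ], C = pl$counts["C", ],
         G = pl$counts["G", ], T = pl$counts["T", ],
         del = pl$counts["-", ],
         top_insertion = top_ins)
}
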