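# Read-backed polishing: iterative pileup majority over the current draft
# with explicit homopolymer run-length voting, plus primer/adapter trimming
# of the final consensus.

#' Consensus homopolymer run length from per-read observations
#'
#' Given per-read observations of the length of one homopolymer run, returns
#' the consensus run length: the longest length whose support reaches
#' `bias_margin` times the maximal support, which reduces to the modal
#' observation with ties resolved toward the *longer* length when
#' `bias_margin = 1`. Both the tie direction and the sub-unity default
#' margin compensate the systematic deletion bias of nanopore-style reads
#' inside homopolymers: under-called lengths dominate the observations at
#' the true length, so when the count one below the truth edges slightly
#' ahead by sampling noise, the longer length is still the better call --
#' while spurious *longer* observations (insertion-driven, several-fold
#' rarer) never come close to the margin.
#'
#' @param obs integer vector of per-read run-length observations (nonempty),
#'   or a table/named vector of counts (names = lengths).
#' @param bias_margin fraction of the maximal support a longer length needs
#'   to win the call (default 0.65; 1 = strict mode with tie to longer).
#' @return the consensus run length (integer).
#' @export
#' @examples
#' homopolymer_adjudicate(c(6, 6, 5, 6, 5)) # 6
#' homopolymer_adjudicate(c(`5` = 50, `6` = 50)) # tie -> 6
homopolymer_adjudicate <- function(obs, bias_margin = 0.65) {
  if (length(obs) == 0) abort("no run-length observations")
  stopifnot(bias_margin > 0, bias_margin <= 1)
  if (!is.null(names(obs))) {
    lens <- as.integer(names(obs)); cnt <- as.numeric(obs)
  } else {
    tb <- table(as.integer(obs))
    lens <- as.integer(names(tb)); cnt <- as.numeric(tb)
  }
  max(lens[cnt >= bias_margin * max(cnt)])
}

# Per-read observed run length for a draft homopolymer run [s, e] of base B:
# B's carried by the read across the run's columns *plus one flanking column
# on each side* (matches and insertions). The widened window makes the count
# robust to near-run alignment ambiguity (a gap/substitution swap at a run
# edge can park a run base one column outside the run without changing the
# read's actual run length).
run_observations <- function(pl, s, e, B) {
  L <- length(pl$span) + 1L
  jlo <- max(1L, s - 1L); jhi <- min(L - 1L, e)
  wlo <- max(1L, s - 1L); whi <- min(L, e + 1L)
  obs <- integer(0)
  for (k in seq_along(pl$per_read)) {
    if (pl$rstart[k] > wlo || pl$rend[k] < whi) next
    pr <- pl$per_read[[k]]
    sel <- pr$mpos >= wlo & pr$mpos <= whi
    n_b <- sum(pr$mchar[sel] == B)
    if (length(pr$ins_j)) {
      jj <- pr$ins_j >= jlo & pr$ins_j <= jhi
      if (any(jj)) {
        n_b <- n_b + sum(vapply(strsplit(pr$ins_s[jj], "", fixed = TRUE),
                                function(ch) sum(ch == B), integer(1)))
      }
    }
    obs <- c(obs, n_b)
  }
  obs
}

# all-one-base test
is_pure_run <- function(x, B) {
  nzchar(x) & vapply(strsplit(x, "", fixed = TRUE),
                     function(ch) all(ch == B), logical(1))
}

# Low-agreement windows of a pileup: maximal groups of columns where the
# top tally falls below `min_agree` of the depth (or an insertion junction
# has ambiguous 20-50% support), merged across gaps of <= 6 columns and
# extended into 4 anchor columns on each side.
unstable_windows <- function(pl, min_agree = 0.7) {
  L <- ncol(pl$counts)
  agree <- rep(1, L)
  pos <- pl$depth > 0
  agree[pos] <- apply(pl$counts[, pos, drop = FALSE], 2, max) / pl$depth[pos]
  unstable <- agree < min_agree
  if (length(pl$span)) {
    frac <- ifelse(pl$span > 0, pl$n_ins_reads / pl$span, 0)
    amb <- which(frac > 0.2 & frac <= 0.5)
    unstable[amb] <- TRUE
    unstable[pmin(amb + 1L, L)] <- TRUE
  }
  w <- which(unstable)
  if (length(w) == 0) return(NULL)
  grp <- cumsum(c(TRUE, diff(w) > 6L))
  win <- lapply(split(w, grp), function(cols) {
    c(max(1L, min(cols) - 4L), min(L, max(cols) + 4L))
  })
  # merge windows whose extended ranges touch: a window boundary inside a
  # disturbed region is unanchored, and re-calling fragments of one
  # disturbance separately defeats the path-invariance of the substrings
  merged <- list(win[[1]])
  for (wi in win[-1]) {
    last <- merged[[length(merged)]]
    if (wi[1] <= last[2] + 1L) {
      merged[[length(merged)]] <- c(last[1], max(last[2], wi[2]))
    } else {
      merged[[length(merged) + 1L]] <- wi
    }
  }
  merged
}

# Per-read substring carried across columns [w1, w2]: matched bases plus
# insertions at the interior junctions, in order. Path-invariant away from
# the window edges, which is the point: reads whose alignments disagree on
# *where* to place an indel still yield the same substring.
window_substrings <- function(pl, w1, w2) {
  L <- length(pl$span) + 1L
  out <- character(0)
  for (k in seq_along(pl$per_read)) {
    if (pl$rstart[k] > max(1L, w1 - 1L) || pl$rend[k] < min(L, w2 + 1L)) next
    pr <- pl$per_read[[k]]
    sel <- pr$mpos >= w1 & pr$mpos <= w2
    piece <- setNames(rep("", w2 - w1 + 1L), as.character(w1:w2))
    mk <- pr$mchar[sel]; mp <- pr$mpos[sel]
    keep <- mk != "-"
    piece[as.character(mp[keep])] <- mk[keep]
    if (length(pr$ins_j)) {
      jj <- which(pr$ins_j >= w1 & pr$ins_j < w2)
      for (i in jj) {
        key <- as.character(pr$ins_j[i])
        piece[key] <- paste0(piece[key], pr$ins_s[i])
      }
    }
    out <- c(out, paste(piece, collapse = ""))
  }
  out
}

# longest stretch of consecutive copies of `unit` in `s`, in copies
max_copies <- function(s, unit) {
  m <- gregexpr(paste0("(?:", unit, ")+"), s)[[1]]
  if (m[1] == -1) return(0L)
  max(attr(m, "match.length")) %/% nchar(unit)
}

# Repair tandem-repeat copy numbers in a window consensus. Nanopore-style
# deletions undercount copies of short tandem units (homopolymers are the
# period-1 case; dinucleotide repeats slip the same way, with the extra
# pathology that reads supporting a missing unit split their insertion
# support across equivalent junctions and never reach a column majority).
# For every unit that a third of the spanning reads carry as an array, the
# per-read copy counts are adjudicated with the deletion-bias margin and
# the (unique) array in the consensus is resized accordingly.
repair_tandem <- function(out, ss, bias_margin = 0.65) {
  if (!nzchar(out) || length(ss) < 3) return(out)
  for (period in 1:2) {
    rx <- if (period == 1) "([ACGT])\\1{2,}" else "([ACGT]{2})\\1+"
    min_copies <- if (period == 1) 3L else 2L
    units <- unique(unlist(lapply(ss, function(s) {
      m <- regmatches(s, gregexpr(rx, s))[[1]]
      substr(m, 1, period)
    })))
    units <- units[nchar(units) == period]
    if (period == 2) {
      units <- units[substr(units, 1, 1) != substr(units, 2, 2)]
      # a unit and its rotation describe the same array; keep one
      units <- units[units <= vapply(units, function(u)
        paste0(substr(u, 2, 2), substr(u, 1, 1)), character(1))]
    }
    for (u in units) {
      obs <- unname(vapply(ss, max_copies, integer(1), unit = u))
      if (mean(obs >= min_copies) < 0.3) next
      # only repair when the consensus holds exactly one array of this unit
      hits <- gregexpr(paste0("(?:", u, ")+"), out)[[1]]
      if (hits[1] == -1 || length(hits) != 1) next
      kstar <- homopolymer_adjudicate(obs, bias_margin)
      len <- attr(hits, "match.length")[1]
      k_now <- len %/% period
      if (kstar == k_now || kstar < 1) next
      out <- paste0(substr(out, 1, hits[1] - 1), strrep(u, kstar),
                    substr(out, hits[1] + k_now * period, nchar(out)))
    }
  }
  out
}

# Consensus of a set of window substrings, voted in run-length space: the
# modal RLE base pattern is chosen first (robust, because homopolymer length
# noise no longer fragments the vote), then each run's length is adjudicated
# with the same deletion-bias rule used for standalone homopolymer runs.
# When no two reads share an exact pattern (long or repeat-dense windows at
# modest depth), the medoid substring -- minimal total edit distance to the
# others -- stands in: it lands the draft in the right neighbourhood for the
# next majority round to refine. NULL when fewer than min_n reads span.
rle_consensus <- function(x, min_n = 3L, min_count = 2L,
                          bias_margin = 0.65) {
  if (length(x) < min_n) return(NULL)
  rles <- lapply(strsplit(x, "", fixed = TRUE), rle)
  pats <- vapply(rles, function(r) paste(r$values, collapse = ""),
                 character(1))
  tb <- sort(table(pats), decreasing = TRUE)
  if (tb[1] < min_count) {
    d <- utils::adist(x)
    tot <- rowSums(d)
    out <- sort(x[tot == min(tot)])[1]
    return(repair_tandem(out, x, bias_margin))
  }
  pat <- sort(names(tb)[tb == tb[1]])[1]
  sel <- which(pats == pat)
  if (!nzchar(pat)) return("")
  bases <- strsplit(pat, "", fixed = TRUE)[[1]]
  lens <- vapply(seq_along(bases), function(i) {
    homopolymer_adjudicate(vapply(rles[sel], function(r) r$lengths[i],
                                  integer(1)), bias_margin)
  }, integer(1))
  repair_tandem(paste(strrep(bases, lens), collapse = ""), x, bias_margin)
}

#' Polish a draft consensus against its reads
#'
#' Iteratively remaps all reads to the current consensus (semi-global, both
#' strands; orientation is fixed after the first round), rebuilds the
#' consensus by pileup majority (substitutions, deletions and insertions),
#' and adjudicates every homopolymer run of length >= `hp_min_run` in the
#' draft by run-length voting ([homopolymer_adjudicate()]). Majority ties
#' are kept at the current draft base, which makes a draft that already
#' equals the majority call of its own pileup a fixed point. Iteration stops
#' when a round changes nothing or after `max_rounds` rounds.
#'
#' Coverage in the report follows the field convention that produced the
#' field-report "total vs average" coverage discrepancy: `total_depth` counts the
#' bases of *all* reads handed to the polisher (junk included) over the
#' consensus length, while `mean_depth` is the mean per-column aligned depth
#' of the reads that actually mapped.
#'
#' @param draft a contig (or nucleotide string) to polish.
#' @param reads reads tibble (all reads, not only the cluster; unrelated
#'   reads fail the identity floor and are ignored).
#' @param max_rounds maximum polishing rounds (default 4).
#' @param min_identity mapping identity floor (default 0.6).
#' @param hp_min_run minimum homopolymer run length adjudicated (default 3).
#' @param band alignment band half-width.
#' @return a list of class `nanobar_polish`: `contig` (polished), `report`
#'   (list: `rounds`, `changes_per_round`, `final_mapped`, `mean_depth`,
#'   `total_depth`).
#' @export
polish_consensus <- function(draft, reads, max_rounds = 4L,
                             min_identity = 0.6, hp_min_run = 3L,
                             band = 100L) {
  if (nrow(reads) == 0) abort("no reads to polish with")
  if (inherits(draft, "nanobar_contig")) {
    contig <- draft
  } else {
    contig <- new_contig(as_seq(draft, "draft"), support = 0L)
  }
  current <- contig$seq
  seqs <- reads$seq
  oriented <- FALSE
  changes <- integer(0)
  final_mapped <- 0L
  mean_depth <- 0
  # rounds can cycle between near-equivalent drafts; keep the draft that
  # maximises the summed read-alignment score (a likelihood proxy) and
  # return it, scoring the last produced draft with one extra pass
  best_score <- -Inf
  best_seq <- current
  for (round in seq_len(max_rounds + 1L)) {
    alns <- vector("list", length(seqs))
    strands <- character(length(seqs))
    for (k in seq_along(seqs)) {
      if (oriented) {
        sq <- seqs[k]
        ctr <- NULL
      } else {
        # orient once by shared-k-mer vote; junk reads fail the identity
        # floor downstream either way
        share <- cpp_kmer_share(current, seqs[k], 12L)
        strands[k] <- if (share[2] > share[1]) "-" else "+"
        sq <- if (strands[k] == "-") revcomp(seqs[k]) else seqs[k]
        ctr <- if (share[1] == 0 && share[2] == 0) NULL else
          share[3 + (strands[k] == "-")]
      }
      a <- align_pair(sq, current, TRUE, TRUE, band,
                      double_band = FALSE, band_center = ctr)
      if (a$columns > 0 && a$identity >= min_identity) {
        # (assigning NULL into a list would drop the element and misalign
        # the mapped mask against the read vector)
        alns[[k]] <- structure(
          list(strand = "+", identity = a$identity,
               score = a$score, aln_q = a$aln_q, aln_r = a$aln_r,
               rstart = a$rstart, rend = a$rend),
          class = "nanobar_alignment")
      }
    }
    ok <- !vapply(alns, is.null, logical(1))
    if (!any(ok)) {
      warn("no reads map to the draft; returning it unchanged")
      report <- list(rounds = 0L, changes_per_round = integer(0),
                     final_mapped = 0L, mean_depth = 0,
                     total_depth = sum(nchar(reads$seq)) / nchar(current))
      return(structure(list(contig = contig, report = report),
                       class = "nanobar_polish"))
    }
    if (!oriented) {
      seqs <- ifelse(ok & strands == "-", revcomp(seqs), seqs)
      oriented <- TRUE
    }
    alns <- alns[ok]
    tot <- sum(vapply(alns, function(a) as.numeric(a$score), numeric(1)))
    if (tot > best_score) { best_score <- tot; best_seq <- current }
    if (round > max_rounds) break
    pl <- pileup_build(alns, nchar(current))
    emm <- pileup_emissions(pl, ref_seq = current, tie = "ref",
                            ref_fill = FALSE)
    # homopolymer run-length voting over the draft's runs
    dr <- rle(strsplit(current, "", fixed = TRUE)[[1]])
    ends <- cumsum(dr$lengths)
    starts <- ends - dr$lengths + 1L
    hp_runs <- which(dr$lengths >= hp_min_run)
    for (ri in hp_runs) {
      B <- dr$values[ri]; s <- starts[ri]; e <- ends[ri]
      # length voting only applies where the reads agree the region is a
      # homopolymer: a non-run base in the column majority (e.g. a
      # substitution the draft had absorbed into the run) is left to the
      # majority call
      if (!all(emm$em[s:e] %in% c(B, ""))) next
      obs <- run_observations(pl, s, e, B)
      if (length(obs) == 0) next
      lstar <- homopolymer_adjudicate(obs)
      emm$em[s] <- strrep(B, lstar)
      if (e > s) emm$em[(s + 1L):e] <- ""
      jlo <- max(1L, s - 1L); jhi <- min(nchar(current) - 1L, e)
      jj <- jlo:jhi
      drop <- jj[is_pure_run(emm$ins_after[jj], B)]
      emm$ins_after[drop] <- ""
    }
    # local re-call of low-agreement windows: column-wise voting cannot
    # escape locally shifted drafts (read support splits between the
    # substitution-path and indel-path alignments of the same difference),
    # so ambiguous stretches are replaced by a consensus of the read
    # substrings across the window, voted in run-length space
    hp_iv <- cbind(starts[hp_runs], ends[hp_runs])
    L <- nchar(current)
    for (w in unstable_windows(pl)) {
      w1 <- w[1]; w2 <- w[2]
      # grow the window over any homopolymer run it touches, so run lengths
      # are never voted on a partial run, then re-anchor by one column
      if (nrow(hp_iv)) {
        repeat {
          clash <- which(hp_iv[, 1] <= w2 + 1L & hp_iv[, 2] >= w1 - 1L)
          if (length(clash) == 0) break
          n1 <- max(1L, min(w1, hp_iv[clash, 1] - 1L))
          n2 <- min(L, max(w2, hp_iv[clash, 2] + 1L))
          if (n1 == w1 && n2 == w2) break
          w1 <- n1; w2 <- n2
        }
      }
      if (w2 - w1 + 1L > 60L) next
      new_piece <- rle_consensus(window_substrings(pl, w1, w2))
      if (is.null(new_piece)) next
      emm$em[w1] <- new_piece
      if (w2 > w1) {
        emm$em[(w1 + 1L):w2] <- ""
        emm$ins_after[w1:(w2 - 1L)] <- ""
      }
    }
    newseq <- emissions_to_seq(emm)
    if (!nzchar(newseq)) newseq <- current
    ch <- utils::adist(current, newseq)[1, 1]
    changes <- c(changes, as.integer(ch))
    current <- newseq
    final_mapped <- sum(ok)
    mean_depth <- mean(pl$depth)
    if (ch == 0) break
  }
  contig$seq <- best_seq
  report <- list(rounds = length(changes), changes_per_round = changes,
                 final_mapped = final_mapped, mean_depth = mean_depth,
                 total_depth = sum(nchar(reads$seq)) / nchar(best_seq))
  structure(list(contig = contig, report = report), class = "nanobar_polish")
}

#' @export
print.nanobar_polish <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<polish> %d round%s (changes: %s), %d reads mapped, mean depth %.1fx, total depth %.1fx\n",
    r$rounds, if (r$rounds == 1) "" else "s",
    paste(r$changes_per_round, collapse = ","),
    r$final_mapped, r$mean_depth, r$total_depth))
  print(x$contig)
  invisible(x)
}

# locate pattern in a region of text; returns hit with absolute coordinates
# or NULL if edits exceed max_error * pattern length
find_motif <- function(pattern, text, from, to, max_error) {
  if (from > to || nchar(pattern) == 0) return(NULL)
  region <- substr(text, from, to)
  h <- edit_locate(pattern, region)
  if (is.null(h) || h$edits > floor(max_error * nchar(pattern))) return(NULL)
  list(edits = h$edits, start = from + h$start - 1L, end = from + h$end - 1L)
}

#' Trim primers and residual adapter from a consensus
#'
#' Locates the forward primer near the 5' end and the reverse-complemented
#' reverse primer near the 3' end of the consensus by semi-global
#' edit-distance search (at most `max_error` edits per primer length, default
#' 20%), in both orientations of the consensus, and removes everything
#' outside the insert. If neither primer is found the input is returned
#' unchanged with attribute `trim_warning = TRUE`.
#'
#' @param consensus a contig or nucleotide string.
#' @param primer_f,primer_r forward/reverse primer sequences (strings). A
#'   list with elements `primer_f`, `primer_r` (e.g. [example_primers()]) can
#'   be given as `primer_f`.
#' @param barcodes optional barcode tibble; unused for locating the cut
#'   (primers define the insert) but accepted for interface symmetry.
#' @param max_error maximum edit fraction when locating a primer (default 0.2).
#' @param window search window at each end in bases (default 150 plus primer
#'   length).
#' @return the trimmed contig (class `nanobar_contig`), with attributes
#'   `trimmed` (logical) and `trim_warning`.
#' @export
trim_consensus <- function(consensus, primer_f, primer_r = NULL,
                           barcodes = NULL, max_error = 0.2, window = 150L) {
  if (is.list(primer_f) && !is.null(primer_f$primer_f)) {
    primer_r <- primer_f$primer_r
    primer_f <- primer_f$primer_f
  }
  if (inherits(consensus, "nanobar_contig")) {
    contig <- consensus
  } else {
    contig <- new_contig(as_seq(consensus, "consensus"), support = 0L)
  }
  seqs <- c("+" = contig$seq, "-" = revcomp(contig$seq))
  best <- NULL
  for (ori in names(seqs)) {
    s <- seqs[[ori]]
    L <- nchar(s)
    w5 <- min(L, window + nchar(primer_f))
    hf <- find_motif(primer_f, s, 1L, w5, max_error)
    hr <- NULL
    if (!is.null(primer_r)) {
      w3 <- max(1L, L - window - nchar(primer_r) + 1L)
      hr <- find_motif(revcomp(primer_r), s, w3, L, max_error)
    }
    found <- sum(!is.null(hf), !is.null(hr))
    edits <- sum(if (is.null(hf)) 0L else hf$edits,
                 if (is.null(hr)) 0L else hr$edits)
    if (is.null(best) || found > best$found ||
        (found == best$found && edits < best$edits)) {
      best <- list(ori = ori, s = s, hf = hf, hr = hr, found = found,
                   edits = edits)
    }
  }
  if (best$found == 0) {
    attr(contig, "trimmed") <- FALSE
    attr(contig, "trim_warning") <- TRUE
    return(contig)
  }
  from <- if (is.null(best$hf)) 1L else best$hf$end + 1L
  to <- if (is.null(best$hr)) nchar(best$s) else best$hr$start - 1L
  if (from > to) {
    attr(contig, "trimmed") <- FALSE
    attr(contig, "trim_warning") <- TRUE
    return(contig)
  }
  contig$seq <- substr(best$s, from, to)
  attr(contig, "trimmed") <- TRUE
  attr(contig, "trim_warning") <- FALSE
  contig
}
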