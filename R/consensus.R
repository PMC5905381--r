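# De novo consensus: overlap detection, read clustering, center-star
# column-majority consensus, and the multiplexed assembly wrapper.

#' Assembly parameters
#'
#' Bundles the amplicon-scale assembly thresholds: the minimum read length
#' admitted to assembly, the minimum overlap span and identity for two reads
#' to be considered the same molecule, and the maximum divergence tolerated
#' within one cluster.
#'
#' @param min_read_len minimum read length for assembly (default 200).
#' @param min_overlap minimum overlap span in alignment columns (default 50).
#' @param min_overlap_identity minimum overlap identity (default 0.7).
#' @param max_cluster_divergence maximum within-cluster divergence; loci more
#'   divergent than this are guaranteed to separate (default 0.15).
#' @param band alignment band half-width used for read-vs-read alignments.
#' @return a list of class `assembly_params`.
#' @export
assembly_params <- function(min_read_len = 200L, min_overlap = 50L,
                            min_overlap_identity = 0.7,
                            max_cluster_divergence = 0.15,
                            band = 100L) {
  stopifnot(min_overlap <= min_read_len,
            min_overlap_identity > 0, min_overlap_identity <= 1,
            max_cluster_divergence > 0, max_cluster_divergence <= 1)
  structure(list(min_read_len = as.integer(min_read_len),
                 min_overlap = as.integer(min_overlap),
                 min_overlap_identity = min_overlap_identity,
                 max_cluster_divergence = max_cluster_divergence,
                 band = as.integer(band)),
            class = "assembly_params")
}

#' Contig constructor
#'
#' A contig is a draft or polished consensus sequence together with the reads
#' that built it.
#'
#' @param seq nucleotide string (nonempty).
#' @param support number of reads used to build the contig.
#' @param read_ids ids of the cluster reads.
#' @param locus_label optional locus annotation.
#' @return an object of class `nanobar_contig` (a named list).
#' @export
new_contig <- function(seq, support, read_ids = character(0),
                       locus_label = NULL) {
  if (!nzchar(seq)) abort("contig sequence must be nonempty")
  structure(list(seq = seq, support = as.integer(support),
                 read_ids = read_ids, locus_label = locus_label),
            class = "nanobar_contig")
}

#' @export
print.nanobar_contig <- function(x, ...) {
  cat(sprintf("<contig> %d bp, support %d read%s%s\n", nchar(x$seq),
              x$support, if (x$support == 1) "" else "s",
              if (is.null(x$locus_label)) "" else paste0(" [", x$locus_label, "]")))
  invisible(x)
}

#' Best overlap between two reads
#'
#' Semi-global (dovetail) alignment of `b` against `a`, testing both
#' orientations of `b`. An overlap is reported only when the aligned span is
#' at least `min_overlap` columns and its identity is at least
#' `min_overlap_identity`.
#'
#' @param a,b reads: nucleotide strings or one-row reads tibbles.
#' @param params an [assembly_params()] list.
#' @return `NULL`, or a list `length` (alignment columns), `identity`,
#'   `orientation` (`"+"`/`"-"`).
#' @export
pairwise_overlap <- function(a, b, params = assembly_params()) {
  sa <- as_seq(a, "a"); sb <- as_seq(b, "b")
  # shared-12-mer prescreen: reads from one molecule share tens of intact
  # 12-mers even at ~11% error, unrelated reads essentially none, so the
  # expensive alignment only runs for plausible pairs (and only in the
  # strand the k-mers vote for)
  share <- cpp_kmer_share(sa, sb, 12L)
  if (max(share[1:2]) < 5L) return(NULL)
  orientations <- if (share[1] == share[2]) c("+", "-") else
    if (share[1] > share[2]) "+" else "-"
  best <- NULL
  for (ori in orientations) {
    sq <- if (ori == "+") sb else revcomp(sb)
    al <- align_pair(sq, sa, free_q = TRUE, free_r = TRUE,
                     band = params$band, double_band = FALSE,
                     band_center = if (ori == "+") share[3] else share[4])
    if (al$columns >= params$min_overlap &&
        al$identity >= params$min_overlap_identity &&
        (is.null(best) || al$score > best$score)) {
      best <- list(length = al$columns, identity = al$identity,
                   orientation = ori, score = al$score)
    }
  }
  if (is.null(best)) return(NULL)
  best[c("length", "identity", "orientation")]
}

#' Cluster reads by overlap
#'
#' Single-linkage clustering over the read-overlap graph, computed by
#' representative linkage: reads are processed longest first, each new read
#' is aligned against up to three representatives (the longest members) of
#' every existing cluster, joins every cluster whose representative it
#' overlaps (merging those clusters), and otherwise founds a new cluster.
#' When within-locus read identity exceeds the overlap threshold and
#' between-locus identity falls below it -- the regime amplicon data is in --
#' this reproduces exact single linkage at a linear number of alignments.
#'
#' Reads shorter than `params$min_read_len` are excluded (they remain
#' available to the polishing stage, which remaps all reads).
#'
#' @param reads reads tibble.
#' @param params an [assembly_params()] list.
#' @return a tibble `read_id`, `cluster` (integer; clusters numbered by
#'   decreasing size).
#' @export
cluster_reads <- function(reads, params = assembly_params()) {
  keep <- nchar(reads$seq) >= params$min_read_len
  rd <- reads[keep, , drop = FALSE]
  n <- nrow(rd)
  if (n == 0) {
    return(tibble(read_id = character(0), cluster = integer(0)))
  }
  ord <- order(-nchar(rd$seq), seq_len(n))
  clusters <- list() # each: list(members = int idx into rd, reps = int idx)
  for (i in ord) {
    hits <- integer(0)
    for (ci in seq_along(clusters)) {
      for (rep_i in clusters[[ci]]$reps) {
        ov <- pairwise_overlap(rd$seq[rep_i], rd$seq[i], params)
        if (!is.null(ov)) { hits <- c(hits, ci); break }
      }
    }
    if (length(hits) == 0) {
      clusters[[length(clusters) + 1L]] <- list(members = i, reps = i)
    } else {
      tgt <- hits[1]
      members <- c(clusters[[tgt]]$members, i)
      if (length(hits) > 1) {
        for (ci in hits[-1]) members <- c(members, clusters[[ci]]$members)
        clusters[hits[-1]] <- NULL
        tgt <- hits[1] - sum(hits[-1] < hits[1])
      }
      members <- sort(members)
      reps <- members[order(-nchar(rd$seq[members]), members)][seq_len(min(3L, length(members)))]
      clusters[[tgt]] <- list(members = members, reps = reps)
    }
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  firsts <- vapply(clusters, function(cl) min(cl$members), integer(1))
  ord_cl <- order(-sizes, firsts)
  out <- vector("list", length(ord_cl))
  for (k in seq_along(ord_cl)) {
    cl <- clusters[[ord_cl[k]]]
    out[[k]] <- tibble(read_id = rd$id[cl$members], cluster = k)
  }
  bind_rows(out)
}

#' Center-star consensus of one read cluster
#'
#' Orients every read to the orientation of a center read -- the k-mer
#' medoid of the cluster for clusters of up to 50 reads (at low depth the
#' center's own errors dominate the draft, and the read sharing the most
#' 12-mers per base with the rest is measurably cleaner), the longest read
#' otherwise -- aligns all reads to that read (semi-global, free ends),
#' and emits the
#' column-majority consensus: per column the plurality of
#' `{A,C,G,T,deletion}` (exact ties by base precedence A<C<G<T over gap),
#' with insertions emitted when supported by more than half of the spanning
#' reads. Gap-majority columns are emitted as deletions. Drafts from this
#' one-round construction are meant to be refined by [polish_consensus()].
#'
#' @param reads reads tibble (the cluster; nonempty).
#' @param params an [assembly_params()] list (used for the alignment band).
#' @return a [contig][new_contig] with `support = nrow(reads)`.
#' @export
build_consensus <- function(reads, params = assembly_params()) {
  if (nrow(reads) == 0) abort("cluster is empty")
  if (nrow(reads) == 1) {
    return(new_contig(reads$seq[1], 1L, reads$id[1]))
  }
  # Center choice: for small clusters the center's own errors dominate the
  # draft, so use the medoid -- the read sharing the most 12-mers per base
  # with the rest of the cluster (intact k-mers are what error-free stretches
  # look like). Large clusters have the depth to vote any center's errors
  # away, so the longest read suffices there.
  n <- nrow(reads)
  if (n <= 50) {
    agree <- numeric(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- cpp_kmer_share(reads$seq[i], reads$seq[j], 12L)
        sh <- max(s[1], s[2])
        agree[i] <- agree[i] + sh
        agree[j] <- agree[j] + sh
      }
    }
    center_i <- order(-agree / pmax(nchar(reads$seq), 1L),
                      -nchar(reads$seq), seq_len(n))[1]
  } else {
    center_i <- order(-nchar(reads$seq), seq_len(n))[1]
  }
  center <- reads$seq[center_i]
  alns <- vector("list", nrow(reads))
  for (k in seq_len(nrow(reads))) {
    share <- cpp_kmer_share(center, reads$seq[k], 12L)
    ori <- if (share[2] > share[1]) "-" else "+"
    sq <- if (ori == "-") revcomp(reads$seq[k]) else reads$seq[k]
    ctr <- if (share[1] == 0 && share[2] == 0) NULL else
      share[3 + (ori == "-")]
    a <- align_pair(sq, center, free_q = TRUE, free_r = TRUE,
                    band = params$band, double_band = FALSE,
                    band_center = ctr)
    if (a$columns > 0) {
      alns[[k]] <- list(aln_q = a$aln_q, aln_r = a$aln_r,
                        rstart = a$rstart, rend = a$rend)
    }
  }
  alns <- alns[!vapply(alns, is.null, logical(1))]
  pl <- pileup_build(alns, nchar(center))
  emm <- pileup_emissions(pl, ref_seq = NULL, tie = "precedence",
                          ref_fill = FALSE)
  seq <- emissions_to_seq(emm)
  if (!nzchar(seq)) seq <- center # degenerate: fall back to the center read
  new_contig(seq, nrow(reads), reads$id)
}

#' Pick the best-supported contig
#'
#' Returns the contig with maximal read support; ties are broken by longer
#' sequence, then lexicographically smaller sequence.
#'
#' @param contigs a (nonempty) list of contigs.
#' @return a single contig.
#' @export
select_best_contig <- function(contigs) {
  if (length(contigs) == 0) abort("no contigs")
  sup <- vapply(contigs, function(x) x$support, integer(1))
  len <- vapply(contigs, function(x) nchar(x$seq), integer(1))
  sq <- vapply(contigs, function(x) x$seq, character(1))
  ord <- order(-sup, -len, sq)
  contigs[[ord[1]]]
}

#' Assemble a multiplexed read set into per-locus contigs
#'
#' Clusters the (possibly multi-locus) reads, builds a center-star consensus
#' per cluster, and returns the `n_loci` best-supported contigs. Loci whose
#' mutual identity is below the overlap threshold are guaranteed to land in
#' distinct clusters. Polishing is left to the caller (see
#' [polish_consensus()]).
#'
#' @param reads reads tibble (may mix loci).
#' @param params an [assembly_params()] list.
#' @param n_loci number of contigs to return.
#' @return a list of contigs ordered by decreasing support; if fewer clusters
#'   than `n_loci` exist, all are returned with a warning. Each contig keeps
#'   its cluster's read ids.
#' @export
assemble_multiplexed <- function(reads, params = assembly_params(),
                                 n_loci = 1L) {
  if (nrow(reads) == 0) abort("empty read set")
  cl <- cluster_reads(reads, params)
  if (nrow(cl) == 0) abort("no reads pass min_read_len")
  ncl <- max(cl$cluster)
  if (ncl < n_loci) {
    warn(sprintf("only %d cluster%s found for n_loci = %d", ncl,
                 if (ncl == 1) "" else "s", n_loci))
  }
  take <- seq_len(min(n_loci, ncl))
  contigs <- lapply(take, function(k) {
    ids <- cl$read_id[cl$cluster == k]
    build_consensus(reads[match(ids, reads$id), , drop = FALSE], params)
  })
  sup <- vapply(contigs, function(x) x$support, integer(1))
  contigs[order(-sup)]
}

#' Write contigs as FASTA
#'
#' Headers carry `support=<n>` so the field's "best supported contig"
#' bookkeeping survives the round trip.
#'
#' @param contigs a list of contigs or a single contig.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  if (inherits(contigs, "nanobar_contig")) contigs <- list(contigs)
  ids <- vapply(seq_along(contigs), function(i) {
    x <- contigs[[i]]
    sprintf("contig%d support=%d reads=%d%s", i, x$support, x$support,
            if (is.null(x$locus_label)) "" else paste0(" locus=", x$locus_label))
  }, character(1))
  write_fasta(tibble(id = ids, seq = vapply(contigs, function(x) x$seq,
                                            character(1))), path)
}
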