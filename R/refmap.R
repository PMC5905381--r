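# Reference-guided consensus: map reads to a (possibly heterospecific)
# reference and call the pileup-majority consensus, then polish.

#' Reference-guided consensus pipeline
#'
#' Aligns every filtered read to the reference ([semiglobal_align()], both
#' strands, banded with automatic widening), calls the pileup-majority
#' consensus ([pileup_consensus()]; columns below `min_depth` inherit the
#' reference base, the source of reference bias), and polishes the result
#' against the same reads ([polish_consensus()]).
#'
#' @param reads reads tibble (filtered).
#' @param ref reference: nucleotide string, or a list/one-row tibble with
#'   `seq` and optionally `id`.
#' @param params an [assembly_params()] list (band is reused).
#' @param min_depth minimum depth for a read-derived call (default 1).
#' @param min_identity mapping identity floor (default 0.6).
#' @param polish polish the pileup consensus with the reads (default TRUE).
#' @param max_rounds polishing rounds.
#' @return a list of class `nanobar_refmap`: `contig`, `polish` (a
#'   `nanobar_polish` or NULL), `ref_id`, `n_mapped`, `fraction_mapped`.
#' @export
refguided_pipeline <- function(reads, ref, params = assembly_params(),
                               min_depth = 1L, min_identity = 0.6,
                               polish = TRUE, max_rounds = 4L) {
  if (nrow(reads) == 0) abort("empty read set")
  ref_id <- if (is.list(ref) && !is.null(ref$id)) ref$id[1] else "reference"
  ref_seq <- as_seq(ref, "ref")
  if (!nzchar(ref_seq)) abort("reference sequence is empty")
  alns <- list()
  for (k in seq_len(nrow(reads))) {
    a <- semiglobal_align(reads$seq[k], ref_seq, band = params$band,
                          min_identity = min_identity)
    if (!is.null(a)) alns[[length(alns) + 1L]] <- a
  }
  if (length(alns) < 2) abort("fewer than 2 reads mapped to the reference")
  contig <- pileup_consensus(alns, ref_seq, min_depth = min_depth)
  contig$read_ids <- reads$id
  pol <- NULL
  if (polish) {
    pol <- polish_consensus(contig, reads, max_rounds = max_rounds,
                            min_identity = min_identity, band = params$band)
    contig <- pol$contig
  }
  structure(list(contig = contig, polish = pol, ref_id = ref_id,
                 n_mapped = length(alns),
                 fraction_mapped = length(alns) / nrow(reads)),
            class = "nanobar_refmap")
}

#' @export
print.nanobar_refmap <- function(x, ...) {
  cat(sprintf("<refmap> ref '%s', %d/%d reads mapped (%.1f%%)\n",
              x$ref_id, x$n_mapped, round(x$n_mapped / x$fraction_mapped),
              100 * x$fraction_mapped))
  print(x$contig)
  invisible(x)
}

#' De novo consensus pipeline for one sample
#'
#' The full de novo route for a demultiplexed read set: overlap clustering,
#' center-star consensus of the largest cluster, polishing against all the
#' reads, and (when primers are given) primer trimming.
#'
#' @param reads reads tibble.
#' @param params an [assembly_params()] list.
#' @param primers optional primer pair (list with `primer_f`, `primer_r`)
#'   for trimming the final consensus.
#' @param polish polish the draft (default TRUE).
#' @param max_rounds polishing rounds.
#' @return a list of class `nanobar_denovo`: `contig`, `clusters` (tibble),
#'   `polish` (a `nanobar_polish` or NULL).
#' @export
consensus_denovo <- function(reads, params = assembly_params(),
                             primers = NULL, polish = TRUE, max_rounds = 4L) {
  if (nrow(reads) == 0) abort("empty read set")
  cl <- cluster_reads(reads, params)
  if (nrow(cl) == 0) abort("no reads pass min_read_len")
  ids <- cl$read_id[cl$cluster == 1L]
  contig <- build_consensus(reads[match(ids, reads$id), , drop = FALSE],
                            params)
  pol <- NULL
  if (polish) {
    pol <- polish_consensus(contig, reads, max_rounds = max_rounds,
                            band = params$band)
    contig <- pol$contig
  }
  if (!is.null(primers)) {
    contig <- trim_consensus(contig, primers)
  }
  structure(list(contig = contig, clusters = cl, polish = pol),
            class = "nanobar_denovo")
}
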