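# Accuracy measurement against a truth (Sanger) sequence: optimal global
# alignment over the truth with free query ends, per-class difference
# bookkeeping, homopolymer annotation, the coverage-subsampling experiment,
# and the de novo vs reference-guided comparison.

#' Percent identity of a consensus against a truth sequence
#'
#' Optimal affine-gap alignment that is global over the truth but leaves the
#' query's ends free, so residual primer/adapter flanks on an untrimmed
#' consensus are soft-clipped rather than penalised. Scores are fixed at
#' match +1, mismatch -1, gap open -2, gap extend -1 (a gap of length L
#' costs 2 + L), so reports are deterministic. Identity is computed over the
#' truth-spanning alignment columns, with every gap base counting one
#' column: `percent_identity = 100 * matches / aligned_columns`. This is the
#' convention under which a single 1 bp deletion against a 500 bp truth
#' yields 99.8%.
#'
#' @param query consensus: contig, nucleotide string, or list/tibble row
#'   with `seq`.
#' @param truth truth sequence, same forms accepted. Both orientations of
#'   the query are tried.
#' @param scores named integer vector `match, mismatch, gap_open, gap_ext`.
#' @return an object of class `nanobar_accuracy`: fields `percent_identity`,
#'   `aligned_columns`, `matches`, `substitutions`, `insertions`,
#'   `deletions`, `homopolymer_indels` (`NA` until [classify_errors()]), and
#'   `diffs`, a tibble of difference events (`column` = 1-based truth
#'   position, `type`, `truth`, `query`, `homopolymer`). Runs of gap columns
#'   are reported as single multi-base events.
#' @export
global_identity <- function(query, truth, scores = default_scores()) {
  q <- as_seq(query, "query")
  t_ <- as_seq(truth, "truth")
  if (!nzchar(q) || !nzchar(t_)) abort("query and truth must be nonempty")
  fwd <- align_pair(q, t_, free_q = TRUE, free_r = FALSE, band = -1L,
                    scores = scores)
  rev <- align_pair(revcomp(q), t_, free_q = TRUE, free_r = FALSE,
                    band = -1L, scores = scores)
  a <- if (rev$score > fwd$score) rev else fwd
  qc <- strsplit(a$aln_q, "", fixed = TRUE)[[1]]
  rc <- strsplit(a$aln_r, "", fixed = TRUE)[[1]]
  tpos <- cumsum(rc != "-") # truth position of each column (del cols -> base)
  type <- rep("match", length(qc))
  type[qc != rc] <- "substitution"
  type[qc == "-"] <- "deletion"
  type[rc == "-"] <- "insertion"
  # difference events: group consecutive columns of one type
  grp <- cumsum(c(TRUE, type[-1] != type[-length(type)]))
  diffs <- tibble(column = integer(0), type = character(0),
                  truth = character(0), query = character(0))
  rows <- list()
  for (g in unique(grp)) {
    ii <- which(grp == g)
    ty <- type[ii[1]]
    if (ty == "match") next
    if (ty == "substitution") {
      # one event per substituted column
      for (i in ii) {
        rows[[length(rows) + 1L]] <- tibble(
          column = tpos[i], type = "substitution",
          truth = rc[i], query = qc[i])
      }
    } else if (ty == "deletion") {
      rows[[length(rows) + 1L]] <- tibble(
        column = tpos[ii[1]], type = "deletion",
        truth = paste(rc[ii], collapse = ""), query = "")
    } else {
      rows[[length(rows) + 1L]] <- tibble(
        column = tpos[ii[1]], type = "insertion",
        truth = "", query = paste(qc[ii], collapse = ""))
    }
  }
  if (length(rows)) diffs <- bind_rows(rows)
  diffs$homopolymer <- NA
  matches <- a$matches
  cols <- a$columns
  structure(list(
    percent_identity = if (cols > 0) 100 * matches / cols else 0,
    aligned_columns = cols, matches = matches,
    substitutions = a$mismatches, insertions = a$insertions,
    deletions = a$deletions, homopolymer_indels = NA_integer_,
    diffs = diffs,
    strand = if (rev$score > fwd$score) "-" else "+"),
    class = "nanobar_accuracy")
}

#' Annotate indels that sit in homopolymer context
#'
#' Flags every indel event of an accuracy report whose truth-side flanking
#' run of a single base has length at least `hp_min_run` -- the classic
#' nanopore error class ("indels in poly-A stretches"). The report's
#' `homopolymer_indels` field is set to the number of indel *columns* (gap
#' bases) in flagged events, so it is bounded by `insertions + deletions`.
#'
#' @param report a `nanobar_accuracy` from [global_identity()].
#' @param truth the same truth sequence the report was computed against.
#' @param hp_min_run minimum run length that counts as a homopolymer
#'   (default 3).
#' @return the report with `diffs$homopolymer` filled and
#'   `homopolymer_indels` set.
#' @export
classify_errors <- function(report, truth, hp_min_run = 3L) {
  stopifnot(inherits(report, "nanobar_accuracy"))
  t_ <- as_seq(truth, "truth")
  tch <- strsplit(t_, "", fixed = TRUE)[[1]]
  r <- rle(tch)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  run_len <- r$lengths[run_id]  # per-position run length in the truth
  run_base <- r$values[run_id]
  L <- length(tch)
  flag_at <- function(pos, base = NULL) {
    # length of the single-base run at/adjacent to `pos` (optionally of `base`)
    cand <- c(pos, pos - 1L, pos + 1L)
    cand <- cand[cand >= 1L & cand <= L]
    if (!is.null(base)) cand <- cand[run_base[cand] == base]
    if (length(cand) == 0) return(0L)
    max(run_len[cand])
  }
  d <- report$diffs
  hp_cols <- 0L
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      if (d$type[i] == "substitution") { d$homopolymer[i] <- FALSE; next }
      bases <- strsplit(if (d$type[i] == "deletion") d$truth[i] else d$query[i],
                        "", fixed = TRUE)[[1]]
      # pure single-base indels check the run of that base; mixed indels
      # check any flanking run
      b <- if (length(unique(bases)) == 1) bases[1] else NULL
      is_hp <- flag_at(d$column[i], b) >= hp_min_run
      d$homopolymer[i] <- is_hp
      if (is_hp) hp_cols <- hp_cols + length(bases)
    }
  }
  report$diffs <- d
  report$homopolymer_indels <- hp_cols
  report
}

#' @export
print.nanobar_accuracy <- function(x, ...) {
  cat(sprintf(
    "<accuracy> %s%% identity (%d/%d columns): %d sub, %d ins, %d del%s\n",
    format(round(x$percent_identity, 1), nsmall = 1), x$matches,
    x$aligned_columns, x$substitutions, x$insertions, x$deletions,
    if (is.na(x$homopolymer_indels)) "" else
      sprintf(" (%d homopolymer indel columns)", x$homopolymer_indels)))
  if (nrow(x$diffs)) print(x$diffs, n = 10)
  invisible(x)
}

#' Coverage subsampling experiment
#'
#' Draws `replicates` random subsets of each size from the read pool
#' (without replacement), runs the de novo pipeline
#' (cluster -> consensus -> polish -> trim) on each subset, and reports the
#' consensus identity against the truth. Each draw uses the derived seed
#' `(seed + 10007 * size + 101 * replicate) mod (2^31 - 1)`, so the whole
#' table is bit-reproducible from `seed` alone and replicates are mutually
#' independent. Sizes exceeding the pool are skipped with a warning.
#'
#' @param reads reads tibble (the pool).
#' @param truth truth sequence (string or tibble row).
#' @param sizes subsample sizes (default `c(30, 100, 300, 1000)`).
#' @param replicates replicates per size (default 3).
#' @param seed base seed (default 1).
#' @param params an [assembly_params()] list.
#' @param primers optional primer pair for trimming.
#' @return a tibble of class `nanobar_subsample`: `size`, `replicate`,
#'   `percent_identity`, `support`.
#' @export
subsample_experiment <- function(reads, truth, sizes = c(30L, 100L, 300L, 1000L),
                                 replicates = 3L, seed = 1L,
                                 params = assembly_params(), primers = NULL) {
  t_ <- as_seq(truth, "truth")
  if (!nzchar(t_)) abort("truth sequence is required")
  stopifnot(all(diff(sizes) > 0), replicates >= 1)
  rows <- list()
  for (size in sizes) {
    if (size > nrow(reads)) {
      warn(sprintf("subsample size %d exceeds pool size %d; skipped",
                   size, nrow(reads)))
      next
    }
    for (rep_i in seq_len(replicates)) {
      s <- (seed + 10007L * as.integer(size) + 101L * rep_i) %% 2147483647L
      idx <- withr::with_seed(s, sample.int(nrow(reads), size))
      sub <- reads[idx, , drop = FALSE]
      res <- consensus_denovo(sub, params, primers = primers)
      acc <- global_identity(res$contig, t_)
      rows[[length(rows) + 1L]] <- tibble(
        size = as.integer(size), replicate = rep_i,
        percent_identity = acc$percent_identity,
        support = res$contig$support)
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(size = integer(0), replicate = integer(0),
           percent_identity = numeric(0), support = integer(0))
  class(out) <- c("nanobar_subsample", class(out))
  out
}

#' Compare the de novo and reference-guided consensi against the truth
#'
#' @param denovo,refbased contigs (or strings) from the two strategies.
#' @param truth truth sequence.
#' @return a list of class `nanobar_compare`: `denovo` and `refbased`
#'   accuracy reports and `delta`, the signed identity difference
#'   (de novo minus reference-guided, percentage points).
#' @export
compare_strategies <- function(denovo, refbased, truth) {
  a <- global_identity(denovo, truth)
  b <- global_identity(refbased, truth)
  structure(list(denovo = a, refbased = b,
                 delta = a$percent_identity - b$percent_identity),
            class = "nanobar_compare")
}

#' @export
print.nanobar_compare <- function(x, ...) {
  cat(sprintf(
    "de novo %.1f%% vs reference-guided %.1f%% (delta %+.1f points)\n",
    x$denovo$percent_identity, x$refbased$percent_identity, x$delta))
  invisible(x)
}
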