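# Read simulator: nanopore-like amplicon reads with an indel-dominated,
# homopolymer-biased error model, plus whole-run simulation with the junk
# classes seen in field data (adapter-only concatemers, random and
# cross-locus contaminants, positive-control reads).

#' Nanopore-like error model
#'
#' Per-base substitution/insertion/deletion probabilities, a multiplicative
#' deletion boost inside homopolymer runs of length >= 3, and the phred
#' quality distribution assigned to simulated bases. The defaults (3% / 3% /
#' 5% with a 2x homopolymer deletion boost, ~11% total error) approximate
#' R9-era nanopore amplicon reads; qualities are decorative (mean 14, sd 3)
#' and deliberately independent of the planted errors.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities.
#' @param hp_del_boost multiplier on `del_rate` inside homopolymer runs >= 3.
#' @param qual_mean,qual_sd phred quality distribution (clipped to 2..40).
#' @return a list of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.03, del_rate = 0.05,
                        hp_del_boost = 2.0, qual_mean = 14, qual_sd = 3) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate < 1, ins_rate < 1, del_rate < 1,
            sub_rate + ins_rate + del_rate < 0.5, hp_del_boost >= 0)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, hp_del_boost = hp_del_boost,
                 qual_mean = qual_mean, qual_sd = qual_sd),
            class = "error_model")
}

# per-position deletion probability, boosted inside runs >= 3
del_prob_vector <- function(chars, model) {
  r <- rle(chars)
  in_run <- rep(r$lengths >= 3L, r$lengths)
  ifelse(in_run, pmin(model$del_rate * model$hp_del_boost, 0.95),
         model$del_rate)
}

#' Simulate one read from a truth sequence
#'
#' Walks the truth emitting substitutions, insertions and deletions at the
#' model's rates (deletions boosted inside homopolymer runs of length >= 3),
#' optionally flips the read to the reverse complement, and assigns per-base
#' qualities drawn from the model's normal distribution, clipped to 2..40.
#' Uses the caller's RNG stream: seed outside (e.g. `withr::with_seed()`).
#'
#' @param truth nucleotide string (nonempty).
#' @param model an [error_model()].
#' @param reverse_prob probability of emitting the reverse complement
#'   (default 0).
#' @return a list `seq`, `qual` (integer vector), `strand`; attribute `ops`
#'   holds the realised operation counts
#'   (`sub`, `ins`, `del`, `del_hp`, `bases_hp`) for rate diagnostics.
#' @export
simulate_read <- function(truth, model = error_model(), reverse_prob = 0) {
  truth <- as_seq(truth, "truth")
  chars <- strsplit(truth, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pdel <- del_prob_vector(chars, model)
  r <- rle(chars)
  in_hp <- rep(r$lengths >= 3L, r$lengths)
  del <- runif(n) < pdel
  sub <- !del & runif(n) < model$sub_rate
  ins <- runif(n) < model$ins_rate
  out <- chars
  if (any(sub)) {
    # substitute with one of the three other bases, uniformly
    out[sub] <- vapply(chars[sub], function(b) {
      sample(setdiff(.BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  out[del] <- ""
  if (any(ins)) {
    wi <- which(ins)
    out[wi] <- paste0(out[wi], sample(.BASES, length(wi), replace = TRUE))
  }
  seq <- paste(out, collapse = "")
  strand <- "+"
  if (reverse_prob > 0 && runif(1) < reverse_prob) {
    seq <- revcomp(seq)
    strand <- "-"
  }
  len <- nchar(seq)
  qual <- as.integer(pmin(40, pmax(2, round(rnorm(len, model$qual_mean,
                                                  model$qual_sd)))))
  structure(list(seq = seq, qual = qual, strand = strand),
            ops = c(sub = sum(sub), ins = sum(ins), del = sum(del),
                    del_hp = sum(del & in_hp), bases_hp = sum(in_hp)))
}

# deterministic synthetic positive-control sequence (kit-control stand-in)
control_sequence <- function() {
  withr::with_seed(80423, random_seq(700))
}

#' Simulate a multiplexed sequencing run
#'
#' Generates barcode- and primer-flanked reads for each locus at its
#' configured count, plus three junk classes at the requested fractions of
#' the *total* output: adapter-only reads (1-3 concatenated copies of
#' flank+barcode, the failed-ligation artifact), contaminants (alternating
#' uniform-random sequences and cross-locus reads carrying the wrong
#' barcode, when more than one locus exists), and positive-control reads (a
#' fixed synthetic control insert behind a random barcode). Category counts
#' are apportioned deterministically (largest remainder), every read's
#' origin is recorded in a truth table, and the whole run is a pure function
#' of `seed`.
#'
#' A locus read is built as
#' `flank + barcode + primer_f + insert + revcomp(primer_r)` and then passed
#' through [simulate_read()], so barcodes and primers are subject to the
#' same errors as the insert.
#'
#' @param loci tibble with columns `locus`, `seq` (insert truth),
#'   `barcode_id`, `n_reads`. Locus labels must be unique.
#' @param model an [error_model()].
#' @param barcodes barcode tibble (must cover all `barcode_id`s).
#' @param primers primer pair list (`primer_f`, `primer_r`).
#' @param adapter_only_fraction,contaminant_fraction,control_fraction
#'   fractions of the total read output (must sum to < 1).
#' @param reverse_prob probability a read is emitted reverse-complemented.
#' @param seed integer seed; same seed, same run, byte for byte.
#' @return a list of class `nanobar_run`: `reads` (tibble `id`, `seq`,
#'   `qual`), `truth` (tibble `read_id`, `category`, `locus`, `barcode_id`,
#'   `strand`), plus the `loci`, `barcodes`, `primers`, `model`, `seed`
#'   used.
#' @seealso [write_run()]
#' @export
simulate_run <- function(loci, model = error_model(),
                         barcodes = example_barcodes(),
                         primers = example_primers(),
                         adapter_only_fraction = 0,
                         contaminant_fraction = 0,
                         control_fraction = 0,
                         reverse_prob = 0.5, seed = 1L) {
  if (anyDuplicated(loci$locus)) abort("duplicate locus labels")
  if (!all(loci$barcode_id %in% barcodes$barcode_id)) {
    abort("loci reference barcodes missing from the barcode set")
  }
  fr <- c(adapter = adapter_only_fraction, contaminant = contaminant_fraction,
          control = control_fraction)
  if (any(fr < 0) || sum(fr) >= 1) abort("junk fractions must sum to < 1")
  n_locus <- sum(loci$n_reads)
  total <- as.integer(round(n_locus / (1 - sum(fr))))
  junk <- largest_remainder(total - n_locus, fr)
  names(junk) <- names(fr)

  withr::with_seed(seed, {
    seqs <- character(0); quals <- list(); strands <- character(0)
    cats <- character(0); locs <- character(0); bcs <- character(0)
    emit <- function(template, category, locus, bc_id) {
      r <- simulate_read(template, model, reverse_prob)
      i <- length(seqs) + 1L
      seqs[i] <<- r$seq; quals[[i]] <<- r$qual; strands[i] <<- r$strand
      cats[i] <<- category; locs[i] <<- locus; bcs[i] <<- bc_id
    }
    for (li in seq_len(nrow(loci))) {
      bc <- barcodes[barcodes$barcode_id == loci$barcode_id[li], ]
      template <- paste0(bc$flank, bc$seq, primers$primer_f,
                         toupper(loci$seq[li]), revcomp(primers$primer_r))
      for (k in seq_len(loci$n_reads[li])) {
        emit(template, "locus", loci$locus[li], bc$barcode_id)
      }
    }
    ctrl <- control_sequence()
    for (k in seq_len(junk[["adapter"]])) {
      bc <- barcodes[sample.int(nrow(barcodes), 1L), ]
      copies <- sample(1:3, 1L)
      emit(strrep(paste0(bc$flank, bc$seq), copies), "adapter_only",
           NA_character_, bc$barcode_id)
    }
    for (k in seq_len(junk[["contaminant"]])) {
      if (nrow(loci) > 1 && k %% 2 == 0) {
        # cross-locus contamination: insert of one locus, barcode of another
        src <- sample.int(nrow(loci), 1L)
        other <- sample(setdiff(seq_len(nrow(loci)), src), 1L)
        bc <- barcodes[barcodes$barcode_id == loci$barcode_id[other], ]
        emit(paste0(bc$flank, bc$seq, primers$primer_f,
                    toupper(loci$seq[src]), revcomp(primers$primer_r)),
             "contaminant", loci$locus[src], bc$barcode_id)
      } else {
        emit(random_seq(sample(300:900, 1L)), "contaminant",
             NA_character_, NA_character_)
      }
    }
    for (k in seq_len(junk[["control"]])) {
      bc <- barcodes[sample.int(nrow(barcodes), 1L), ]
      emit(paste0(bc$flank, bc$seq, ctrl), "control", NA_character_,
           bc$barcode_id)
    }
    ids <- sprintf("read%06d", seq_along(seqs))
    structure(list(
      reads = tibble(id = ids, seq = seqs, qual = quals),
      truth = tibble(read_id = ids, category = cats, locus = locs,
                     barcode_id = bcs, strand = strands),
      loci = loci, barcodes = barcodes, primers = primers,
      model = model, seed = seed),
      class = "nanobar_run")
  })
}

#' @export
print.nanobar_run <- function(x, ...) {
  cat(sprintf("<simulated run> %d reads, %d loci, seed %d\n",
              nrow(x$reads), nrow(x$loci), x$seed))
  print(dplyr::count(x$truth, .data$category))
  invisible(x)
}

#' Write a simulated run to disk
#'
#' Emits `reads.fastq` (multiplexed, phred+33), `truth.tsv` (per-read
#' origin: `read_id`, `category`, `locus`, `barcode_id`, `strand`) and
#' `truth.fasta` (the locus truth sequences) under `dir`.
#'
#' @param run a `nanobar_run` from [simulate_run()].
#' @param dir output directory (created if needed).
#' @param gzip compress the FASTQ (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(run$reads, file.path(dir, if (gzip) "reads.fastq.gz" else "reads.fastq"))
  readr::write_tsv(run$truth, file.path(dir, "truth.tsv"))
  write_fasta(tibble(id = run$loci$locus, seq = run$loci$seq),
              file.path(dir, "truth.fasta"))
  invisible(dir)
}
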