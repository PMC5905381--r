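# Whole-workflow orchestration: demux -> filter -> consensus (de novo and/or
# reference-guided) -> polish -> trim -> evaluate, with a per-barcode report.

#' Run the full barcoding workflow
#'
#' Executes, per barcode: demultiplexing, adapter-only exclusion,
#' quality/length filtering, consensus building by the requested strategy
#' (de novo, reference-guided, or both), polishing, primer trimming, and --
#' when truth sequences are supplied -- accuracy evaluation. The per-barcode
#' report reconciles exactly: `reads_in = adapter_only + kept + dropped_q +
#' dropped_len`, and `sum(reads_in) + unassigned = total reads`.
#'
#' @param config a named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{reads / fastq}{a reads tibble, a `nanobar_run`, or a FASTQ path.}
#'     \item{barcodes}{barcode tibble or FASTA/TSV path.}
#'     \item{primers}{optional primer pair list or FASTA path (records
#'       `primer_f`, `primer_r`).}
#'     \item{reference}{reference sequence(s) for the reference-guided
#'       strategy: tibble (`id`, `seq`), string, or FASTA path.}
#'     \item{truth}{optional truth sequences, same forms; each contig is
#'       scored against its best-matching truth.}
#'     \item{strategy}{`"denovo"` (default), `"refmap"`, or `"both"`.}
#'     \item{min_mean_q, min_length}{filter thresholds (defaults 13, 200).}
#'     \item{max_edits, window}{demultiplexing parameters.}
#'     \item{assembly}{list passed to [assembly_params()].}
#'     \item{out_dir}{optional output directory for artifacts
#'       (per-barcode FASTQ, `unassigned.fastq`, `assignments.tsv`,
#'       consensus FASTA, `report.tsv`, `report.json`).}
#'   }
#' @return the report tibble (one row per barcode with assigned reads):
#'   `barcode`, `reads_in`, `adapter_only`, `kept`, `dropped_q`,
#'   `dropped_len`, `contig_support`, `consensus_length`, plus
#'   `identity_denovo` / `identity_refmap` / `delta` columns as applicable.
#'   Attributes: `unassigned` (count), `assignments`, `contigs` (named list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  strategy <- cfg$strategy %||% "denovo"
  if (!strategy %in% c("denovo", "refmap", "both")) {
    abort("strategy must be one of 'denovo', 'refmap', 'both'")
  }
  reads <- cfg$reads %||% cfg$fastq
  if (is.null(reads)) abort("config error: no reads/fastq given")
  if (inherits(reads, "nanobar_run")) reads <- reads$reads
  if (is.character(reads)) reads <- read_fastq(reads)
  if (nrow(reads) == 0) abort("config error: empty read set")
  barcodes <- cfg$barcodes
  if (is.null(barcodes)) abort("config error: no barcodes given")
  if (is.character(barcodes)) barcodes <- read_barcodes(barcodes)
  validate_barcodes(barcodes)
  primers <- cfg$primers
  if (is.character(primers)) {
    fa <- read_fasta(primers)
    primers <- list(primer_f = fa$seq[match("primer_f", fa$id)],
                    primer_r = fa$seq[match("primer_r", fa$id)])
  }
  as_seq_tbl <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1 && file.exists(x)) return(read_fasta(x))
    if (is.character(x)) return(tibble(id = what, seq = toupper(x)))
    if (inherits(x, "data.frame")) return(tibble(id = as.character(x$id %||% x$locus),
                                                 seq = toupper(x$seq)))
    abort(sprintf("config error: cannot interpret %s", what))
  }
  reference <- as_seq_tbl(cfg$reference, "reference")
  truth <- as_seq_tbl(cfg$truth, "truth")
  if (strategy %in% c("refmap", "both") && is.null(reference)) {
    abort("config error: strategy 'refmap' requires a reference")
  }
  params <- do.call(assembly_params, cfg$assembly %||% list())
  min_mean_q <- cfg$min_mean_q %||% 13
  min_length <- cfg$min_length %||% 200

  asg <- demultiplex(reads, barcodes, max_edits = cfg$max_edits,
                     window = cfg$window %||% 150L)
  unassigned_n <- sum(asg$barcode_id == "unassigned")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  best_truth <- function(contig) {
    accs <- lapply(seq_len(nrow(truth)), function(i)
      global_identity(contig, truth$seq[i]))
    accs[[which.max(vapply(accs, function(a) a$percent_identity, numeric(1)))]]
  }

  rows <- list(); contigs <- list()
  for (bc in unique(asg$barcode_id[asg$barcode_id != "unassigned"])) {
    sel <- asg$barcode_id == bc
    rd <- reads[match(asg$read_id[sel], reads$id), , drop = FALSE]
    adapter_only <- isTRUE_vec(asg$adapter_only[sel])
    n_in <- nrow(rd)
    rd_real <- rd[!adapter_only, , drop = FALSE]
    kept <- filter_reads(rd_real, min_mean_q, min_length)
    st <- filter_stats(kept)
    row <- tibble(barcode = bc, reads_in = n_in,
                  adapter_only = sum(adapter_only),
                  kept = st$kept, dropped_q = st$dropped_q,
                  dropped_len = st$dropped_len)
    row$contig_support <- NA_integer_
    row$consensus_length <- NA_integer_
    dn <- rf <- NULL
    if (st$kept >= 1 && strategy %in% c("denovo", "both")) {
      dn <- try(consensus_denovo(kept, params, primers = primers), silent = TRUE)
      if (inherits(dn, "try-error")) dn <- NULL
    }
    if (st$kept >= 2 && strategy %in% c("refmap", "both")) {
      ref <- reference[1, ]
      if (!is.null(reference$id) && bc %in% reference$id) {
        ref <- reference[reference$id == bc, ]
      }
      rf <- try(refguided_pipeline(kept, ref, params), silent = TRUE)
      if (inherits(rf, "try-error")) rf <- NULL
      if (!is.null(rf) && !is.null(primers)) {
        rf$contig <- trim_consensus(rf$contig, primers)
      }
    }
    main <- if (!is.null(dn)) dn$contig else if (!is.null(rf)) rf$contig else NULL
    if (!is.null(main)) {
      row$contig_support <- main$support
      row$consensus_length <- nchar(main$seq)
      contigs[[bc]] <- main
    }
    if (!is.null(truth)) {
      row$identity_denovo <- if (is.null(dn)) NA_real_ else
        best_truth(dn$contig)$percent_identity
      row$identity_refmap <- if (is.null(rf)) NA_real_ else
        best_truth(rf$contig)$percent_identity
      if (strategy == "both") {
        row$delta <- row$identity_denovo - row$identity_refmap
      }
    }
    rows[[length(rows) + 1L]] <- row
    if (!is.null(out_dir)) {
      write_fastq(rd, file.path(out_dir, paste0(bc, ".fastq")))
    }
  }
  report <- if (length(rows)) bind_rows(rows) else
    tibble(barcode = character(0), reads_in = integer(0),
           adapter_only = integer(0), kept = integer(0),
           dropped_q = integer(0), dropped_len = integer(0),
           contig_support = integer(0), consensus_length = integer(0))
  report <- arrange(report, desc(.data$reads_in), .data$barcode)
  if (!is.null(out_dir)) {
    write_fastq(reads[match(asg$read_id[asg$barcode_id == "unassigned"],
                            reads$id), , drop = FALSE],
                file.path(out_dir, "unassigned.fastq"))
    readr::write_tsv(asg, file.path(out_dir, "assignments.tsv"))
    if (length(contigs)) {
      ctg <- contigs
      for (nm in names(ctg)) ctg[[nm]]$locus_label <- nm
      write_contigs(unname(ctg), file.path(out_dir, "consensus.fasta"))
    }
    readr::write_tsv(report, file.path(out_dir, "report.tsv"))
    jsonlite::write_json(list(seed = cfg$seed, unassigned = unassigned_n,
                              report = report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(report, "unassigned") <- unassigned_n
  attr(report, "assignments") <- asg
  attr(report, "contigs") <- contigs
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

isTRUE_vec <- function(x) !is.na(x) & x
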