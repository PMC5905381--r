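bcs <- example_barcodes(4)

test_that("barcodes are located exactly at read ends on both strands", {
  insert <- random_locus(500, seed = 10)
  a <- locate_barcode(paste0(bcs$seq[1], insert), bcs, max_edits = 3)
  expect_equal(a$barcode_id, "BC01")
  expect_equal(a$strand, "+")
  expect_equal(a$edits, 0L)

  rc_read <- revcomp(paste0(bcs$seq[2], insert))
  a <- locate_barcode(rc_read, bcs)
  expect_equal(a$barcode_id, "BC02")
  expect_equal(a$strand, "-")
  expect_equal(a$edits, 0L)

  expect_error(locate_barcode("ACGT", bcs[0, ]), "empty")
})

test_that("substituted barcodes are found with the edit distance the oracle computes", {
  insert <- random_locus(400, seed = 11)
  b <- strsplit(bcs$seq[1], "")[[1]]
  b[3] <- setdiff(c("A", "C", "G", "T"), b[3])[1]
  b[17] <- setdiff(c("A", "C", "G", "T"), b[17])[1]
  read <- paste0(paste(b, collapse = ""), insert)
  a <- locate_barcode(read, bcs, max_edits = 3)
  expect_equal(a$barcode_id, "BC01")
  expect_equal(a$edits, 2L)
  expect_equal(oracle_semiglobal_edits(bcs$seq[1], substr(read, 1, 150)), 2L)
})

test_that("uniform-random reads stay unassigned and the oracle agrees", {
  read <- random_locus(500, seed = 12)
  a <- locate_barcode(read, bcs, max_edits = 3)
  expect_equal(a$barcode_id, "unassigned")
  expect_true(is.na(a$edits))
  # exhaustive check: every barcode, both strands, both windows, distance > 3
  for (b in c(bcs$seq, revcomp(bcs$seq))) {
    expect_gt(oracle_semiglobal_edits(b, substr(read, 1, 150)), 3)
    expect_gt(oracle_semiglobal_edits(b, substr(read, 351, 500)), 3)
  }
})

test_that("adapter-only reads are flagged by coverage of adapter hits", {
  unit <- paste0(bcs$flank[1], bcs$seq[1])
  junk <- strrep(unit, 2)
  cl <- classify_adapter_only(junk, bcs)
  expect_true(cl$adapter_only)
  expect_gt(cl$covered_fraction, 0.95)

  amplicon <- paste0(unit, random_locus(560, seed = 13))
  cl <- classify_adapter_only(amplicon, bcs)
  expect_false(cl$adapter_only)
  expect_lt(abs(cl$covered_fraction -
                oracle_coverage(nchar(amplicon), 1, nchar(unit))), 0.02)

  # ~50% covered: two adapter units around a random core of equal length
  half <- paste0(unit, random_locus(2 * nchar(unit), seed = 14), unit)
  cl <- classify_adapter_only(half, bcs, min_fraction = 0.8)
  expect_false(cl$adapter_only)
  expect_equal(cl$covered_fraction, 0.5, tolerance = 0.05)
  # monotone in min_fraction: raising the threshold can only turn true->false
  expect_true(classify_adapter_only(half, bcs, min_fraction = 0.4)$adapter_only)
})

test_that("the quality/length filter applies strict thresholds and reconciles", {
  reads <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c(random_locus(500, 1), random_locus(150, 2), random_locus(500, 3)),
    qual = list(rep(20L, 500), rep(20L, 150), rep(10L, 500)))
  out <- filter_reads(reads)
  expect_equal(out$id, "a")
  expect_equal(filter_stats(out),
               tibble::tibble(kept = 1L, dropped_q = 1L, dropped_len = 1L))

  # mean quality exactly at the threshold is dropped (strict >)
  q13 <- tibble::tibble(id = "x", seq = random_locus(300, 4),
                        qual = list(rep(13L, 300)))
  expect_equal(nrow(filter_reads(q13)), 0L)
  # as is length exactly at the threshold
  l200 <- make_reads(random_locus(200, 5))
  expect_equal(nrow(filter_reads(l200)), 0L)

  empty <- filter_reads(reads[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(unlist(filter_stats(empty)), c(kept = 0L, dropped_q = 0L,
                                              dropped_len = 0L))

  # idempotent, and output is a subsequence of input
  twice <- filter_reads(filter_reads(reads))
  expect_equal(twice$id, out$id)
  expect_true(all(out$id %in% reads$id))
})

test_that("demultiplexing a simulated run recovers labels without mis-assignment", {
  loci <- tibble::tibble(
    locus = sprintf("L%02d", 1:12),
    seq = vapply(1:12, function(i) random_locus(300, seed = 100 + i), character(1)),
    barcode_id = sprintf("BC%02d", 1:12),
    n_reads = 25L)
  model <- error_model(sub_rate = 0.02, ins_rate = 0.01, del_rate = 0.02)
  run <- simulate_run(loci, model = model, seed = 5)
  asg <- demultiplex(run$reads, run$barcodes, classify_adapter = FALSE)
  joined <- merge(asg, run$truth, by = "read_id")
  assigned <- joined$barcode_id.x != "unassigned"
  expect_gt(mean(assigned), 0.95)
  expect_equal(sum(joined$barcode_id.x[assigned] != joined$barcode_id.y[assigned]), 0L)
  # simulator orientation is recovered too
  expect_equal(sum(joined$strand.x[assigned] != joined$strand.y[assigned]), 0L)
})

test_that("unassigned reads are rescued by mapping back to the consensi", {
  consA <- random_locus(500, seed = 20)
  consB <- random_locus(500, seed = 21)
  model <- error_model()
  sim <- withr::with_seed(22, lapply(1:10, function(i) simulate_read(consA, model)))
  noise <- withr::with_seed(23, lapply(1:5, function(i) list(seq = random_locus(500))))
  reads <- make_reads(vapply(c(sim, noise), function(x) x$seq, character(1)))
  res <- rescue_unassigned(reads, tibble::tibble(id = c("A", "B"),
                                                 seq = c(consA, consB)))
  expect_equal(res$counts$n_rescued[res$counts$consensus_id == "A"], 10L)
  expect_equal(res$counts$n_rescued[res$counts$consensus_id == "B"], 0L)
  expect_equal(res$total_rescued, 10L)

  none <- rescue_unassigned(reads[0, ], tibble::tibble(id = "A", seq = consA))
  expect_equal(sum(none$counts$n_rescued), 0L)

  exact <- rescue_unassigned(make_reads(consA),
                             tibble::tibble(id = "A", seq = consA))
  expect_equal(exact$assignments$identity, 1)
  expect_error(rescue_unassigned(reads, tibble::tibble(id = character(0),
                                                       seq = character(0))),
               "nonempty")
})
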