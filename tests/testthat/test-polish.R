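test_that("polishing a correct draft with clean reads changes nothing", {
  truth <- random_locus(400, seed = 90)
  reads <- make_reads(rep(truth, 10))
  res <- polish_consensus(truth, reads)
  expect_equal(res$contig$seq, truth)
  expect_equal(res$report$changes_per_round, 0L)
  expect_equal(res$report$final_mapped, 10L)
  expect_equal(res$report$mean_depth, 10)
})

test_that("majority voting repairs substituted and corrupted drafts", {
  truth <- random_locus(500, seed = 91)
  corrupt <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), n)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  draft <- withr::with_seed(92, corrupt(truth, 5))
  res <- polish_consensus(draft, make_reads(rep(truth, 40)))
  expect_equal(res$contig$seq, truth)

  # 5% of sites corrupted, depth 100 of error-free reads: fully repaired
  draft25 <- withr::with_seed(93, corrupt(truth, 25))
  res <- polish_consensus(draft25, make_reads(rep(truth, 100)))
  expect_equal(res$contig$seq, truth)
})

test_that("homopolymer run lengths are restored by run-length voting", {
  base <- random_locus(200, seed = 94)
  truth <- paste0(substr(base, 1, 100), "CCCCCC", substr(base, 101, 200))
  draft <- paste0(substr(base, 1, 100), "CCCCC", substr(base, 101, 200))
  model <- error_model()
  reads <- withr::with_seed(95, make_reads(vapply(1:100, function(i)
    simulate_read(truth, model)$seq, character(1))))
  res <- polish_consensus(draft, reads)
  acc <- global_identity(res$contig, truth)
  # the 6-mer is restored in its flanking context
  expect_true(grepl(paste0(substr(base, 96, 100), "CCCCCC",
                           substr(base, 101, 105)),
                    res$contig$seq, fixed = TRUE))
  expect_gte(acc$percent_identity, 99.5)
})

test_that("run-length adjudication follows the stated mode and tie rules", {
  expect_equal(homopolymer_adjudicate(c(`6` = 70, `5` = 30)), 6L)
  expect_equal(homopolymer_adjudicate(c(`5` = 50, `6` = 50)), 6L)
  expect_equal(homopolymer_adjudicate(c(`4` = 1)), 4L)
  expect_equal(homopolymer_adjudicate(rep(c(6L, 5L), c(7, 3))), 6L)
  # strict mode at margin 1 (no deletion-bias correction)
  expect_equal(homopolymer_adjudicate(c(`5` = 60, `6` = 40), bias_margin = 1), 5L)
  # the default margin forgives a small under-called excess
  expect_equal(homopolymer_adjudicate(c(`5` = 55, `6` = 45)), 6L)
  expect_error(homopolymer_adjudicate(integer(0)), "observations")
})

test_that("unmapped read sets leave the draft unchanged with a warning", {
  draft <- random_locus(300, seed = 96)
  junk <- make_reads(vapply(1:4, function(i)
    random_locus(300, seed = 960 + i), character(1)))
  expect_warning(res <- polish_consensus(draft, junk), "no reads map")
  expect_equal(res$contig$seq, draft)
  expect_equal(res$report$rounds, 0L)
})

test_that("changes per round never increase on simulated fixtures", {
  truth <- random_locus(400, seed = 97)
  model <- error_model()
  for (sd in 1:5) {
    reads <- withr::with_seed(sd, make_reads(vapply(1:25, function(i)
      simulate_read(truth, model)$seq, character(1))))
    draft <- build_consensus(reads)
    res <- polish_consensus(draft, reads)
    expect_true(all(diff(res$report$changes_per_round) <= 0))
  }
})

test_that("coverage accounting separates total from aligned depth", {
  truth <- random_locus(300, seed = 98)
  good <- rep(truth, 10)
  junk <- vapply(1:5, function(i) random_locus(300, seed = 980 + i),
                 character(1))
  res <- polish_consensus(truth, make_reads(c(good, junk)))
  # total depth counts junk bases; mean depth only the mapped pileup
  expect_equal(res$report$total_depth, 15 * 300 / nchar(res$contig$seq))
  expect_equal(res$report$mean_depth, 10)
  expect_equal(res$report$final_mapped, 10L)
})

test_that("primer trimming recovers the insert from flanked consensi", {
  primers <- example_primers()
  bcs <- example_barcodes(1)
  insert <- random_locus(450, seed = 99)
  full <- paste0(bcs$flank[1], bcs$seq[1], primers$primer_f, insert,
                 revcomp(primers$primer_r), "ACGTAC")
  out <- trim_consensus(full, primers)
  expect_equal(out$seq, insert)
  expect_true(attr(out, "trimmed"))

  # reverse-complemented consensus trims too
  out <- trim_consensus(revcomp(full), primers)
  expect_equal(out$seq, insert)

  # two errors in the forward primer still trim
  pf <- strsplit(primers$primer_f, "")[[1]]
  pf[3] <- setdiff(c("A", "C", "G", "T"), pf[3])[1]
  pf[10] <- setdiff(c("A", "C", "G", "T"), pf[10])[1]
  noisy <- paste0(paste(pf, collapse = ""), insert,
                  revcomp(primers$primer_r))
  out <- trim_consensus(noisy, primers)
  expect_equal(out$seq, insert)
  expect_equal(oracle_semiglobal_edits(primers$primer_f,
                                       substr(noisy, 1, 40)), 2L)

  # an already-trimmed consensus comes back unchanged with the warning flag
  out <- trim_consensus(insert, primers)
  expect_equal(out$seq, insert)
  expect_true(attr(out, "trim_warning"))
})
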