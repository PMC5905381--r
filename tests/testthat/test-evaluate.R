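test_that("identity reports count matches and indel columns over the truth", {
  truth <- random_locus(500, seed = 100)
  acc <- global_identity(truth, truth)
  expect_equal(acc$percent_identity, 100)
  expect_equal(acc$matches, 500L)
  expect_equal(acc$aligned_columns, 500L)
  expect_equal(nrow(acc$diffs), 0L)

  # one deletion in 500 truth columns: 99.8% by the columns convention
  del1 <- paste0(substr(truth, 1, 249), substr(truth, 251, 500))
  acc <- global_identity(del1, truth)
  expect_equal(acc$percent_identity, 100 * 499 / 500)
  expect_equal(acc$deletions, 1L)
  expect_equal(acc$substitutions + acc$insertions, 0L)
  # the score agrees with an independent pairwise aligner
  a <- nanobar:::align_pair(del1, truth, free_q = TRUE, free_r = FALSE)
  expect_equal(a$score, oracle_accuracy_score(del1, truth))

  # a 4 bp deletion is one event of 4 columns
  del4 <- paste0(substr(truth, 1, 249), substr(truth, 254, 500))
  acc <- global_identity(del4, truth)
  expect_equal(acc$deletions, 4L)
  ev <- acc$diffs[acc$diffs$type == "deletion", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(nchar(ev$truth), 4L)
  expect_equal(acc$percent_identity, 100 * 496 / 500)

  # residual flanks on the query are soft-clipped, not penalised
  flanked <- paste0("AACCGGTTAACC", truth, "GGTTAACCGGTT")
  expect_equal(global_identity(flanked, truth)$percent_identity, 100)
})

test_that("identity is symmetric for full-length substitution differences", {
  withr::with_seed(101, {
    for (i in 1:5) {
      a <- random_locus(200)
      ch <- strsplit(a, "")[[1]]
      pos <- sample(5:195, 4)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      b <- paste(ch, collapse = "")
      expect_equal(global_identity(a, b)$percent_identity,
                   global_identity(b, a)$percent_identity)
    }
  })
})

test_that("error bookkeeping identity holds on random sequence pairs", {
  withr::with_seed(102, {
    for (i in 1:20) {
      q <- random_locus(sample(50:300, 1))
      t_ <- random_locus(sample(50:300, 1))
      acc <- global_identity(q, t_)
      expect_equal(acc$matches + acc$substitutions + acc$insertions +
                   acc$deletions, acc$aligned_columns)
      expect_equal(acc$percent_identity,
                   100 * acc$matches / acc$aligned_columns)
    }
  })
})

test_that("indels in homopolymer context are classified as such", {
  truth <- paste0("GCGTACGTAC", "AAAAA", "GTCAGCGTGC", "CGCATT")
  # delete one A of the AAAAA run
  q_del <- sub("AAAAA", "AAAA", truth)
  acc <- classify_errors(global_identity(q_del, truth), truth)
  expect_equal(acc$homopolymer_indels, 1L)
  expect_true(acc$diffs$homopolymer[acc$diffs$type == "deletion"])

  # a substitution in mixed context is never a homopolymer error
  q_sub <- sub("GTCAGC", "GTGAGC", truth)
  acc <- classify_errors(global_identity(q_sub, truth), truth)
  expect_equal(acc$homopolymer_indels, 0L)
  expect_false(any(acc$diffs$homopolymer[acc$diffs$type == "substitution"]))

  # a deletion in mixed context is an indel but not homopolymer-flagged
  q_mix <- sub("GTCAGC", "GTCGC", truth)
  acc <- classify_errors(global_identity(q_mix, truth), truth)
  expect_equal(acc$homopolymer_indels, 0L)

  perfect <- classify_errors(global_identity(truth, truth), truth)
  expect_equal(perfect$homopolymer_indels, 0L)
  expect_equal(nrow(perfect$diffs), 0L)

  # the count is bounded by the indel columns
  expect_lte(acc$homopolymer_indels, acc$insertions + acc$deletions)
})

test_that("the subsampling experiment is reproducible and reports all cells", {
  truth <- random_locus(300, seed = 103)
  model <- error_model()
  pool <- withr::with_seed(104, make_reads(vapply(1:60, function(i)
    simulate_read(truth, model)$seq, character(1))))
  tab <- subsample_experiment(pool, truth, sizes = c(10, 25), replicates = 3,
                              seed = 7)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$size, rep(c(10L, 25L), each = 3))
  expect_equal(tab$replicate, rep(1:3, 2))
  expect_true(all(tab$percent_identity > 90))
  expect_true(all(tab$support <= tab$size))

  # bit-reproducible from the seed
  tab2 <- subsample_experiment(pool, truth, sizes = c(10, 25), replicates = 3,
                               seed = 7)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  # sizes beyond the pool are skipped with a warning
  expect_warning(small <- subsample_experiment(pool, truth,
                                               sizes = c(10, 1000),
                                               replicates = 1, seed = 7),
                 "exceeds pool")
  expect_equal(unique(small$size), 10L)
  expect_error(subsample_experiment(pool, "", sizes = 10), "truth")
})

test_that("strategy comparison reports the signed identity difference", {
  truth <- random_locus(500, seed = 105)
  cmp <- compare_strategies(truth, truth, truth)
  expect_equal(cmp$delta, 0)

  # de novo with one substitution against a perfect reference consensus
  dn <- truth
  substr(dn, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                  substr(truth, 100, 100))[1]
  cmp <- compare_strategies(dn, truth, truth)
  expect_equal(cmp$delta, -100 * 1 / 500)
  expect_equal(cmp$denovo$substitutions, 1L)
})
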