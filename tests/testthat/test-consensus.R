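test_that("pairwise overlaps respect the span and identity thresholds", {
  r <- random_locus(300, seed = 30)
  ov <- pairwise_overlap(r, r)
  expect_equal(ov$length, 300L)
  expect_equal(ov$identity, 1)
  expect_equal(ov$orientation, "+")

  # reverse-complement orientation is detected
  ov <- pairwise_overlap(r, revcomp(r))
  expect_equal(ov$orientation, "-")
  expect_equal(ov$identity, 1)

  # exact 50 bp suffix/prefix overlap sits exactly at the boundary
  shared <- random_locus(50, seed = 31)
  a <- paste0(random_locus(250, seed = 32), shared)
  b <- paste0(shared, random_locus(250, seed = 33))
  ov <- pairwise_overlap(a, b)
  expect_false(is.null(ov))
  expect_equal(ov$length, 50L)

  # one base fewer and the overlap is not reported
  a49 <- paste0(random_locus(250, seed = 32), substr(shared, 1, 49))
  b49 <- paste0(substr(shared, 1, 49), random_locus(250, seed = 34))
  expect_null(pairwise_overlap(a49, b49))

  # unrelated reads share nothing
  expect_null(pairwise_overlap(random_locus(300, seed = 35),
                               random_locus(300, seed = 36)))
})

test_that("overlap clustering separates loci and tolerates read noise", {
  x <- random_locus(400, seed = 40)
  y <- random_locus(400, seed = 41)
  reads <- make_reads(c(rep(x, 10), rep(y, 10)))
  cl <- cluster_reads(reads)
  expect_equal(max(cl$cluster), 2L)
  expect_equal(as.integer(table(cl$cluster)), c(10L, 10L))
  byc <- split(cl$read_id, cl$cluster)
  expect_true(all(byc[[1]] %in% reads$id[1:10]) ||
              all(byc[[1]] %in% reads$id[11:20]))

  one <- cluster_reads(make_reads(rep(x, 10)))
  expect_equal(max(one$cluster), 1L)

  # 5% per-base error, n = 30: at least 29 reads land in the main cluster
  model <- error_model(sub_rate = 0.02, ins_rate = 0.01, del_rate = 0.02)
  noisy <- withr::with_seed(42, vapply(1:30, function(i)
    simulate_read(x, model)$seq, character(1)))
  cln <- cluster_reads(make_reads(noisy))
  expect_gte(sum(cln$cluster == 1), 29L)
})

test_that("center-star consensus reproduces clean and noisy truths", {
  x <- random_locus(240, seed = 50)
  ctg <- build_consensus(make_reads(rep(x, 3)))
  expect_equal(ctg$seq, x)
  expect_equal(ctg$support, 3L)

  one <- build_consensus(make_reads(x))
  expect_equal(one$seq, x)
  expect_equal(one$support, 1L)

  # error-free homogeneous input gives the truth exactly at any depth,
  # also with mixed orientations
  for (n in c(2, 6)) {
    mixed <- withr::with_seed(51, ifelse(runif(n) < 0.5, x, revcomp(x)))
    expect_equal(build_consensus(make_reads(c(x, mixed)))$seq, x)
  }

  # 5% error, n = 30 reads: draft identity at least 99%
  model <- error_model(sub_rate = 0.02, ins_rate = 0.01, del_rate = 0.02)
  truth <- random_locus(500, seed = 52)
  noisy <- withr::with_seed(53, vapply(1:30, function(i)
    simulate_read(truth, model)$seq, character(1)))
  acc <- global_identity(build_consensus(make_reads(noisy)), truth)
  expect_gte(acc$percent_identity, 99)
})

test_that("consensus identity improves as the error rate drops", {
  truth <- random_locus(400, seed = 54)
  mean_id <- vapply(c(0.12, 0.06, 0.01), function(r) {
    ids <- vapply(1:3, function(sd) {
      model <- error_model(sub_rate = r * 3 / 11, ins_rate = r * 3 / 11,
                           del_rate = r * 5 / 11)
      reads <- withr::with_seed(sd, vapply(1:30, function(i)
        simulate_read(truth, model)$seq, character(1)))
      res <- polish_consensus(build_consensus(make_reads(reads)),
                              make_reads(reads))
      global_identity(res$contig, truth)$percent_identity
    }, numeric(1))
    mean(ids)
  }, numeric(1))
  expect_true(all(diff(mean_id) >= 0))
})

test_that("column majority consensus agrees with brute-force MSA oracles", {
  # substitutions only: the optimal MSA is gapless, so the brute-force
  # consensus is the per-position majority of the raw strings
  withr::with_seed(55, {
    for (rep_i in 1:5) {
      center <- random_locus(25)
      reads <- vapply(1:5, function(i) {
        ch <- strsplit(center, "")[[1]]
        flip <- sample(3:23, 2) # interior flips: edge mismatches would be
        for (p in flip) {       # soft-clipped by the free-end alignment
          ch[p] <- sample(c("A", "C", "G", "T"), 1)
        }
        paste(ch, collapse = "")
      }, character(1))
      expected <- {
        m <- do.call(rbind, strsplit(reads, ""))
        paste(apply(m, 2, function(col) {
          tb <- table(factor(col, levels = c("A", "C", "G", "T")))
          names(tb)[which.max(tb)] # first max: A<C<G<T precedence
        }), collapse = "")
      }
      expect_equal(build_consensus(make_reads(reads))$seq, expected)
    }
  })

  # a deletion case against the exhaustive 3-sequence alignment oracle
  s <- "ACGTTGCAAGCT"
  s_del <- "ACGTTGAAGCT" # C deleted
  expect_equal(build_consensus(make_reads(c(s, s, s_del)))$seq,
               oracle_msa3_consensus(s, s, s_del))
  # and an insertion case
  s_ins <- "ACGTTGCGAAGCT" # G inserted
  expect_equal(build_consensus(make_reads(c(s, s_ins, s)))$seq,
               oracle_msa3_consensus(s, s_ins, s))
})

test_that("the best contig is picked by support, then length, then sequence", {
  c55 <- new_contig(random_locus(500, seed = 60), 55L)
  c3 <- new_contig(random_locus(500, seed = 61), 3L)
  expect_identical(select_best_contig(list(c3, c55)), c55)

  t500 <- new_contig(random_locus(500, seed = 62), 10L)
  t480 <- new_contig(random_locus(480, seed = 63), 10L)
  expect_identical(select_best_contig(list(t480, t500)), t500)

  expect_identical(select_best_contig(list(c3)), c3)
  expect_error(select_best_contig(list()), "no contigs")
})

test_that("multiplexed read sets assemble into one contig per locus", {
  x <- random_locus(350, seed = 70)
  y <- random_locus(500, seed = 71)
  model <- error_model()
  reads <- withr::with_seed(72, make_reads(c(
    vapply(1:20, function(i) simulate_read(x, model)$seq, character(1)),
    vapply(1:12, function(i) simulate_read(y, model)$seq, character(1)))))
  ctgs <- assemble_multiplexed(reads, n_loci = 2)
  expect_length(ctgs, 2)
  expect_equal(ctgs[[1]]$support, 20L)
  expect_equal(ctgs[[2]]$support, 12L)
  # drafts only (unpolished): identity is high but not final
  expect_gte(global_identity(ctgs[[1]], x)$percent_identity, 95)
  expect_gte(global_identity(ctgs[[2]], y)$percent_identity, 95)

  expect_warning(one <- assemble_multiplexed(make_reads(rep(x, 5)), n_loci = 2),
                 "1 cluster")
  expect_length(one, 1)
  expect_error(assemble_multiplexed(make_reads(character(0))), "empty")
})
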