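# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's own alignment code paths:
# base R adist(), Biostrings::pairwiseAlignment(), and small brute-force
# dynamic programs written directly from the definitions.

# reads tibble from bare sequences, constant quality
make_reads <- function(seqs, qual = 20L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  tibble::tibble(id = ids, seq = seqs,
                 qual = lapply(nchar(seqs), function(n) rep(as.integer(qual), n)))
}

# brute-force semi-global edit distance: minimum Levenshtein distance of
# `pattern` against any substring of `text` (O(m^2) adist calls)
oracle_semiglobal_edits <- function(pattern, text) {
  m <- nchar(text)
  best <- nchar(pattern)
  for (i in seq_len(m)) {
    for (j in i:min(m, i + 2L * nchar(pattern))) {
      d <- utils::adist(pattern, substr(text, i, j))[1, 1]
      if (d < best) best <- d
    }
  }
  best
}

# Biostrings score oracle for the accuracy alignment: query ends free,
# truth global, match +1 / mismatch -1 / gap of length L costs 2 + L
oracle_accuracy_score <- function(query, truth) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(truth),
    type = "local-global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1, scoreOnly = TRUE)
}

# exhaustive optimal 3-sequence multiple alignment (sum-of-pairs score,
# match +1 / mismatch -1 / gap -1, gap-gap 0) returning the column-majority
# consensus; feasible for sequences up to ~12 bp
oracle_msa3_consensus <- function(s1, s2, s3) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]; c_ <- strsplit(s3, "")[[1]]
  n1 <- length(a); n2 <- length(b); n3 <- length(c_)
  sc <- function(x, y) {
    if (is.na(x) && is.na(y)) 0 else if (is.na(x) || is.na(y)) -1 else
      if (x == y) 1 else -1
  }
  D <- array(-Inf, dim = c(n1 + 1, n2 + 1, n3 + 1))
  P <- array(0L, dim = c(n1 + 1, n2 + 1, n3 + 1)) # move index 1..7
  D[1, 1, 1] <- 0
  moves <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, ]
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0) next
    best <- -Inf; arg <- 0L
    for (m in seq_len(nrow(moves))) {
      di <- moves[m, 1]; dj <- moves[m, 2]; dk <- moves[m, 3]
      pi <- i - di; pj <- j - dj; pk <- k - dk
      if (pi < 0 || pj < 0 || pk < 0) next
      x <- if (di) a[i] else NA; y <- if (dj) b[j] else NA
      z <- if (dk) c_[k] else NA
      v <- D[pi + 1, pj + 1, pk + 1] + sc(x, y) + sc(x, z) + sc(y, z)
      if (v > best) { best <- v; arg <- m }
    }
    D[i + 1, j + 1, k + 1] <- best
    P[i + 1, j + 1, k + 1] <- arg
  }
  # traceback, then column majority (ties: base order, gap loses)
  i <- n1; j <- n2; k <- n3
  cons <- character(0)
  while (i + j + k > 0) {
    m <- P[i + 1, j + 1, k + 1]
    di <- moves[m, 1]; dj <- moves[m, 2]; dk <- moves[m, 3]
    col <- c(if (di) a[i] else NA, if (dj) b[j] else NA, if (dk) c_[k] else NA)
    col <- col[!is.na(col)]
    tb <- sort(table(factor(col, levels = c("A", "C", "G", "T"))),
               decreasing = TRUE)
    cons <- c(if (tb[1] >= 3 - length(col)) names(tb)[1] else character(0), cons)
    i <- i - di; j <- j - dj; k <- k - dk
  }
  paste(cons, collapse = "")
}

# independent interval-coverage oracle: fraction of 1..len covered by hits
oracle_coverage <- function(len, starts, ends) {
  covered <- logical(len)
  for (i in seq_along(starts)) {
    covered[seq(starts[i], ends[i])] <- TRUE
  }
  mean(covered)
}
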