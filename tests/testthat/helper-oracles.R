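## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (and Biostrings) so they can arbitrate.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Global-alignment identity by dynamic programming: maximize the number of
## identical aligned positions (match 1, mismatch 0, gaps free); among
## equally matching alignments maximize the number of paired columns, which
## minimizes the alignment length L1 + L2 - pairs. Identity = matches /
## alignment length. Pure R, quadratic; for short test sequences only.
nwIdentityOracle <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  M <- matrix(0L, n + 1L, m + 1L)  # best match count
  P <- matrix(0L, n + 1L, m + 1L)  # best paired-column count given M
  for (i in seq_len(n)) {
    Mi <- M[i, ]; Pi <- P[i, ]          # row i-1 (1-based offset)
    Mrow <- integer(m + 1L); Prow <- integer(m + 1L)
    for (j in seq_len(m)) {
      dm <- Mi[j] + (x[i] == y[j]); dp <- Pi[j] + 1L   # diagonal
      um <- Mi[j + 1L]; up <- Pi[j + 1L]               # gap in y
      lm <- Mrow[j];    lp <- Prow[j]                  # gap in x
      bm <- dm; bp <- dp
      if (um > bm || (um == bm && up > bp)) { bm <- um; bp <- up }
      if (lm > bm || (lm == bm && lp > bp)) { bm <- lm; bp <- lp }
      Mrow[j + 1L] <- bm; Prow[j + 1L] <- bp
    }
    M[i + 1L, ] <- Mrow; P[i + 1L, ] <- Prow
  }
  M[n + 1L, m + 1L] / (n + m - P[n + 1L, m + 1L])
}

## Greedy longest-first clustering recomputed from an all-pairs identity
## matrix produced by the DP oracle (same visiting rule the package
## documents: length descending, ties by id in C-locale order).
greedyKeepOracle <- function(seqs, ids, threshold, identityFun = nwIdentityOracle) {
  visit <- order(-nchar(seqs), ids, method = "radix")
  kept <- integer(0)
  for (i in visit) {
    if (!any(vapply(kept, function(j) identityFun(seqs[i], seqs[j]) > threshold,
                    logical(1))))
      kept <- c(kept, i)
  }
  sort(kept)
}

## Brute-force per-example confusion recount.
bruteConfusion <- function(true, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(true)) {
    if (true[i] > 0 && pred[i] > 0) tp <- tp + 1L
    else if (true[i] < 0 && pred[i] < 0) tn <- tn + 1L
    else if (true[i] < 0 && pred[i] > 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

## Random standard-residue sequence (test data only).
randomProtein <- function(L) {
  paste(sample(AA_LETTERS, L, replace = TRUE), collapse = "")
}

## Tiny labelled feature fixture shared by model/evaluation tests: two
## compositionally distinct classes, AAC-encoded.
makeSyntheticAAC <- function(nPos = 20, nNeg = 20, len = c(80, 120), seed = 1) {
  sim <- simulateProteins(nPos = nPos, nNeg = nNeg, lengthRange = len,
                          seed = seed)
  list(features = encodeAAC(sim$dataset), labels = labels(sim$dataset),
       dataset = sim$dataset)
}
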