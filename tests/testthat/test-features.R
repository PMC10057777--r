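canonical <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

test_that("AAC matches hand and brute-force counting and sums to one", {
  d <- ProteinDataset(c(h = "AAAA", s = "ACAC"))
  m <- featureMatrix(encodeAAC(d))
  expect_identical(colnames(m), canonical)
  expect_equal(m["h", ], setNames(c(1, rep(0, 19)), canonical))
  expect_equal(unname(m["s", c("A", "C")]), c(0.5, 0.5))

  set.seed(41)
  s <- randomProtein(200)
  v <- featureMatrix(encodeAAC(ProteinDataset(c(r = s))))[1, ]
  counts <- table(factor(strsplit(s, "")[[1]], levels = canonical))
  expect_equal(v, setNames(as.numeric(counts) / 200, canonical))
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("DPC counts overlapping dipeptides over L-1 and sums to one", {
  d <- ProteinDataset(c(s = "ACAC", h = "AAAAAA"))
  m <- featureMatrix(encodeDPC(d))
  expect_identical(ncol(m), 400L)
  expect_equal(unname(m["s", c("AC", "CA")]), c(2 / 3, 1 / 3))
  expect_equal(sum(m["s", ]), 1, tolerance = 1e-9)
  expect_equal(unname(m["h", "AA"]), 1)

  ## brute-force sliding-window oracle on a random 100-mer
  set.seed(42)
  s <- randomProtein(100)
  v <- featureMatrix(encodeDPC(ProteinDataset(c(r = s))))[1, ]
  ch <- strsplit(s, "")[[1]]
  dip <- paste0(ch[-100], ch[-1])
  expected <- setNames(numeric(400), names(v))
  for (dp in dip) expected[dp] <- expected[dp] + 1 / 99
  expect_equal(v, expected, tolerance = 1e-12)

  expect_error(encodeDPC(ProteinDataset(c(x = "A"))), "length < 2")
})

test_that("hybrid is the 420-component concatenation of AAC and DPC", {
  set.seed(43)
  d <- ProteinDataset(setNames(vapply(rep(60, 5), randomProtein, character(1)),
                               paste0("p", 1:5)))
  h <- featureMatrix(encodeHybrid(d))
  expect_identical(ncol(h), 420L)
  expect_equal(h[, 1:20], featureMatrix(encodeAAC(d)))
  expect_equal(h[, 21:420], featureMatrix(encodeDPC(d)))

  hs <- featureMatrix(encodeHybrid(ProteinDataset(c(s = "ACAC"))))[1, ]
  expect_equal(unname(hs[1]), 0.5)            # A of AAC
  expect_equal(unname(hs[20 + 2]), 2 / 3)     # AC of DPC block
})

test_that("AAC is shuffle-invariant but DPC is not", {
  set.seed(44)
  s <- randomProtein(150)
  shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  a1 <- featureMatrix(encodeAAC(ProteinDataset(c(x = s))))[1, ]
  a2 <- featureMatrix(encodeAAC(ProteinDataset(c(x = shuf))))[1, ]
  expect_equal(a1, a2)
  d1 <- featureMatrix(encodeDPC(ProteinDataset(c(x = s))))[1, ]
  d2 <- featureMatrix(encodeDPC(ProteinDataset(c(x = shuf))))[1, ]
  expect_false(isTRUE(all.equal(d1, d2)))
})

test_that("composition sums hold across many random sequences", {
  set.seed(45)
  seqs <- vapply(sample(10:200, 300, replace = TRUE), randomProtein,
                 character(1))
  d <- ProteinDataset(setNames(seqs, paste0("q", seq_along(seqs))))
  expect_true(all(abs(rowSums(featureMatrix(encodeAAC(d))) - 1) < 1e-9))
  expect_true(all(abs(rowSums(featureMatrix(encodeDPC(d))) - 1) < 1e-9))
})

test_that("encodeDataset dispatches schemes and reports missing PSSM files", {
  sim <- simulateProteins(nPos = 5, nNeg = 5, lengthRange = c(50, 80),
                          seed = 46)
  d <- sim$dataset
  expect_identical(dim(featureMatrix(encodeDataset(d, "AAC"))), c(10L, 20L))
  expect_identical(dim(featureMatrix(encodeDataset(d, "hybrid"))), c(10L, 420L))
  td <- withr::local_tempdir()
  simulatePSSMFixtures(d, td, seed = 47)
  file.remove(file.path(td, paste0(ids(d)[3], ".pssm")))
  expect_error(encodeDataset(d, "PSSM", pssmDir = td), ids(d)[3])
  expect_error(encodeDataset(d, "PSSM"), "pssmDir")
})
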