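canonical <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

test_that("readPSSM parses the ASCII dialect and flags malformed rows", {
  f <- system.file("extdata", "example_synthetic.pssm", package = "aromapred")
  p <- readPSSM(f)
  expect_s4_class(p, "PSSMProfile")
  expect_identical(dim(p@profile), c(6L, 20L))
  expect_identical(nchar(p@sequence), 6L)
  expect_identical(p@residueOrder[1:4], c("A", "R", "N", "D"))

  lines <- readLines(f)
  bad <- withr::local_tempfile(fileext = ".pssm")
  truncated <- lines
  truncated[6] <- substr(truncated[6], 1, 40)  # cut row 3 short
  writeLines(truncated, bad)
  expect_error(readPSSM(bad), "line 6")

  noninteger <- lines
  tok <- strsplit(trimws(noninteger[5]), "\\s+")[[1]]
  tok[7] <- "x"  # corrupt one score cell of row 2
  noninteger[5] <- paste(tok, collapse = " ")
  writeLines(noninteger, bad)
  expect_error(readPSSM(bad), "line 5")

  writeLines(c("no", "pssm", "here"), bad)
  expect_error(readPSSM(bad), "column header")
})

test_that("PSSM write/parse round-trips synthetic profiles", {
  sim <- simulateProteins(nPos = 3, nNeg = 3, lengthRange = c(30, 50),
                          seed = 51)
  td <- withr::local_tempdir()
  simulatePSSMFixtures(sim$dataset, td, seed = 52)
  for (id in ids(sim$dataset)) {
    p <- readPSSM(file.path(td, paste0(id, ".pssm")))
    expect_identical(p@sequence,
                     as.character(sequences(sim$dataset))[[id]])
    f2 <- file.path(td, "rt.pssm")
    writePSSM(p, f2)
    p2 <- readPSSM(f2)
    expect_identical(p2@profile, p@profile)
    expect_identical(p2@sequence, p@sequence)
  }
  ## fixed seed regenerates byte-identical files
  td2 <- withr::local_tempdir()
  simulatePSSMFixtures(sim$dataset, td2, seed = 52)
  id1 <- ids(sim$dataset)[1]
  expect_identical(readLines(file.path(td2, paste0(id1, ".pssm"))),
                   readLines(file.path(td, paste0(id1, ".pssm"))))
})

test_that("normalizePSSM min-max scales over all cells", {
  p <- PSSMProfile("MK", rbind(c(-3, rep(0, 19)), c(5, rep(0, 19))))
  n <- normalizePSSM(p)
  ## cells {-3, 0, 5} -> {0, 0.375, 1}
  expect_equal(unname(n@profile[1, 1]), 0)
  expect_equal(unname(n@profile[2, 1]), 1)
  expect_equal(unname(n@profile[1, 2]), 0.375)
  expect_equal(min(n@profile), 0)
  expect_equal(max(n@profile), 1)

  const <- normalizePSSM(PSSMProfile("MK", matrix(7, 2, 20)))
  expect_true(all(const@profile == 0))
})

test_that("pssmComposition aggregates rows per sequence residue over L", {
  ## homopolymer with all scores 1: A-row all 1, everything else 0
  p <- PSSMProfile("AAAA", matrix(1, 4, 20), normalized = TRUE)
  v <- pssmComposition(p)
  expect_identical(length(v), 400L)
  arow <- v[startsWith(names(v), "A|")]
  expect_true(all(arow == 1))
  expect_true(all(v[!startsWith(names(v), "A|")] == 0))

  ## independent double-loop accumulation on a 30-position random profile
  set.seed(53)
  s <- randomProtein(30)
  m <- matrix(runif(30 * 20), 30, 20)
  order20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  v <- pssmComposition(PSSMProfile(s, m, residueOrder = order20,
                                   normalized = TRUE))
  res <- strsplit(s, "")[[1]]
  expected <- setNames(numeric(400), names(v))
  for (i in canonical) for (j in canonical) {
    acc <- 0
    for (pth in which(res == i)) acc <- acc + m[pth, match(j, order20)]
    expected[paste(i, j, sep = "|")] <- acc / 30
  }
  expect_equal(v, expected, tolerance = 1e-12)

  ## components are bounded by the residue frequency
  freq <- table(factor(res, levels = canonical)) / 30
  for (i in canonical)
    expect_true(all(v[startsWith(names(v), paste0(i, "|"))] <=
                      as.numeric(freq[i]) + 1e-12))

  expect_error(pssmComposition(PSSMProfile("MK", matrix(3, 2, 20))),
               "normalized")
})

test_that("uniformly-scored profiles reduce pssm composition to scaled AAC", {
  set.seed(54)
  s <- randomProtein(80)
  cval <- 0.6
  p <- PSSMProfile(s, matrix(cval, 80, 20), normalized = TRUE)
  v <- pssmComposition(p)
  aac <- featureMatrix(encodeAAC(ProteinDataset(c(x = s))))[1, ]
  for (i in canonical)
    expect_equal(unname(v[paste(i, i, sep = "|")]), unname(cval * aac[i]),
                 tolerance = 1e-12)
})
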