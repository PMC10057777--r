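#' Default residue-weight profile of the positive class
#'
#' Weight multipliers over a uniform background emulating the composition
#' signature of aromatase-like sequences: leucine strongly enriched
#' (observed above 10% in curated aromatase sets), F/P/S/V moderately
#' enriched (above 6%), C and W depleted (below 2%); all other residues at
#' background weight 1.
#'
#' @return named numeric vector of 20 positive weights.
#' @export
defaultPositiveBias <- function() {
    w <- setNames(rep(1, 20L), AA20)
    w["L"] <- 2.0
    w[c("F", "P", "S", "V")] <- 1.5
    w[c("C", "W")] <- 0.3
    w
}

.residueProbs <- function(bias) {
    w <- setNames(rep(1, 20L), AA20)
    if (!is.null(bias)) {
        if (is.null(names(bias)) || !all(names(bias) %in% AA20))
            stop("bias weights must be named by standard residue letters")
        if (any(bias <= 0)) stop("bias weights must be strictly positive")
        w[names(bias)] <- bias
    }
    w / sum(w)
}

#' Simulate a labelled two-class protein dataset
#'
#' Draws `nPos` positive and `nNeg` negative sequences residue-i.i.d. from
#' two residue-frequency profiles: the positive profile applies
#' `posBias` weight multipliers to a uniform background (default:
#' [defaultPositiveBias]), the negative profile applies `negBias` (default:
#' none, i.e. uniform). Sequence lengths are uniform on `lengthRange`. The
#' run is fully reproducible from `seed`. No positional structure is
#' simulated: the generator exercises composition-based encoders, not real
#' protein grammar.
#'
#' @param nPos,nNeg class sizes (>= 1).
#' @param lengthRange integer (min, max) sequence length, min >= 2.
#' @param posBias,negBias named residue weight multipliers (see
#'   [defaultPositiveBias]); `NULL` means uniform.
#' @param seed RNG seed.
#' @return list with `dataset` (a labelled [ProteinDataset-class]; ids
#'   `POS_0001`..., `NEG_0001`...) and `truth` (list with the exact
#'   generating residue probabilities and a per-record table).
#' @examples
#' sim <- simulateProteins(nPos = 5, nNeg = 5, lengthRange = c(60, 80),
#'                         seed = 7)
#' sim$dataset
#' @export
simulateProteins <- function(nPos = 100L, nNeg = 100L,
                             lengthRange = c(100L, 500L),
                             posBias = defaultPositiveBias(),
                             negBias = NULL, seed = 42L) {
    if (nPos < 1L || nNeg < 1L)
        stop("'nPos' and 'nNeg' must be positive")
    if (length(lengthRange) != 2L || lengthRange[1L] < 2L ||
        lengthRange[2L] < lengthRange[1L])
        stop("'lengthRange' must be (min, max) with min >= 2")
    p_pos <- .residueProbs(posBias)
    p_neg <- .residueProbs(negBias)
    withSeed(seed, {
        draw <- function(n, prefix, probs) {
            ## sample() treats a length-1 vector as 1:x; guard min == max
            lens <- seq(lengthRange[1L], lengthRange[2L])
            len <- if (length(lens) == 1L) rep(lens, n)
                   else sample(lens, n, replace = TRUE)
            seqs <- vapply(len, function(L)
                paste(sample(AA20, L, replace = TRUE, prob = probs),
                      collapse = ""), character(1))
            names(seqs) <- sprintf("%s_%04d", prefix, seq_len(n))
            seqs
        }
        pos <- draw(nPos, "POS", p_pos)
        neg <- draw(nNeg, "NEG", p_neg)
    })
    ds <- ProteinDataset(c(pos, neg),
                         description = c(rep("synthetic positive-class sequence", nPos),
                                         rep("synthetic background sequence", nNeg)),
                         label = c(rep(1L, nPos), rep(-1L, nNeg)),
                         provenance = sprintf(
                             "simulateProteins(nPos=%d, nNeg=%d, length=%d-%d, seed=%d)",
                             nPos, nNeg, lengthRange[1L], lengthRange[2L], seed),
                         clean = FALSE)
    truth <- list(posProbs = p_pos, negProbs = p_neg, seed = seed,
                  records = data.frame(id = ids(ds), label = labels(ds),
                                       length = Biostrings::width(sequences(ds)),
                                       stringsAsFactors = FALSE))
    list(dataset = ds, truth = truth)
}

#' Append mutated near-duplicate records
#'
#' Picks `nPairs` records at random and appends a copy of each with
#' per-residue substitution probability `mutationRate` (substitutions go to
#' a random different residue). Copies get the suffix `_dup`. At low
#' mutation rates (<= 0.05) the expected identity of a copy to its source
#' exceeds 90%, making these fixtures for redundancy reduction.
#'
#' @param dataset a [ProteinDataset-class].
#' @param nPairs number of records to duplicate (<= number of records).
#' @param mutationRate substitution probability in [0, 0.5).
#' @param seed RNG seed.
#' @return the dataset with `nPairs` mutated copies appended.
#' @export
addRedundantPairs <- function(dataset, nPairs, mutationRate = 0.02,
                              seed = 1L) {
    stopifnot(is(dataset, "ProteinDataset"))
    if (nPairs > length(dataset))
        stop("'nPairs' exceeds the dataset size")
    if (mutationRate < 0 || mutationRate >= 0.5)
        stop("'mutationRate' must be in [0, 0.5)")
    seqs <- as.character(sequences(dataset))
    withSeed(seed, {
        pick <- sample.int(length(dataset), nPairs)
        dup <- vapply(seqs[pick], function(s) {
            r <- strsplit(s, "", fixed = TRUE)[[1L]]
            hit <- runif(length(r)) < mutationRate
            if (any(hit))
                r[hit] <- vapply(r[hit], function(orig)
                    sample(setdiff(AA20, orig), 1L), character(1))
            paste(r, collapse = "")
        }, character(1))
    })
    ProteinDataset(c(seqs, dup),
                   ids = c(ids(dataset), paste0(ids(dataset)[pick], "_dup")),
                   description = c(descriptions(dataset),
                                   paste0(descriptions(dataset)[pick],
                                          " [mutated copy]")),
                   label = c(labels(dataset), labels(dataset)[pick]),
                   provenance = paste0(provenance(dataset),
                                       sprintf(" | +%d mutated duplicates (rate %g, seed %d)",
                                               nPairs, mutationRate, seed)),
                   clean = FALSE)
}

#' Write synthetic PSSM fixture files for a dataset
#'
#' For every record writes `<id>.pssm` in the ASCII PSSM dialect read by
#' [readPSSM]: at each position the column matching the sequence residue
#' receives a high integer score (uniform on 4..9) and the remaining
#' columns low scores (uniform on -4..2), so the profiles carry the same
#' class-correlated composition signal as the sequences. Deterministic
#' given `seed`.
#'
#' @param dataset a non-empty [ProteinDataset-class].
#' @param outDir output directory (created if needed).
#' @param seed RNG seed.
#' @return `outDir`, invisibly.
#' @export
simulatePSSMFixtures <- function(dataset, outDir, seed = 1L) {
    stopifnot(is(dataset, "ProteinDataset"))
    if (length(dataset) == 0L) stop("empty dataset")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seqs <- as.character(sequences(dataset))
    withSeed(seed, {
        for (i in seq_along(seqs)) {
            res <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
            L <- length(res)
            m <- matrix(sample(-4:2, L * 20L, replace = TRUE), L, 20L,
                        dimnames = list(NULL, PSSM_COLUMN_ORDER))
            m[cbind(seq_len(L), match(res, PSSM_COLUMN_ORDER))] <-
                sample(4:9, L, replace = TRUE)
            writePSSM(PSSMProfile(seqs[i], m),
                      file.path(outDir, paste0(ids(dataset)[i], ".pssm")))
        }
    })
    invisible(outDir)
}
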