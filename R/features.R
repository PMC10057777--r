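## Composition encoders. Canonical residue order for every scheme is the
## alphabetical one-letter order A,C,D,...,Y (AA20); PSSM file columns are
## remapped to this order at composition time.

.dipeptideNames <- function() {
    as.vector(t(outer(AA20, AA20, paste0)))  # AA, AC, ..., YY (first residue slowest)
}

#' Amino-acid composition (AAC) of protein sequences
#'
#' Encodes each sequence as the 20-vector of residue frequencies
#' (count of residue i divided by sequence length), in canonical
#' alphabetical residue order. Components sum to 1.
#'
#' @param x a [ProteinDataset-class].
#' @return a [FeatureSet-class] with scheme `"AAC"` (n x 20).
#' @examples
#' fs <- encodeAAC(ProteinDataset(c(p = "ACAC")))
#' featureMatrix(fs)[, c("A", "C")]
#' @export
encodeAAC <- function(x) {
    stopifnot(is(x, "ProteinDataset"))
    if (length(x) == 0L) stop("empty dataset")
    counts <- Biostrings::letterFrequency(sequences(x), letters = AA20)
    mat <- counts / Biostrings::width(sequences(x))
    dimnames(mat) <- list(ids(x), AA20)
    FeatureSet(mat, "AAC")
}

#' Dipeptide composition (DPC) of protein sequences
#'
#' Encodes each sequence as the 400-vector of overlapping dipeptide
#' frequencies: the count of each ordered residue pair divided by the
#' number of overlapping dipeptides, L - 1. Components are indexed
#' (first residue, second residue) in canonical order and sum to 1.
#'
#' @param x a [ProteinDataset-class]; every sequence must have length >= 2.
#' @return a [FeatureSet-class] with scheme `"DPC"` (n x 400).
#' @export
encodeDPC <- function(x) {
    stopifnot(is(x, "ProteinDataset"))
    if (length(x) == 0L) stop("empty dataset")
    w <- Biostrings::width(sequences(x))
    if (any(w < 2L))
        stop("sequence length < 2 (no dipeptides) for: ",
             paste(ids(x)[w < 2L], collapse = ", "))
    seqs <- as.character(sequences(x))
    mat <- t(vapply(seqs, .dpcOne, numeric(400L)))
    dimnames(mat) <- list(ids(x), .dipeptideNames())
    FeatureSet(mat, "DPC")
}

.dpcOne <- function(s) {
    r <- match(strsplit(s, "", fixed = TRUE)[[1L]], AA20)
    L <- length(r)
    idx <- (r[-L] - 1L) * 20L + r[-1L]
    tabulate(idx, nbins = 400L) / (L - 1L)
}

#' Hybrid (AAC + DPC) composition
#'
#' Concatenates the amino-acid and dipeptide compositions into one
#' 420-dimensional vector per sequence: components 1-20 are the AAC,
#' components 21-420 the DPC.
#'
#' @param x a [ProteinDataset-class]; every sequence must have length >= 2.
#' @return a [FeatureSet-class] with scheme `"HYBRID"` (n x 420).
#' @export
encodeHybrid <- function(x) {
    aac <- featureMatrix(encodeAAC(x))
    dpc <- featureMatrix(encodeDPC(x))
    FeatureSet(cbind(aac, dpc), "HYBRID")
}

#' Min-max normalize a PSSM profile
#'
#' Rescales every cell by (value - min) / (max - min), with min and max
#' taken over all L x 20 cells of this profile. A constant matrix maps to
#' all zeros by convention.
#'
#' @param profile a [PSSMProfile-class].
#' @return the normalized [PSSMProfile-class] (values in [0, 1]).
#' @export
normalizePSSM <- function(profile) {
    stopifnot(is(profile, "PSSMProfile"))
    m <- profile@profile
    if (nrow(m) == 0L) stop("empty profile")
    lo <- min(m)
    hi <- max(m)
    m <- if (hi == lo) matrix(0, nrow(m), ncol(m),
                              dimnames = dimnames(m))
         else (m - lo) / (hi - lo)
    initialize(profile, profile = m, normalized = TRUE)
}

#' PSSM composition vector (400 dimensions)
#'
#' Aggregates a normalized profile into a fixed-length encoding indexed by
#' (sequence residue i, profile column j), both in canonical order: the sum
#' of normalized scores in column j over all positions whose sequence
#' residue is i, divided by the sequence length L. Residues absent from the
#' sequence contribute zero rows, so each component lies in
#' [0, frequency of residue i].
#'
#' @param profile a normalized [PSSMProfile-class] (all cells in [0, 1]).
#' @return named numeric vector of length 400 (names `"i|j"`).
#' @export
pssmComposition <- function(profile) {
    stopifnot(is(profile, "PSSMProfile"))
    m <- profile@profile
    if (min(m) < 0 || max(m) > 1)
        stop("profile must be normalized to [0, 1] first (see normalizePSSM)")
    m <- m[, AA20, drop = FALSE]  # remap file column order to canonical
    res <- strsplit(profile@sequence, "", fixed = TRUE)[[1L]]
    L <- length(res)
    out <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
    for (i in seq_along(AA20)) {
        rows <- which(res == AA20[i])
        if (length(rows))
            out[i, ] <- colSums(m[rows, , drop = FALSE]) / L
    }
    v <- as.vector(t(out))
    names(v) <- as.vector(t(outer(AA20, AA20, paste, sep = "|")))
    v
}

#' Encode a dataset under one feature scheme
#'
#' Dispatches to [encodeAAC], [encodeDPC], [encodeHybrid] or, for
#' `scheme = "PSSM"`, parses `<id>.pssm` files from `pssmDir`, min-max
#' normalizes each profile and computes its composition vector.
#'
#' @param x a [ProteinDataset-class].
#' @param scheme one of `"AAC"`, `"DPC"`, `"HYBRID"`, `"PSSM"`
#'   (case-insensitive).
#' @param pssmDir directory containing one `<id>.pssm` file per record
#'   (required for `scheme = "PSSM"`).
#' @return a [FeatureSet-class], one row per record, order preserved.
#' @export
encodeDataset <- function(x, scheme = c("AAC", "DPC", "HYBRID", "PSSM"),
                          pssmDir = NULL) {
    stopifnot(is(x, "ProteinDataset"))
    scheme <- match.arg(toupper(scheme), c("AAC", "DPC", "HYBRID", "PSSM"))
    if (scheme != "PSSM")
        return(switch(scheme,
                      AAC = encodeAAC(x),
                      DPC = encodeDPC(x),
                      HYBRID = encodeHybrid(x)))
    if (is.null(pssmDir))
        stop("scheme 'PSSM' requires 'pssmDir'")
    paths <- file.path(pssmDir, paste0(ids(x), ".pssm"))
    missing <- !file.exists(paths)
    if (any(missing))
        stop("missing PSSM file(s) for record(s): ",
             paste(ids(x)[missing], collapse = ", "))
    rows <- lapply(paths, function(p)
        pssmComposition(normalizePSSM(readPSSM(p))))
    mat <- do.call(rbind, rows)
    rownames(mat) <- ids(x)
    FeatureSet(mat, "PSSM")
}
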