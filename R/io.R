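#' Read a multi-record protein FASTA file
#'
#' Parses a FASTA file into a [ProteinDataset-class]. The header token before
#' the first whitespace becomes the record id; the remainder becomes the
#' description. Sequences are uppercased; letters outside the 20 standard
#' amino acids (ambiguity codes, gaps, stops) are removed with a warning, so
#' downstream composition denominators use the cleaned length. Wrapped and
#' unwrapped sequence lines are both accepted.
#'
#' @param path path to a FASTA file.
#' @param label optional class label (+1/-1) applied to every record.
#' @return a [ProteinDataset-class]; record order follows the file.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKL", ">b some description", "GG"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, label = NA) {
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stop("FASTA parse error in '", path,
                                             "': ", conditionMessage(e)))
    if (length(raw) == 0L)
        stop("no records in FASTA file: ", path)
    headers <- names(raw)
    id <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (any(!nzchar(id)))
        stop("record with empty id at entry ", which(!nzchar(id))[1L])
    if (anyDuplicated(id))
        stop("duplicate record id(s): ",
             paste(unique(id[duplicated(id)]), collapse = ", "))
    seqs <- as.character(raw)
    if (any(!nzchar(seqs)))
        stop("record(s) without sequence: ",
             paste(id[!nzchar(seqs)], collapse = ", "))
    ProteinDataset(seqs, ids = id, description = desc, label = label,
                   provenance = paste0("read_fasta:", path), clean = TRUE)
}

#' Write a ProteinDataset to FASTA
#'
#' Headers are `>id description` (no trailing space when the description is
#' empty); sequence lines wrap at 60 columns. `readFasta(writeFasta(d))`
#' reproduces ids, descriptions and sequences.
#'
#' @param dataset a non-empty [ProteinDataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(dataset, path) {
    stopifnot(is(dataset, "ProteinDataset"))
    if (length(dataset) == 0L)
        stop("cannot write an empty dataset")
    out <- sequences(dataset)
    hdr <- ids(dataset)
    has_desc <- nzchar(descriptions(dataset))
    hdr[has_desc] <- paste(hdr[has_desc], descriptions(dataset)[has_desc])
    names(out) <- hdr
    Biostrings::writeXStringSet(out, filepath = path, width = 60L)
    invisible(path)
}

#' Filter records by annotation keywords
#'
#' Removes records whose description contains any of the given keywords,
#' matched case-insensitively as substrings (so the singular form also
#' matches plurals). This mirrors the curation step of dropping UniProt
#' entries annotated as fragments, isoforms, potentials, similarity or
#' probables before training.
#'
#' @param dataset a [ProteinDataset-class].
#' @param keywords non-empty character vector of annotation words to exclude
#'   (default: `fragment`, `isoform`, `potential`, `similarity`, `probable`).
#' @return the retained records, input order preserved (possibly empty).
#' @examples
#' d <- ProteinDataset(c(a = "MKL", b = "MKV"),
#'                     description = c("Aromatase (Fragment)", "Aromatase"))
#' ids(filterAnnotations(d))
#' @export
filterAnnotations <- function(dataset,
                              keywords = c("fragment", "isoform", "potential",
                                           "similarity", "probable")) {
    stopifnot(is(dataset, "ProteinDataset"))
    if (length(keywords) == 0L || any(!nzchar(keywords)))
        stop("'keywords' must be a non-empty character vector")
    desc <- tolower(descriptions(dataset))
    hit <- Reduce(`|`, lapply(tolower(keywords), function(k)
        grepl(k, desc, fixed = TRUE)), accumulate = FALSE)
    out <- dataset[which(!hit)]
    out@provenance <- paste0(provenance(dataset), " | filter_annotations[",
                             paste(keywords, collapse = ","), "]: ",
                             length(dataset), " -> ", length(out))
    out
}

#' Global pairwise sequence identity
#'
#' Identity between two protein sequences under a global (Needleman-Wunsch)
#' alignment scored with match = 1, mismatch = 0 and zero gap penalties:
#' the number of identical aligned positions divided by the alignment length
#' (columns, gaps included).
#'
#' @param a,b protein sequence strings.
#' @return identity fraction in [0, 1].
#' @examples
#' pairwiseIdentity("MKLV", "MKIV")
#' @export
pairwiseIdentity <- function(a, b) {
    a <- as.character(a)
    b <- as.character(b)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(a), b,
        type = "global", substitutionMatrix = .identityMatrix(),
        gapOpening = 0, gapExtension = 0)
    ## alignment length = reported (terminal-gap-trimmed) length plus the
    ## unaligned overhangs of both sequences, so free end gaps still count
    p <- Biostrings::pattern(aln)
    s <- Biostrings::subject(aln)
    len <- Biostrings::nchar(aln) +
        (BiocGenerics::start(p) - 1L) + (nchar(a) - BiocGenerics::end(p)) +
        (BiocGenerics::start(s) - 1L) + (nchar(b) - BiocGenerics::end(s))
    Biostrings::nmatch(aln) / len
}

.identityMatrix <- local({
    m <- NULL
    function() {
        if (is.null(m)) {
            m <<- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
            diag(m) <<- 1
        }
        m
    }
})

#' Greedy redundancy reduction at an identity threshold
#'
#' A deterministic stand-in for CD-HIT-style clustering: records are visited
#' longest first (ties broken by id, C-locale lexicographic); a record is
#' kept iff its global pairwise identity (see [pairwiseIdentity]) to every
#' already-kept record is at most `identityThreshold`. Records more than
#' `identityThreshold` identical to a kept record are dropped.
#'
#' @param dataset a [ProteinDataset-class].
#' @param identityThreshold identity fraction in (0, 1]; default 0.90.
#' @return the kept records, in the input order of `dataset`.
#' @export
reduceRedundancy <- function(dataset, identityThreshold = 0.90) {
    stopifnot(is(dataset, "ProteinDataset"))
    if (!is.numeric(identityThreshold) || length(identityThreshold) != 1L ||
        is.na(identityThreshold) ||
        identityThreshold <= 0 || identityThreshold > 1)
        stop("'identityThreshold' must be a single number in (0, 1]")
    n <- length(dataset)
    if (n <= 1L) return(dataset)
    w <- Biostrings::width(sequences(dataset))
    id <- ids(dataset)
    visit <- order(-w, id, method = "radix")
    seqs <- as.character(sequences(dataset))
    kept <- integer(0)
    for (i in visit) {
        redundant <- FALSE
        for (j in kept) {
            if (pairwiseIdentity(seqs[i], seqs[j]) > identityThreshold) {
                redundant <- TRUE
                break
            }
        }
        if (!redundant) kept <- c(kept, i)
    }
    out <- dataset[sort(kept)]
    out@provenance <- paste0(provenance(dataset), " | reduce_redundancy[",
                             identityThreshold, "]: ", n, " -> ", length(out))
    out
}

#' Write labelled feature vectors in SVM-light sparse format
#'
#' One line per vector: `<label> <index>:<value> ...` with 1-based ascending
#' indices; zero-valued components are omitted (an all-zero vector yields a
#' label-only line). Values are printed with 6 significant digits.
#'
#' @param features a [FeatureSet-class] or numeric matrix (rows = vectors).
#' @param labs one label (+1/-1) per vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSvmLight <- function(features, labs, path) {
    mat <- if (is(features, "FeatureSet")) featureMatrix(features) else
        as.matrix(features)
    if (nrow(mat) != length(labs))
        stop(sprintf("have %d vectors but %d labels", nrow(mat), length(labs)))
    if (any(!labs %in% c(1, -1)))
        stop("labels must be +1 or -1")
    lines <- vapply(seq_len(nrow(mat)), function(i) {
        v <- mat[i, ]
        nz <- which(v != 0)
        lab <- if (labs[i] > 0) "+1" else "-1"
        if (length(nz) == 0L) return(lab)
        paste(lab, paste0(nz, ":", sprintf("%.6g", v[nz]), collapse = " "))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read an SVM-light sparse feature file
#'
#' Inverse of [writeSvmLight]. Component indices absent from a line are
#' zero; the vector dimension defaults to the largest index seen.
#'
#' @param path path to an SVM-light format file.
#' @param dim vector dimension; `NULL` (default) infers it from the file.
#' @return list with `values` (numeric matrix) and `labels` (+1/-1 vector).
#' @export
readSvmLight <- function(path, dim = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("no vectors in SVM-light file: ", path)
    parsed <- lapply(seq_along(lines), function(i) {
        tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        lab <- suppressWarnings(as.numeric(tok[1L]))
        if (is.na(lab) || !lab %in% c(1, -1))
            stop("bad label on line ", i, ": ", tok[1L])
        if (length(tok) == 1L)
            return(list(lab = lab, idx = integer(0), val = numeric(0)))
        kv <- strsplit(tok[-1L], ":", fixed = TRUE)
        idx <- as.integer(vapply(kv, `[`, character(1), 1L))
        val <- as.numeric(vapply(kv, `[`, character(1), 2L))
        if (any(is.na(idx)) || any(is.na(val)))
            stop("malformed index:value pair on line ", i)
        list(lab = lab, idx = idx, val = val)
    })
    d <- if (is.null(dim)) max(1L, unlist(lapply(parsed, `[[`, "idx"))) else dim
    mat <- matrix(0, nrow = length(parsed), ncol = d)
    for (i in seq_along(parsed))
        mat[i, parsed[[i]]$idx] <- parsed[[i]]$val
    list(values = mat, labels = vapply(parsed, `[[`, numeric(1), "lab"))
}
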