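#' @import methods
#' @importFrom Biostrings AAStringSet width readBStringSet writeXStringSet
#'   pairwiseAlignment nmatch letterFrequency pattern subject
#' @importFrom BiocGenerics start end
#' @importFrom stats predict runif setNames
#' @importFrom utils head modifyList write.table read.table packageVersion
NULL

## canonical residue order used by every composition encoder
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## column order emitted by PSI-BLAST -out_ascii_pssm
PSSM_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

FEATURE_DIMS <- c(AAC = 20L, DPC = 400L, HYBRID = 420L, PSSM = 400L)

#' ProteinDataset: a labelled collection of protein sequences
#'
#' An ordered set of validated protein sequences with per-record identifiers,
#' free-text descriptions and an optional class label (+1 aromatase-like /
#' -1 background). Sequences are stored as a [Biostrings::AAStringSet] and
#' contain only the 20 standard amino-acid letters.
#'
#' @slot sequences [Biostrings::AAStringSet] with unique, non-empty names
#'   (the record ids).
#' @slot description character vector of per-record descriptions (may be
#'   empty strings).
#' @slot label integer vector of class labels in \{+1, -1\}, or `NA` when
#'   unlabelled.
#' @slot provenance single string recording where the records came from and
#'   which curation steps were applied.
#'
#' @aliases ProteinDataset-class
#' @exportClass ProteinDataset
setClass("ProteinDataset",
    representation(sequences = "AAStringSet",
                   description = "character",
                   label = "integer",
                   provenance = "character"))

setValidity("ProteinDataset", function(object) {
    n <- length(object@sequences)
    ids <- names(object@sequences)
    msg <- character()
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
        msg <- c(msg, "all records must have non-empty ids")
    else if (anyDuplicated(ids))
        msg <- c(msg, paste0("duplicate record ids: ",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (length(object@description) != n)
        msg <- c(msg, "'description' length must match number of records")
    if (length(object@label) != n)
        msg <- c(msg, "'label' length must match number of records")
    if (any(!is.na(object@label) & !object@label %in% c(1L, -1L)))
        msg <- c(msg, "labels must be +1, -1 or NA")
    if (length(object@provenance) != 1L)
        msg <- c(msg, "'provenance' must be a single string")
    if (n > 0L) {
        if (any(Biostrings::width(object@sequences) < 1L))
            msg <- c(msg, "all sequences must have length >= 1")
        bad <- vapply(seq_len(n), function(i)
            grepl(sprintf("[^%s]", paste(AA20, collapse = "")),
                  as.character(object@sequences[[i]])), logical(1))
        if (any(bad))
            msg <- c(msg, paste0("non-standard residues in: ",
                                 paste(head(ids[bad], 5L), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinDataset
#'
#' @param sequences character vector or [Biostrings::AAStringSet] of protein
#'   sequences. Lowercase input is uppercased.
#' @param ids character vector of unique record identifiers; defaults to the
#'   names of `sequences`.
#' @param description per-record description strings (default empty).
#' @param label per-record class labels (+1/-1) or `NA`.
#' @param provenance free-text note on the origin of the records.
#' @param clean if `TRUE` (default), letters outside the 20 standard
#'   amino-acid alphabet (ambiguity codes B/J/O/U/X/Z, gaps, stops) are
#'   removed with a warning; composition denominators then use the cleaned
#'   length.
#'
#' @return a [ProteinDataset-class] object.
#' @examples
#' d <- ProteinDataset(c(p1 = "MKLV", p2 = "GGAW"), label = c(1, -1))
#' length(d)
#' @export
ProteinDataset <- function(sequences, ids = names(sequences),
                           description = character(), label = NA,
                           provenance = "in-memory", clean = TRUE) {
    seqs <- toupper(as.character(sequences))
    n <- length(seqs)
    if (is.null(ids))
        stop("record ids are required (name 'sequences' or pass 'ids')")
    if (clean) {
        cleaned <- gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "", seqs)
        dropped <- nchar(seqs) - nchar(cleaned)
        if (any(dropped > 0L))
            warning(sprintf("removed %d non-standard residue(s) from %d record(s)",
                            sum(dropped), sum(dropped > 0L)))
        seqs <- cleaned
    }
    if (any(!nzchar(seqs)))
        stop("empty sequence (after validation) for record(s): ",
             paste(ids[!nzchar(seqs)], collapse = ", "))
    if (length(description) == 0L) description <- rep("", n)
    if (length(label) == 1L) label <- rep(label, n)
    aa <- Biostrings::AAStringSet(seqs)
    names(aa) <- as.character(ids)
    new("ProteinDataset", sequences = aa,
        description = as.character(description),
        label = as.integer(label),
        provenance = as.character(provenance))
}

#' PSSMProfile: a per-sequence position-specific scoring matrix
#'
#' Holds the first (log-odds) score block of a PSI-BLAST ASCII PSSM: one row
#' per sequence position, twenty residue columns in the order given by the
#' source file.
#'
#' @slot sequence the residue string of length L.
#' @slot profile numeric L x 20 matrix of scores; columns named by
#'   `residueOrder`.
#' @slot residueOrder the twenty-letter column order as read from the file.
#' @slot normalized `TRUE` once scores have been min-max scaled to [0, 1].
#'
#' @aliases PSSMProfile-class
#' @exportClass PSSMProfile
setClass("PSSMProfile",
    representation(sequence = "character",
                   profile = "matrix",
                   residueOrder = "character",
                   normalized = "logical"))

setValidity("PSSMProfile", function(object) {
    msg <- character()
    if (length(object@sequence) != 1L || !nzchar(object@sequence))
        msg <- c(msg, "'sequence' must be a single non-empty string")
    if (length(object@residueOrder) != 20L ||
        anyDuplicated(object@residueOrder) ||
        !all(object@residueOrder %in% AA20))
        msg <- c(msg, "'residueOrder' must be 20 distinct standard residues")
    if (ncol(object@profile) != 20L)
        msg <- c(msg, "profile must have 20 columns")
    if (nrow(object@profile) != nchar(object@sequence))
        msg <- c(msg, sprintf("profile has %d rows but sequence has %d residues",
                              nrow(object@profile), nchar(object@sequence)))
    if (isTRUE(object@normalized) &&
        (min(object@profile) < 0 || max(object@profile) > 1))
        msg <- c(msg, "normalized profile must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a PSSMProfile
#'
#' @param sequence residue string of length L.
#' @param profile L x 20 numeric matrix of scores.
#' @param residueOrder column order of `profile` (default: the PSI-BLAST
#'   ASCII column order A R N D C Q E G H I L K M F P S T W Y V).
#' @param normalized whether the scores are already min-max scaled.
#' @return a [PSSMProfile-class] object.
#' @export
PSSMProfile <- function(sequence, profile,
                        residueOrder = PSSM_COLUMN_ORDER,
                        normalized = FALSE) {
    profile <- as.matrix(profile)
    colnames(profile) <- residueOrder
    new("PSSMProfile", sequence = as.character(sequence), profile = profile,
        residueOrder = residueOrder, normalized = isTRUE(normalized))
}

#' FeatureSet: fixed-length numeric encodings of sequences
#'
#' A numeric matrix with one row per encoded sequence under one of the four
#' schemes: `AAC` (20), `DPC` (400), `HYBRID` (420) or `PSSM` (400).
#'
#' @slot values numeric matrix, rows named by source record id.
#' @slot scheme one of `"AAC"`, `"DPC"`, `"HYBRID"`, `"PSSM"`.
#'
#' @aliases FeatureSet-class
#' @exportClass FeatureSet
setClass("FeatureSet",
    representation(values = "matrix", scheme = "character"))

setValidity("FeatureSet", function(object) {
    msg <- character()
    if (!object@scheme %in% names(FEATURE_DIMS))
        msg <- c(msg, "scheme must be one of AAC, DPC, HYBRID, PSSM")
    else if (ncol(object@values) != FEATURE_DIMS[[object@scheme]])
        msg <- c(msg, sprintf("%s features must have %d columns, got %d",
                              object@scheme, FEATURE_DIMS[[object@scheme]],
                              ncol(object@values)))
    if (is.null(rownames(object@values)) && nrow(object@values) > 0L)
        msg <- c(msg, "feature rows must be named by source id")
    tol <- 1e-9
    if (object@scheme %in% c("AAC", "DPC", "PSSM") && nrow(object@values) > 0L &&
        (min(object@values) < -tol || max(object@values) > 1 + tol))
        msg <- c(msg, "composition features must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

FeatureSet <- function(values, scheme) {
    new("FeatureSet", values = values, scheme = scheme)
}

#' AromataseSVM: a trained SVM classifier over one feature scheme
#'
#' Opaque handle around a fitted support-vector machine, remembering the
#' feature scheme, input dimension and kernel configuration it was trained
#' with. Scores are oriented so that positive decision values favour the
#' +1 (aromatase-like) class.
#'
#' @slot fit the underlying [e1071::svm] fit.
#' @slot scheme feature scheme the model expects.
#' @slot dim input dimension.
#' @slot config list with `kernel`, `gamma`, `cost` and default `threshold`.
#'
#' @aliases AromataseSVM-class
#' @exportClass AromataseSVM
setClass("AromataseSVM",
    representation(fit = "ANY", scheme = "character", dim = "integer",
                   config = "list"))

#' CVResult: five-fold cross-validation output
#'
#' @slot foldMetrics data.frame with one row per fold (ACC, SN, SP, MCC and
#'   the confusion counts).
#' @slot meanMetrics unweighted mean of the per-fold metrics.
#' @slot pooledMetrics metrics recomputed from the summed confusion counts
#'   across folds (secondary output).
#' @slot foldAssignments named integer vector mapping record id to fold.
#' @slot scores data.frame of held-out scores: id, fold, decision, true,
#'   predicted.
#'
#' @aliases CVResult-class
#' @exportClass CVResult
setClass("CVResult",
    representation(foldMetrics = "data.frame",
                   meanMetrics = "numeric",
                   pooledMetrics = "numeric",
                   foldAssignments = "integer",
                   scores = "data.frame"))
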