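#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: after the header lines, a column
#' header giving the residue order, then one row per sequence position with
#' the position index, the residue, and at least twenty integer log-odds
#' scores. Only the first 20-column score block is read; the weighted
#' observed-percentage block, if present, is ignored.
#'
#' @param path path to an ASCII PSSM file.
#' @return a [PSSMProfile-class] with one row per sequence position.
#' @export
readPSSM <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    ## locate the column-header line: >= 20 single-letter residue tokens
    header_at <- NA_integer_
    for (i in seq_along(lines)) {
        tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
        if (length(tok) >= 20L && all(nchar(tok) == 1L) &&
            all(tok[1:20] %in% AA20)) {
            header_at <- i
            break
        }
    }
    if (is.na(header_at))
        stop("not an ASCII PSSM: no residue column header in ", path)
    residue_order <- strsplit(trimws(lines[header_at]), "\\s+")[[1L]][1:20]
    if (anyDuplicated(residue_order))
        stop("duplicate residue letters in PSSM column header (line ",
             header_at, ")")

    res <- character()
    rows <- list()
    for (i in seq(header_at + 1L, length(lines))) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) {
            if (length(rows)) break else next
        }
        tok <- strsplit(ln, "\\s+")[[1L]]
        if (!grepl("^[0-9]+$", tok[1L])) {
            if (length(rows)) break
            stop("malformed PSSM row at line ", i,
                 ": expected a position index, got '", tok[1L], "'")
        }
        if (length(tok) < 22L)
            stop("truncated PSSM row at line ", i, ": ", length(tok) - 2L,
                 " score column(s), need 20")
        scores <- suppressWarnings(as.integer(tok[3:22]))
        if (any(is.na(scores)))
            stop("non-integer score cell in PSSM row at line ", i)
        res[length(res) + 1L] <- tok[2L]
        rows[[length(rows) + 1L]] <- scores
    }
    if (length(rows) == 0L)
        stop("no score rows found in ", path)
    mat <- do.call(rbind, rows)
    PSSMProfile(sequence = paste(res, collapse = ""), profile = mat,
                residueOrder = residue_order, normalized = FALSE)
}

#' Write a PSSMProfile in the ASCII PSSM dialect
#'
#' Emits a file readable by [readPSSM] (and shaped like PSI-BLAST
#' `-out_ascii_pssm` output restricted to the log-odds block): two header
#' lines, the residue column header, one row per position. Scores are
#' rounded to integers.
#'
#' @param profile a [PSSMProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePSSM <- function(profile, path) {
    stopifnot(is(profile, "PSSMProfile"))
    m <- round(profile@profile)
    res <- strsplit(profile@sequence, "", fixed = TRUE)[[1L]]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("",
                 "Last position-specific scoring matrix computed",
                 paste0("            ",
                        paste(sprintf("%3s", profile@residueOrder),
                              collapse = " "))), con)
    for (p in seq_len(nrow(m)))
        writeLines(paste0(sprintf("%5d %s  ", p, res[p]),
                          paste(sprintf("%3d", m[p, ]), collapse = " ")), con)
    writeLines("", con)
    invisible(path)
}
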