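#' Accessors for aromapred classes
#'
#' `ids`, `descriptions`, `sequences`, `labels` and `provenance` extract the
#' corresponding fields of a [ProteinDataset-class]; `featureMatrix` and
#' `scheme` extract the numeric matrix and encoding scheme of a
#' [FeatureSet-class].
#'
#' @param x a `ProteinDataset` or `FeatureSet`.
#' @return the requested component.
#' @name accessors
#' @aliases ids descriptions sequences labels provenance featureMatrix scheme
#' @examples
#' d <- ProteinDataset(c(a = "MKL", b = "GGA"))
#' ids(d)
NULL

#' @rdname accessors
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname accessors
#' @export
setGeneric("descriptions", function(x) standardGeneric("descriptions"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("labels")

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname accessors
#' @export
setMethod("ids", "ProteinDataset", function(x) names(x@sequences))

#' @rdname accessors
#' @export
setMethod("descriptions", "ProteinDataset", function(x) x@description)

#' @rdname accessors
#' @export
setMethod("sequences", "ProteinDataset", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("labels", "ProteinDataset", function(object, ...) object@label)

#' @rdname accessors
#' @export
setMethod("provenance", "ProteinDataset", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureSet", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("scheme", "FeatureSet", function(x) x@scheme)

#' @describeIn ProteinDataset number of records
#' @param x a `ProteinDataset`
#' @export
setMethod("length", "ProteinDataset", function(x) length(x@sequences))

#' @describeIn ProteinDataset subset records by index, id or logical mask
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "ProteinDataset", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, names(x@sequences))
    initialize(x, sequences = x@sequences[i],
               description = x@description[i], label = x@label[i])
})

setMethod("show", "ProteinDataset", function(object) {
    n <- length(object)
    lab <- object@label
    cat(sprintf("ProteinDataset with %d record(s) (%d positive, %d negative, %d unlabelled)\n",
                n, sum(lab %in% 1L), sum(lab %in% -1L), sum(is.na(lab))))
    if (n > 0L)
        cat(sprintf("  lengths: %d-%d | first id: %s\n",
                    min(Biostrings::width(object@sequences)),
                    max(Biostrings::width(object@sequences)),
                    names(object@sequences)[1L]))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "PSSMProfile", function(object) {
    cat(sprintf("PSSMProfile: %d positions x 20 residues (%s)\n",
                nrow(object@profile),
                if (object@normalized) "normalized to [0,1]" else "raw log-odds"))
})

setMethod("show", "FeatureSet", function(object) {
    cat(sprintf("FeatureSet: %d sequence(s) x %d %s feature(s)\n",
                nrow(object@values), ncol(object@values), object@scheme))
})

setMethod("show", "AromataseSVM", function(object) {
    cat(sprintf("AromataseSVM: %s kernel SVM on %s features (dim %d), gamma=%g, cost=%g\n",
                object@config$kernel, object@scheme, object@dim,
                object@config$gamma, object@config$cost))
})

setMethod("show", "CVResult", function(object) {
    cat("Five-fold cross-validation result\n")
    cat(sprintf("  mean: ACC %.2f%%  SN %.2f%%  SP %.2f%%  MCC %.3f\n",
                object@meanMetrics[["ACC"]], object@meanMetrics[["SN"]],
                object@meanMetrics[["SP"]], object@meanMetrics[["MCC"]]))
})

#' @describeIn CVResult per-fold metrics with a trailing mean row
#' @param object a `CVResult`
#' @export
setGeneric("foldMetrics", function(object) standardGeneric("foldMetrics"))

#' @rdname CVResult-class
#' @export
setMethod("foldMetrics", "CVResult", function(object) {
    fm <- object@foldMetrics
    mean_row <- as.data.frame(as.list(object@meanMetrics))
    mean_row$fold <- "mean"
    cols <- c("fold", "ACC", "SN", "SP", "MCC")
    rbind(fm[, cols], mean_row[, cols])
})

#' @describeIn CVResult unweighted mean of per-fold metrics
#' @export
setGeneric("meanMetrics", function(object) standardGeneric("meanMetrics"))

#' @rdname CVResult-class
#' @export
setMethod("meanMetrics", "CVResult", function(object) object@meanMetrics)

#' @describeIn CVResult held-out decision scores for every record
#' @export
setGeneric("cvScores", function(object) standardGeneric("cvScores"))

#' @rdname CVResult-class
#' @export
setMethod("cvScores", "CVResult", function(object) object@scores)

#' @describeIn CVResult record-id to fold-index assignment
#' @export
setGeneric("foldAssignments", function(object) standardGeneric("foldAssignments"))

#' @rdname CVResult-class
#' @export
setMethod("foldAssignments", "CVResult", function(object) object@foldAssignments)
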