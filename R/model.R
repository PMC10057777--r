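#' Kernel configuration for the SVM classifier
#'
#' @param kernel one of `"rbf"`, `"linear"`, `"polynomial"`.
#' @param gamma RBF kernel width (> 0).
#' @param cost soft-margin trade-off C (> 0).
#' @param threshold default decision cutoff applied at prediction time
#'   (SVM-light convention: 0; a decision value >= threshold is called +1).
#' @return a validated configuration list.
#' @seealso [svmDefaults] for the per-scheme defaults.
#' @export
svmConfig <- function(kernel = "rbf", gamma = 1, cost = 100, threshold = 0) {
    kernel <- match.arg(kernel, c("rbf", "linear", "polynomial"))
    if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
    if (!is.numeric(cost) || cost <= 0) stop("'cost' must be > 0")
    list(kernel = kernel, gamma = as.numeric(gamma), cost = as.numeric(cost),
         threshold = as.numeric(threshold))
}

#' Default SVM configuration per feature scheme
#'
#' The dipeptide-composition model uses the published RBF parameters
#' gamma = 3, cost = 375; the remaining schemes use gamma = 1, cost = 100
#' (their tuned values were never published) and can be overridden.
#'
#' @param scheme one of `"AAC"`, `"DPC"`, `"HYBRID"`, `"PSSM"`.
#' @return a configuration list as from [svmConfig].
#' @export
svmDefaults <- function(scheme = c("AAC", "DPC", "HYBRID", "PSSM")) {
    scheme <- match.arg(toupper(scheme), c("AAC", "DPC", "HYBRID", "PSSM"))
    if (scheme == "DPC") svmConfig("rbf", gamma = 3, cost = 375)
    else svmConfig("rbf", gamma = 1, cost = 100)
}

#' Train an RBF-kernel SVM on feature vectors
#'
#' Fits a two-class support-vector machine on the rows of `features` with
#' +1/-1 labels. Feature values are used as-is (no internal rescaling), so
#' training is deterministic given identical inputs and configuration.
#' Decision values are oriented so positive scores favour the +1 class.
#'
#' @param features a [FeatureSet-class] or numeric matrix (rows = examples).
#' @param labs vector of +1/-1 labels, one per row; both classes must be
#'   present.
#' @param config configuration from [svmConfig]/[svmDefaults]; defaults to
#'   the scheme default when `features` is a `FeatureSet`, else
#'   `svmConfig()`.
#' @return an [AromataseSVM-class] handle.
#' @examples
#' x <- rbind(a = c(1, 0), b = c(0.9, 0), c = c(0, 1), d = c(0, 0.9))
#' m <- trainSVM(x, c(1, 1, -1, -1), svmConfig("linear"))
#' predict(m, x)$predicted
#' @export
trainSVM <- function(features, labs, config = NULL) {
    mat <- if (is(features, "FeatureSet")) featureMatrix(features) else
        as.matrix(features)
    sch <- if (is(features, "FeatureSet")) scheme(features) else "CUSTOM"
    if (is.null(config))
        config <- if (sch == "CUSTOM") svmConfig() else svmDefaults(sch)
    if (nrow(mat) != length(labs))
        stop(sprintf("have %d vectors but %d labels", nrow(mat), length(labs)))
    if (any(!labs %in% c(1, -1)))
        stop("labels must be +1 or -1")
    if (length(unique(labs)) < 2L)
        stop("training requires at least one example of each class")
    y <- factor(ifelse(labs > 0, "pos", "neg"), levels = c("pos", "neg"))
    kern <- c(rbf = "radial", linear = "linear",
              polynomial = "polynomial")[[config$kernel]]
    fit <- e1071::svm(x = mat, y = y, type = "C-classification",
                      kernel = kern, gamma = config$gamma, cost = config$cost,
                      scale = FALSE, tolerance = 1e-5)
    new("AromataseSVM", fit = fit, scheme = sch, dim = ncol(mat),
        config = config)
}

#' Score sequences with a trained SVM
#'
#' Returns one row per input vector with the continuous SVM decision value
#' and the thresholded class call. A decision value greater than or equal to
#' `threshold` is called +1 (ties resolve to the positive class).
#'
#' @param object an [AromataseSVM-class] model.
#' @param features a [FeatureSet-class] or numeric matrix matching the
#'   training dimension.
#' @param threshold decision cutoff; defaults to the training
#'   configuration's threshold (0).
#' @param trueLabels optional +1/-1 labels carried through to the output.
#' @param ... ignored.
#' @return data.frame with columns `id`, `decision`, `predicted` and, when
#'   supplied, `true`.
#' @export
setMethod("predict", "AromataseSVM",
          function(object, features, threshold = NULL, trueLabels = NULL, ...) {
    mat <- if (is(features, "FeatureSet")) featureMatrix(features) else
        as.matrix(features)
    if (ncol(mat) != object@dim)
        stop(sprintf("model expects %d-dimensional input (%s), got %d",
                     object@dim, object@scheme, ncol(mat)))
    if (is.null(threshold)) threshold <- object@config$threshold
    rn <- rownames(mat)
    if (is.null(rn)) rn <- as.character(seq_len(nrow(mat)))
    pr <- predict(object@fit, mat, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    ## e1071 orients decision values toward the class named first in the
    ## "A/B" column label; flip if that is the negative class
    if (startsWith(colnames(dv)[1L], "neg")) dv <- -dv
    dv <- as.numeric(dv[, 1L])
    out <- data.frame(id = rn, decision = dv,
                      predicted = ifelse(dv >= threshold, 1L, -1L),
                      stringsAsFactors = FALSE)
    if (!is.null(trueLabels)) {
        if (length(trueLabels) != nrow(mat))
            stop("'trueLabels' length must match the number of vectors")
        out$true <- as.integer(trueLabels)
    }
    out
})

MODEL_FORMAT <- "aromapred-svm"
MODEL_VERSION <- 1L

#' Persist and restore trained models
#'
#' `saveModel` writes a versioned container (RDS serialization of the fit
#' plus scheme, dimension and configuration); `loadModel` validates the
#' container and reconstructs the [AromataseSVM-class] handle. A round trip
#' reproduces decision values exactly.
#'
#' @param model an [AromataseSVM-class].
#' @param path file path.
#' @return `saveModel`: `path`, invisibly; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "AromataseSVM"))
    saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
                 scheme = model@scheme, dim = model@dim,
                 config = model@config, fit = model@fit),
            path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    obj <- tryCatch(readRDS(path),
                    error = function(e) stop("cannot read model file '", path,
                                             "': ", conditionMessage(e)))
    if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
        stop("'", path, "' is not an aromapred model file")
    if (!identical(obj$version, MODEL_VERSION))
        stop("unsupported model file version: ", obj$version)
    expected <- FEATURE_DIMS[obj$scheme]
    if (!is.na(expected) && obj$dim != expected)
        stop(sprintf("corrupt model file: scheme %s requires dimension %d, file says %d",
                     obj$scheme, expected, obj$dim))
    new("AromataseSVM", fit = obj$fit, scheme = obj$scheme,
        dim = as.integer(obj$dim), config = obj$config)
}
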