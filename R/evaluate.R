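## run code under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Stratified k-fold assignment
#'
#' Shuffles the positive and the negative class separately under the given
#' seed and deals each round-robin into `k` folds, so per-class fold sizes
#' differ by at most one. When `ids` are supplied the shuffle is keyed by
#' sorted record id, making the assignment invariant to the input order of
#' the records.
#'
#' @param labs vector of +1/-1 labels.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the shuffles.
#' @param ids optional record ids (names the result and keys the shuffle).
#' @return integer vector of fold indices in 1..k, aligned with `labs`
#'   (named by `ids` when given).
#' @examples
#' table(kfoldSplit(rep(c(1, -1), each = 10), k = 5, seed = 1),
#'       rep(c(1, -1), each = 10))
#' @export
kfoldSplit <- function(labs, k = 5L, seed = 1L, ids = NULL) {
    if (any(!labs %in% c(1, -1)))
        stop("labels must be +1 or -1")
    if (!is.null(ids) && length(ids) != length(labs))
        stop("'ids' length must match 'labs'")
    n_pos <- sum(labs > 0)
    n_neg <- sum(labs < 0)
    if (n_pos < k || n_neg < k)
        stop(sprintf("each class must have at least k=%d members (have %d positive, %d negative)",
                     k, n_pos, n_neg))
    fold <- integer(length(labs))
    withSeed(seed, {
        for (cls in c(1, -1)) {
            idx <- which(labs == cls)
            if (!is.null(ids))  # key by id so input order is irrelevant
                idx <- idx[order(ids[idx], method = "radix")]
            shuffled <- idx[sample.int(length(idx))]
            fold[shuffled] <- rep_len(seq_len(k), length(shuffled))
        }
    })
    if (!is.null(ids)) names(fold) <- ids
    fold
}

#' Confusion counts from true and predicted labels
#'
#' @param true,predicted vectors of +1/-1 labels.
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusionCounts <- function(true, predicted) {
    if (length(true) != length(predicted))
        stop("'true' and 'predicted' must have equal length")
    c(TP = sum(true > 0 & predicted > 0),
      TN = sum(true < 0 & predicted < 0),
      FP = sum(true < 0 & predicted > 0),
      FN = sum(true > 0 & predicted < 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity and specificity as percentages, and the Matthews
#' correlation coefficient:
#' \deqn{ACC = 100 (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{SN = 100\, TP/(TP+FN), \quad SP = 100\, TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' MCC is defined as 0 when any factor of the denominator is 0.
#'
#' @param counts named vector with elements TP, TN, FP, FN (e.g. from
#'   [confusionCounts]); alternatively pass the four counts via `TP`, `TN`,
#'   `FP`, `FN`.
#' @param TP,TN,FP,FN individual counts (used when `counts` is missing).
#' @return named numeric vector `c(ACC, SN, SP, MCC)`; ACC/SN/SP in
#'   [0, 100], MCC in [-1, 1].
#' @examples
#' computeMetrics(TP = 50, TN = 50, FP = 0, FN = 0)
#' @export
computeMetrics <- function(counts = NULL, TP = NULL, TN = NULL, FP = NULL,
                           FN = NULL) {
    if (!is.null(counts)) {
        TP <- counts[["TP"]]; TN <- counts[["TN"]]
        FP <- counts[["FP"]]; FN <- counts[["FN"]]
    }
    v <- c(TP, TN, FP, FN)
    if (length(v) != 4L || any(is.na(v)) || any(v < 0))
        stop("TP, TN, FP, FN must be four non-negative counts")
    ## counts as doubles: integer products overflow for large tables
    TP <- as.numeric(TP); TN <- as.numeric(TN)
    FP <- as.numeric(FP); FN <- as.numeric(FN)
    total <- TP + TN + FP + FN
    if (total == 0)
        stop("all confusion counts are zero")
    acc <- 100 * (TP + TN) / total
    sn <- if (TP + FN > 0) 100 * TP / (TP + FN) else NaN
    sp <- if (TN + FP > 0) 100 * TN / (TN + FP) else NaN
    denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / sqrt(denom)
    c(ACC = acc, SN = sn, SP = sp, MCC = mcc)
}

#' Stratified five-fold cross-validation of an SVM model
#'
#' Splits the data with [kfoldSplit], and for each fold trains on the other
#' k - 1 folds and scores the held-out fold at the configured decision
#' threshold. Reports per-fold metrics, their unweighted mean (the headline
#' number), and metrics pooled from the summed confusion counts as a
#' secondary output.
#'
#' @param features a [FeatureSet-class] or numeric matrix with row names.
#' @param labs +1/-1 labels, one per row.
#' @param config SVM configuration (default: the scheme default, see
#'   [svmDefaults]).
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param threshold decision cutoff (default from `config`).
#' @return a [CVResult-class].
#' @export
crossValidate <- function(features, labs, config = NULL, k = 5L, seed = 1L,
                          threshold = NULL) {
    mat <- if (is(features, "FeatureSet")) featureMatrix(features) else
        as.matrix(features)
    sch <- if (is(features, "FeatureSet")) scheme(features) else "CUSTOM"
    if (is.null(config))
        config <- if (sch == "CUSTOM") svmConfig() else svmDefaults(sch)
    if (is.null(threshold)) threshold <- config$threshold
    rn <- rownames(mat)
    if (is.null(rn)) rn <- as.character(seq_len(nrow(mat)))
    fold <- kfoldSplit(labs, k = k, seed = seed, ids = rn)
    fold_rows <- vector("list", k)
    scores <- vector("list", k)
    for (f in seq_len(k)) {
        test <- which(fold == f)
        train <- which(fold != f)
        m <- trainSVM(mat[train, , drop = FALSE], labs[train], config)
        pr <- predict(m, mat[test, , drop = FALSE], threshold = threshold,
                      trueLabels = labs[test])
        cc <- confusionCounts(pr$true, pr$predicted)
        met <- computeMetrics(cc)
        fold_rows[[f]] <- data.frame(fold = f, t(as.data.frame(met)),
                                     t(as.data.frame(cc)), row.names = NULL)
        scores[[f]] <- cbind(pr[, c("id", "decision", "true", "predicted")],
                             fold = f)
    }
    fm <- do.call(rbind, fold_rows)
    pooled <- computeMetrics(c(TP = sum(fm$TP), TN = sum(fm$TN),
                               FP = sum(fm$FP), FN = sum(fm$FN)))
    new("CVResult",
        foldMetrics = fm,
        meanMetrics = colMeans(fm[, c("ACC", "SN", "SP", "MCC")]),
        pooledMetrics = pooled,
        foldAssignments = setNames(as.integer(fold), rn),
        scores = do.call(rbind, scores))
}

#' Metrics across a grid of decision thresholds
#'
#' Re-labels each scored sequence by `decision >= t` for every threshold in
#' the grid and recomputes the four metrics, tracing how accuracy,
#' sensitivity, specificity and MCC move with the cutoff. Sensitivity is
#' non-increasing and specificity non-decreasing in the threshold.
#'
#' @param scores data.frame with columns `decision` and `true` (e.g. from
#'   [predict] with `trueLabels`, or [cvScores]).
#' @param thresholds numeric grid; default 101 evenly spaced points from
#'   the minimum to the maximum observed decision value.
#' @return data.frame with one row per threshold: `threshold`, `ACC`, `SN`,
#'   `SP`, `MCC`, ordered by threshold.
#' @export
thresholdSweep <- function(scores, thresholds = NULL) {
    if (!all(c("decision", "true") %in% names(scores)))
        stop("'scores' must have 'decision' and 'true' columns")
    if (any(is.na(scores$true)))
        stop("true labels are required for a threshold sweep")
    if (is.null(thresholds))
        thresholds <- seq(min(scores$decision), max(scores$decision),
                          length.out = 101L)
    thresholds <- sort(thresholds)
    rows <- lapply(thresholds, function(t) {
        pred <- ifelse(scores$decision >= t, 1L, -1L)
        met <- computeMetrics(confusionCounts(scores$true, pred))
        data.frame(threshold = t, t(as.data.frame(met)), row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Prediction-score graph data and false-positive rate
#'
#' Splits per-sequence decision scores by true class for plotting, and
#' counts the misclassifications at the given threshold: false negatives
#' (positives scored below threshold), false positives (negatives scored at
#' or above threshold) and the false-positive rate FPR = FP / (FP + TN).
#'
#' @param scores data.frame with columns `decision` and `true` (and
#'   optionally `id`).
#' @param threshold decision cutoff (default 0).
#' @return list with `series` (data.frame `index`, `id`, `decision`,
#'   `true`), `falseNegatives`, `falsePositives` and `FPR`.
#' @export
scoreGraph <- function(scores, threshold = 0) {
    if (!all(c("decision", "true") %in% names(scores)))
        stop("'scores' must have 'decision' and 'true' columns")
    id <- if ("id" %in% names(scores)) scores$id else
        as.character(seq_len(nrow(scores)))
    series <- data.frame(index = seq_len(nrow(scores)), id = id,
                         decision = scores$decision, true = scores$true,
                         stringsAsFactors = FALSE)
    fn <- sum(series$true > 0 & series$decision < threshold)
    fp <- sum(series$true < 0 & series$decision >= threshold)
    tn <- sum(series$true < 0 & series$decision < threshold)
    list(series = series, falseNegatives = fn, falsePositives = fp,
         FPR = if (fp + tn > 0) fp / (fp + tn) else NaN)
}

#' Plot a prediction-score graph
#'
#' Scatter of per-sequence decision values, positives and negatives in
#' different colours, with the decision threshold as a horizontal line —
#' the visual check that the two classes separate.
#'
#' @param scores as for [scoreGraph].
#' @param threshold decision cutoff drawn as a horizontal line.
#' @param ... passed to [graphics::plot].
#' @return the [scoreGraph] list, invisibly.
#' @export
plotScoreGraph <- function(scores, threshold = 0, ...) {
    g <- scoreGraph(scores, threshold)
    s <- g$series
    pos <- s$true > 0
    graphics::plot(s$index, s$decision, type = "n",
                   xlab = "sequence index", ylab = "SVM decision value", ...)
    graphics::points(s$index[pos], s$decision[pos], col = "#2166ac", pch = 16)
    graphics::points(s$index[!pos], s$decision[!pos], col = "#b2182b", pch = 1)
    graphics::abline(h = threshold, lty = 2)
    graphics::legend("topright", legend = c("positive", "negative"),
                     col = c("#2166ac", "#b2182b"), pch = c(16, 1), bty = "n")
    invisible(g)
}
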