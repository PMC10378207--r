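#' Leave-one-subject-out folds
#'
#' One fold per subject, ordered by subject id; the fold's test set is that
#' subject's samples and its training set everything else, so no subject
#' ever appears on both sides.
#'
#' @param subjects character/factor vector, one entry per sample.
#' @return list of folds, each `list(subject, trainIdx, testIdx)`.
#' @export
losoSplits <- function(subjects) {
  subjects <- as.character(subjects)
  ids <- sort(unique(subjects))
  if (length(ids) < 2L) stop("LOSO needs at least 2 subjects")
  lapply(ids, function(s)
    list(subject = s,
         trainIdx = which(subjects != s),
         testIdx = which(subjects == s)))
}

#' Classification metrics from a pooled confusion matrix
#'
#' Per-class recall `Acc_c = TP_c / N_c` and
#' `F1_c = 2 TP_c / (2 TP_c + FP_c + FN_c)`; their unweighted means over
#' classes give UAR and UF1. Classes absent from the test pool (row sum 0)
#' have undefined scores and are dropped from the macro averages with a
#' warning.
#'
#' @param cm square confusion matrix, rows = truth, columns = prediction.
#' @return list with `perClass` data.frame, `accuracy`, `uf1`, `uar`.
#' @export
confusionMetrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  tp <- diag(cm)
  nc <- rowSums(cm)
  fn <- nc - tp
  fp <- colSums(cm) - tp
  accC <- ifelse(nc > 0, tp / nc, NA_real_)
  f1C <- ifelse(nc > 0, 2 * tp / pmax(2 * tp + fp + fn, 1e-300), NA_real_)
  if (anyNA(accC))
    warning("class(es) absent from all test sets excluded from UF1/UAR: ",
            paste(which(is.na(accC)), collapse = ", "))
  list(perClass = data.frame(class = seq_len(nrow(cm)), TP = tp, FP = fp,
                             FN = fn, N = nc, accuracy = accC, F1 = f1C),
       accuracy = sum(tp) / sum(cm),
       uf1 = mean(f1C, na.rm = TRUE),
       uar = mean(accC, na.rm = TRUE))
}

#' Leave-one-subject-out evaluation of the flow network
#'
#' Trains one model per subject fold with [trainFold()] (fold seeds are
#' derived from the run seed, so the whole report is reproducible
#' bit-for-bit) and pools all test predictions into a single confusion
#' matrix from which pooled accuracy, per-class scores, UF1 and UAR are
#' computed; mean per-fold accuracy is reported alongside.
#'
#' @param dataset triplet dataset as produced by [makeDataset()] or
#'   [readTripletArchive()]: a list with `triplets` (S x S x 3 x N array),
#'   `labels` (1-based integers), `subjects`, `sampleIds`, `labelVocab`.
#' @param trainConfig a [TrainConfig-class].
#' @param netConfig a [NetConfig-class] (`nClasses` must match the vocab).
#' @param returnModels keep the per-fold trained models (for Grad-CAM on
#'   held-out subjects).
#' @param verbose print one line per fold.
#' @return an [EvalReport-class]; with `returnModels`, the models are
#'   attached to each fold record.
#' @export
evaluateLoso <- function(dataset, trainConfig, netConfig,
                         returnModels = FALSE, verbose = FALSE) {
  x <- dataset$triplets
  labels <- as.integer(dataset$labels)
  subjects <- as.character(dataset$subjects)
  C <- netConfig@nClasses
  stopifnot(length(labels) == dim(x)[4L], C >= max(labels))
  folds <- losoSplits(subjects)
  cm <- matrix(0L, C, C)
  foldRecs <- vector("list", length(folds))
  pred <- integer(length(labels))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tc <- trainConfig
    tc@seed <- as.integer(trainConfig@seed + 1000L * f)
    fit <- tryCatch(
      trainFold(x[, , , fold$trainIdx, drop = FALSE], labels[fold$trainIdx],
                tc, netConfig),
      error = function(e)
        stop("fold '", fold$subject, "': ", conditionMessage(e), call. = FALSE))
    ph <- netPredict(fit$model, x[, , , fold$testIdx, drop = FALSE])
    pred[fold$testIdx] <- ph
    for (i in seq_along(fold$testIdx))
      cm[labels[fold$testIdx[i]], ph[i]] <- cm[labels[fold$testIdx[i]], ph[i]] + 1L
    foldAcc <- mean(ph == labels[fold$testIdx])
    foldRecs[[f]] <- list(subject = fold$subject, n = length(fold$testIdx),
                          accuracy = foldAcc, history = fit$history,
                          model = if (returnModels) fit$model else NULL,
                          testIdx = fold$testIdx)
    if (verbose)
      message(sprintf("fold %s: n=%d acc=%.3f", fold$subject,
                      length(fold$testIdx), foldAcc))
  }
  met <- confusionMetrics(cm)
  vocab <- dataset$labelVocab %||% as.character(seq_len(C))
  dimnames(cm) <- list(truth = vocab, predicted = vocab)
  new("EvalReport", confusion = cm, perClass = met$perClass,
      accuracy = met$accuracy,
      meanFoldAccuracy = mean(vapply(foldRecs, `[[`, numeric(1), "accuracy")),
      uf1 = met$uf1, uar = met$uar, folds = foldRecs,
      predictions = data.frame(
        sampleId = dataset$sampleIds %||% as.character(seq_along(labels)),
        subjectId = subjects, truth = labels, predicted = pred,
        stringsAsFactors = FALSE),
      labelVocab = vocab, seed = trainConfig@seed)
}
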