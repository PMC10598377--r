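#' Train a multi-view model
#'
#' Mini-batch Adam optimisation of the cross-entropy loss for
#' \code{cfg@epochs} epochs. After every epoch the validation AUC is
#' computed in eval mode; the parameter snapshot with the highest
#' validation AUC is returned (ties resolved in favour of the earlier
#' epoch). The per-epoch training loss and validation AUC are recorded in
#' the returned model's \code{trainLog}.
#'
#' Training is deterministic for a fixed \code{cfg@seed} on a given
#' machine: the seed drives batch shuffling (and nothing else once the
#' model is initialised).
#'
#' @param model an \linkS4class{MVModel} (untrained or to be fine-tuned).
#' @param split a \linkS4class{DatasetSplit} with non-empty train and
#'   validation partitions; the training partition must contain both
#'   classes. Cases must be preprocessed to a common shape.
#' @param cfg a \linkS4class{TrainConfig}.
#' @return the trained \linkS4class{MVModel} (best-on-validation snapshot,
#'   including its batch-norm running statistics) with populated
#'   \code{trainLog} and attribute-free selection recorded in the log.
#' @export
trainModel <- function(model, split, cfg = trainConfig()) {
  trn <- trainCases(split)
  val <- valCases(split)
  if (!length(trn) || !length(val))
    stop("train and validation partitions must be non-empty")
  yTrain <- caseLabels(trn)
  if (length(unique(yTrain)) < 2L)
    stop("training partition contains a single class; cannot train")
  yVal <- caseLabels(val)
  n <- nViews(model)

  # stack all training volumes once; batches index into the sample axis
  xAll <- stackCases(trn, model@viewIds)
  nTrain <- length(trn)

  params <- model@params
  state <- adamInit(params)
  bestParams <- params
  bestAuc <- -Inf
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_auc = numeric())

  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(nTrain)
      batches <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
      epochLoss <- 0
      for (bi in batches) {
        vol <- unlist(lapply(bi, function(b) (b - 1L) * n + seq_len(n)))
        x <- xAll[, , , , vol, drop = FALSE]
        fw <- modelForward(params, model@strategy, x, n, length(bi),
                           y = yTrain[bi], training = TRUE,
                           posWeight = cfg@posWeight)
        if (!is.finite(fw$loss))
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (lr %g)",
            epoch, cfg@learningRate))
        params <- fw$params
        grads <- modelBackward(params, model@strategy, fw$cache, yTrain[bi],
                               posWeight = cfg@posWeight)
        upd <- adamStep(params, grads, state, cfg@learningRate, cfg@beta1,
                        cfg@beta2, cfg@weightDecay)
        params <- upd$params
        state <- upd$state
        epochLoss <- epochLoss + fw$loss * length(bi)
      }
      model@params <- params
      valProbs <- predictProbs(model, val)
      vAuc <- evaluateAuc(valProbs, yVal)
      log[epoch, ] <- list(epoch, epochLoss / nTrain, vAuc)
      if (vAuc > bestAuc) {
        bestAuc <- vAuc
        bestParams <- params
      }
    }
  })
  model@params <- bestParams
  model@trainLog <- log
  model
}
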