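# Ablation harnesses: same data, same seeds, one factor varied.

subsetCaseViews <- function(case, ids) {
  keep <- match(ids, viewIds(case))
  if (anyNA(keep))
    stop(sprintf("case '%s' lacks view(s): %s", caseId(case),
                 paste(ids[is.na(keep)], collapse = ", ")))
  new("MultiViewCase", caseId = caseId(case),
      views = caseViews(case)[keep], label = caseLabel(case))
}

subsetSplitViews <- function(split, ids) {
  datasetSplit(lapply(trainCases(split), subsetCaseViews, ids = ids),
               lapply(valCases(split), subsetCaseViews, ids = ids),
               lapply(testCases(split), subsetCaseViews, ids = ids))
}

#' Ablation over the number of views
#'
#' Trains one model per view subset under identical configuration and seed
#' and reports the test AUC of each, quantifying how much additional views
#' contribute.
#'
#' @param split a preprocessed \linkS4class{DatasetSplit}.
#' @param viewSubsets list of character vectors, each a non-empty subset of
#'   the canonical view ids (no duplicates).
#' @param encoderConfig encoder architecture used for every subset.
#' @param cfg \linkS4class{TrainConfig} shared by every subset.
#' @param strategy fusion strategy (default the weighted feature fusion).
#' @return data.frame with columns \code{views}, \code{n_views},
#'   \code{auc}, \code{val_auc}.
#' @export
runViewAblation <- function(split, viewSubsets,
                            encoderConfig = reducedEncoderConfig(),
                            cfg = trainConfig(), strategy = "weighted_feature") {
  if (!length(viewSubsets)) stop("viewSubsets must be non-empty")
  canonical <- viewIds(trainCases(split)[[1]])
  res <- lapply(viewSubsets, function(ids) {
    if (!length(ids)) stop("empty view subset")
    if (anyDuplicated(ids))
      stop(sprintf("duplicate view in subset: %s",
                   paste(ids[duplicated(ids)], collapse = ", ")))
    if (!all(ids %in% canonical))
      stop(sprintf("unknown view(s): %s",
                   paste(setdiff(ids, canonical), collapse = ", ")))
    sub <- subsetSplitViews(split, ids)
    model <- mvModel(ids, encoderConfig, strategy, seed = cfg@seed)
    model <- trainModel(model, sub, cfg)
    rep <- evaluateModel(model, testCases(sub))
    data.frame(views = paste(ids, collapse = "+"), n_views = length(ids),
               auc = auc(rep), val_auc = max(trainLog(model)$val_auc))
  })
  do.call(rbind, res)
}

#' Ablation over fusion strategies
#'
#' Trains the four fusion strategies (label average, label weighting,
#' feature concatenation, weighted feature concatenation) on the same data
#' with the same seed and configuration, and reports each test AUC.
#'
#' @param split a preprocessed \linkS4class{DatasetSplit}.
#' @param encoderConfig encoder architecture shared by all strategies.
#' @param cfg \linkS4class{TrainConfig} shared by all strategies.
#' @param strategies strategies to compare (default all four).
#' @return data.frame with columns \code{strategy}, \code{auc},
#'   \code{val_auc}.
#' @export
runFusionAblation <- function(split, encoderConfig = reducedEncoderConfig(),
                              cfg = trainConfig(),
                              strategies = fusionStrategies()) {
  canonical <- viewIds(trainCases(split)[[1]])
  res <- lapply(strategies, function(st) {
    model <- mvModel(canonical, encoderConfig, st, seed = cfg@seed)
    model <- trainModel(model, split, cfg)
    rep <- evaluateModel(model, testCases(split))
    data.frame(strategy = st, auc = auc(rep),
               val_auc = max(trainLog(model)$val_auc))
  })
  do.call(rbind, res)
}
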