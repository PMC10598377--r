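#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney rank formulation: the fraction of
#' (positive, negative) pairs in which the positive case receives the
#' higher score, with tied scores counted 1/2. Equivalent to brute-force
#' pairwise counting (which the test suite uses as an independent oracle).
#'
#' @param probabilities numeric scores (higher = more positive).
#' @param labels binary labels (0/1), same length; both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @examples
#' evaluateAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
evaluateAuc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: need at least one positive and one negative label")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Youden-optimal operating point
#'
#' Scans every observed score as a candidate threshold (predict positive
#' when score >= threshold) and returns the one maximising Youden's
#' J = sensitivity + specificity - 1; among ties the lowest threshold is
#' chosen.
#'
#' @inheritParams evaluateAuc
#' @return named numeric vector \code{c(threshold, sensitivity,
#'   specificity)}.
#' @export
optimalOperatingPoint <- function(probabilities, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("operating point undefined: both classes must be present")
  thr <- sort(unique(probabilities))
  # cumulative counts: for threshold t, sens = P(score >= t | pos),
  # spec = P(score < t | neg)
  sens <- vapply(thr, function(t) sum(probabilities >= t & labels == 1),
                 numeric(1)) / npos
  spec <- vapply(thr, function(t) sum(probabilities < t & labels == 0),
                 numeric(1)) / nneg
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]   # thr ascending => lowest threshold
  c(threshold = thr[best], sensitivity = sens[best], specificity = spec[best])
}

#' Evaluate a trained model on test cases
#'
#' Predicts probabilities in eval mode and summarises discrimination (AUC)
#' and the Youden-optimal operating point.
#'
#' @param model a trained \linkS4class{MVModel}.
#' @param cases list of preprocessed test \linkS4class{MultiViewCase}.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(model, cases) {
  probs <- predictProbs(model, cases)
  labels <- caseLabels(cases)
  op <- optimalOperatingPoint(probs, labels)
  new("EvalReport", probabilities = probs, labels = labels,
      auc = evaluateAuc(probs, labels), optimalThreshold = op[["threshold"]],
      sensitivity = op[["sensitivity"]], specificity = op[["specificity"]])
}
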