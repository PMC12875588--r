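# Evaluation: classification metrics, repeated-seed stability summaries,
# and the comparison arithmetic used in cross-domain reports.

#' Compute classification metrics
#'
#' Accuracy, macro-averaged recall and F1 (equal class weights; per-class
#' F1 is the harmonic mean of precision and recall), per-class accuracy and
#' the confusion matrix. A class present in the level set but absent from
#' the labels contributes recall 0 with a warning.
#'
#' @param predictions factor (or vector) of predicted classes.
#' @param labels factor (or vector) of true classes, same length.
#' @return a \linkS4class{MetricsReport}.
#' @examples
#' computeMetrics(c("a", "a", "b"), c("a", "b", "b"))
#' @export
computeMetrics <- function(predictions, labels) {
  if (length(predictions) == 0L || length(labels) == 0L)
    stop("empty predictions or labels")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  lv <- union(levels(factor(labels)), levels(factor(predictions)))
  truth <- factor(labels, levels = lv)
  pred <- factor(predictions, levels = lv)
  cm <- table(truth = truth, predicted = pred)
  cm <- matrix(as.integer(cm), nrow = length(lv),
               dimnames = list(truth = lv, predicted = lv))
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  rowS <- rowSums(cm); colS <- colSums(cm)
  if (any(rowS == 0))
    warning("class(es) absent from labels contribute recall 0: ",
            paste(lv[rowS == 0], collapse = ", "), call. = FALSE)
  recall <- ifelse(rowS > 0, diag(cm) / rowS, 0)
  precision <- ifelse(colS > 0, diag(cm) / colS, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  new("MetricsReport", accuracy = acc, macroRecall = mean(recall),
      macroF1 = mean(f1),
      perClassAccuracy = stats::setNames(as.numeric(recall), lv),
      confusion = cm)
}

#' @describeIn computeMetrics overall accuracy of a report
#' @param report a \linkS4class{MetricsReport}
#' @export
accuracy <- function(report) report@accuracy

#' Run an experiment over repeated seeds
#'
#' Calls \code{experiment(seed)} once per seed and summarizes the returned
#' scalar metric with its mean and sample standard deviation (n-1
#' denominator). A failed run is recorded as NA with a warning and excluded
#' from the summary.
#'
#' @param experiment function of a single integer seed returning a scalar.
#' @param seeds integer vector of seeds (default 1:10); at least 2.
#' @return a \linkS4class{RunSummary}.
#' @export
repeatRuns <- function(experiment, seeds = 1:10) {
  stopifnot(length(seeds) >= 2L)
  vals <- vapply(seeds, function(s) {
    tryCatch(as.numeric(experiment(s)), error = function(e) {
      warning("run with seed ", s, " failed: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  }, 0)
  ok <- vals[!is.na(vals)]
  new("RunSummary", values = ok, mean = mean(ok), sd = stats::sd(ok),
      seeds = as.integer(seeds))
}

#' Relative improvement of an adapted accuracy over a baseline
#'
#' \code{100 * (adapted - baseline) / baseline}, the percentage used to
#' report cross-device adaptation gains.
#'
#' @param baseline baseline (direct-transfer) accuracy; must be > 0.
#' @param adapted adapted accuracy on the same scale.
#' @return relative improvement in percent.
#' @examples
#' relativeImprovement(56.2, 75.4)  # 34.2 (to one decimal)
#' @export
relativeImprovement <- function(baseline, adapted) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  100 * (adapted - baseline) / baseline
}

#' Absolute margin between two accuracies, in percentage points
#'
#' Plain difference \code{a - b}, the comparison arithmetic used when
#' reporting how far one method's accuracy sits above another's.
#'
#' @param a,b accuracies in percent.
#' @return margin in percentage points.
#' @examples
#' accuracyMargin(95.5, 94.3)  # 1.2
#' @export
accuracyMargin <- function(a, b) a - b

#' Method-comparison table
#'
#' Builds the report-module comparison of several methods' accuracies
#' against a reference method: margins in points and relative differences.
#'
#' @param accuracies named numeric vector of accuracies in percent.
#' @param reference name of the reference method (default: the maximum).
#' @return data.frame with method, accuracy, margin (reference - method)
#'   and relative difference in percent.
#' @export
compareMethods <- function(accuracies, reference = NULL) {
  stopifnot(!is.null(names(accuracies)))
  if (is.null(reference)) reference <- names(which.max(accuracies))
  ref <- accuracies[[reference]]
  data.frame(method = names(accuracies),
             accuracy = as.numeric(accuracies),
             margin = accuracyMargin(ref, as.numeric(accuracies)),
             relative = relativeImprovement(as.numeric(accuracies), ref),
             row.names = NULL)
}
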