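## Evaluation harness: confusion-matrix construction over affected vs
## unaffected tiles, truncated ("floor") percentage metrics, and the
## train/tune/validation splitter used for cross-validation.

#' Confusion matrix from predicted and true tile labels
#'
#' Tiles labelled `non_informative` by either side are excluded; the
#' positive class is `affected`.
#'
#' @param predicted,truth equal-length character vectors of tile labels
#'   (`affected`, `unaffected`, `non_informative`).
#' @return a [ConfusionMatrix-class].
#' @export
confusionTiles <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    tmaError("predicted and truth must have equal length", "tmaLabelMismatch")
  keep <- predicted != "non_informative" & truth != "non_informative"
  p <- predicted[keep]; t <- truth[keep]
  ConfusionMatrix(tp = sum(p == "affected" & t == "affected"),
                  fp = sum(p == "affected" & t == "unaffected"),
                  fn = sum(p == "unaffected" & t == "affected"),
                  tn = sum(p == "unaffected" & t == "unaffected"))
}

#' Truncated percentage metrics
#'
#' Accuracy, sensitivity and specificity as integer percentages obtained
#' by truncation (floor), i.e. `floor(100 * (TP+TN) / total)` and
#' analogously for the class rates. Truncation, not rounding, is the
#' convention that reproduces reported screening percentages consistently
#' (e.g. 302/360 = 83.9 percent prints as 83).
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named integer vector `c(accuracy=, sensitivity=, specificity=)`.
#' @examples
#' percentMetrics(ConfusionMatrix(541, 37, 101, 617))  # 89 84 94
#' @export
percentMetrics <- function(cm) {
  n <- counts(cm)
  total <- sum(n)
  if (total == 0 || n[["TP"]] + n[["FN"]] == 0 || n[["TN"]] + n[["FP"]] == 0)
    tmaError("zero denominator: metrics undefined", "tmaUndefinedMetric")
  c(accuracy = as.integer(floor(100 * (n[["TP"]] + n[["TN"]]) / total)),
    sensitivity = as.integer(floor(100 * n[["TP"]] / (n[["TP"]] + n[["FN"]]))),
    specificity = as.integer(floor(100 * n[["TN"]] / (n[["TN"]] + n[["FP"]]))))
}

#' Random train / tune / validation split
#'
#' Uniform random partition of `1:n` into three disjoint, exhaustive index
#' sets, deterministic per seed. The default sizes reproduce a 650/323/323
#' split of a 1296-tile corpus.
#'
#' @param n number of items.
#' @param sizes integer vector (train, tune, validation); must sum to `n`.
#' @param seed integer seed.
#' @return list with integer elements `train`, `tune`, `validation`.
#' @export
splitDataset <- function(n, sizes = c(650, 323, 323), seed = 0) {
  if (length(sizes) != 3 || any(sizes < 0) || sum(sizes) != n)
    tmaError("sizes must be three non-negative counts summing to n",
             "tmaBadSplit")
  idx <- withLocalSeed(seed, sample.int(n))
  list(train = sort(idx[seq_len(sizes[1])]),
       tune = sort(idx[sizes[1] + seq_len(sizes[2])]),
       validation = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}
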