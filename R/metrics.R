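# Segmentation metrics: Dice, precision/recall, per-case vs global
# aggregation, patient-level cross-validation folds, repeated-run summaries
# and the paired t-test protocol.

#' Dice similarity coefficient for one class
#'
#' `2 |A intersect B| / (|A| + |B|)` where A and B are the pixel sets of
#' `cls` in the prediction and the ground truth. When the class is absent
#' from both masks the coefficient is defined as 1 (perfect agreement on
#' absence) and flagged via attribute `"empty"`.
#'
#' @param pred,truth integer label masks of identical shape
#' @param cls class label to score
#' @return Dice value in `[0, 1]`; attribute `"empty"` is TRUE when the
#'   class is absent from both masks
#' @export
dice_coefficient <- function(pred, truth, cls) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("prediction and truth masks have different shapes")
  a <- pred == cls
  b <- truth == cls
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, empty = TRUE))
  structure(2 * sum(a & b) / (na + nb), empty = FALSE)
}

#' Per-class confusion counts
#'
#' @param pred,truth integer label masks of identical shape
#' @param cls class label
#' @return list with integer `tp`, `fp`, `fn`
#' @export
confusion_counts <- function(pred, truth, cls) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("prediction and truth masks have different shapes")
  a <- pred == cls
  b <- truth == cls
  list(tp = sum(a & b), fp = sum(a & !b), fn = sum(!a & b))
}

#' Precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A zero
#' denominator yields `NA` (undefined), which aggregation excludes from
#' averages rather than zero-filling.
#'
#' @param counts list with nonnegative `tp`, `fp`, `fn` (as from
#'   [confusion_counts()])
#' @return list with `precision` and `recall` (each possibly `NA`)
#' @export
precision_recall <- function(counts) {
  with(counts, {
    if (tp < 0 || fp < 0 || fn < 0) stop("negative confusion counts")
    list(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  })
}

#' Per-case and global Dice over patient volumes
#'
#' Per-case: the Dice of each patient volume (all slices pooled) averaged
#' over volumes. Global: the Dice of all volumes pooled into one pixel set.
#'
#' @param volumes list of `list(pred =, truth =)` mask pairs (one per
#'   patient volume)
#' @param cls class label to score
#' @return list with `per_case` and `global`
#' @export
dice_per_case_and_global <- function(volumes, cls) {
  if (length(volumes) == 0) stop("empty volume list")
  inter <- 0; na <- 0; nb <- 0
  per <- numeric(length(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (length(v$pred) != length(v$truth))
      stop("volume ", i, ": prediction and truth shapes differ")
    a <- v$pred == cls
    b <- v$truth == cls
    per[i] <- if (sum(a) + sum(b) == 0) 1 else
      2 * sum(a & b) / (sum(a) + sum(b))
    inter <- inter + sum(a & b)
    na <- na + sum(a)
    nb <- nb + sum(b)
  }
  list(per_case = mean(per),
       global = if (na + nb == 0) 1 else 2 * inter / (na + nb))
}

#' Full metrics report for a prediction/truth mask pair
#'
#' Per-class Dice, precision and recall for every foreground class plus
#' their means; the background class (0) is excluded from all means, and
#' undefined precision/recall values are dropped from the means.
#'
#' @param pred,truth integer label masks of identical shape
#' @param classes integer vector of foreground class labels to score
#' @param class_names optional character names for the classes
#' @return data frame (one row per class plus a `"mean"` row) with columns
#'   `class`, `dice`, `precision`, `recall`
#' @export
evaluate_segmentation <- function(pred, truth, classes,
                                  class_names = as.character(classes)) {
  rows <- lapply(seq_along(classes), function(i) {
    cls <- classes[i]
    cc <- confusion_counts(pred, truth, cls)
    pr <- precision_recall(cc)
    data.frame(class = class_names[i],
               dice = as.numeric(dice_coefficient(pred, truth, cls)),
               precision = pr$precision, recall = pr$recall)
  })
  df <- do.call(rbind, rows)
  rbind(df, data.frame(class = "mean", dice = mean(df$dice),
                       precision = mean(df$precision, na.rm = TRUE),
                       recall = mean(df$recall, na.rm = TRUE)))
}

#' Patient-level k-fold cross-validation split
#'
#' Assigns whole patients to folds (all slices of a patient share a fold);
#' folds are disjoint, exhaustive, of sizes differing by at most one, and
#' deterministic given the seed.
#'
#' @param patient_ids vector of distinct patient identifiers
#' @param k number of folds
#' @param seed integer seed for the shuffle
#' @return list of `k` vectors of patient ids
#' @export
kfold_split_patients <- function(patient_ids, k = 5L, seed = 1L) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  if (n < k) stop("need at least k = ", k, " distinct patients, got ", n)
  set.seed(seed)
  shuffled <- sample(patient_ids)
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(unname(split(shuffled, fold_of)), unname)
}

#' Paired t-test between two score vectors
#'
#' Classical two-sided paired t-test on the differences. Zero-variance
#' differences are flagged degenerate: all-zero differences give p = 1 (no
#' evidence of a difference); constant nonzero differences give the p -> 0
#' limit.
#'
#' @param scores_a,scores_b equal-length paired score vectors, `n >= 2`
#' @param alpha significance level
#' @return list with `t`, `p`, `significant`, `degenerate`
#' @export
paired_t_test <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors have different lengths")
  if (length(scores_a) < 2) stop("need at least two paired scores")
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, significant = FALSE, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE,
                degenerate = TRUE))
  }
  ht <- t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, degenerate = FALSE)
}

#' Mean and sample standard deviation across repeated runs
#'
#' Entrywise mean and sample (n - 1) standard deviation over a list of
#' per-run metric vectors; a single run yields std 0 with a flag.
#'
#' @param run_metrics list of equally named numeric vectors, one per run
#' @return data frame with columns `metric`, `mean`, `std`; attribute
#'   `"single_run"` is TRUE when only one run was supplied
#' @export
aggregate_runs <- function(run_metrics) {
  if (length(run_metrics) == 0) stop("need at least one run")
  nms <- names(run_metrics[[1]])
  for (r in run_metrics) {
    if (!identical(sort(names(r)), sort(nms)))
      stop("inconsistent metric names across runs")
  }
  m <- do.call(rbind, lapply(run_metrics, function(r) r[nms]))
  single <- nrow(m) == 1
  out <- data.frame(metric = nms,
                    mean = colMeans(m),
                    std = if (single) 0 else apply(m, 2, sd),
                    row.names = NULL)
  attr(out, "single_run") <- single
  out
}
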