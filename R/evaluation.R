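# Seeded train/validation/test splits and the six standard classification
# metrics: accuracy, AUPRC, AUROC, precision, recall, F-score.

#' Split samples into train/validation/test index sets
#'
#' Sizes are `floor(n * fraction)` for validation and test with the
#' remainder going to train, so e.g. 100 samples at (0.8, 0.1, 0.1) give
#' exactly 80/10/10. With `stratify = TRUE` the allocation is done per
#' label class and then pooled, preserving class balance.
#'
#' @param labels Label vector (its length defines `n`; values are used for
#'   stratification only).
#' @param fractions Numeric triple (train, validation, test) summing to 1.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param stratify Stratify on `labels`?
#' @return List of integer index vectors `train`, `validation`, `test`
#'   (disjoint, exhaustive).
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          stratify = FALSE) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    err_invalid_config("fractions must be a (train, validation, test) triple summing to 1")
  if (any(fractions < 0)) err_invalid_config("fractions must be nonnegative")
  # a bare sample count may stand in for labels when stratification is off
  n <- if (is.matrix(labels)) nrow(labels)
       else if (length(labels) == 1 && is.numeric(labels)) as.integer(labels)
       else length(labels)

  alloc <- function(idx) {
    m <- length(idx)
    n_val <- floor(m * fractions[2])
    n_test <- floor(m * fractions[3])
    perm <- sample(idx)
    taken <- seq_len(n_val + n_test)
    list(validation = sort(perm[seq_len(n_val)]),
         test = sort(perm[n_val + seq_len(n_test)]),
         train = sort(perm[setdiff(seq_along(perm), taken)]))
  }
  parts <- with_seed(seed, {
    if (stratify && length(labels) > 1) {
      key <- if (is.matrix(labels)) apply(labels, 1, paste, collapse = ",")
             else as.character(labels)
      per <- lapply(split(seq_len(n), key), alloc)
      list(train = sort(unlist(lapply(per, `[[`, "train"), use.names = FALSE)),
           validation = sort(unlist(lapply(per, `[[`, "validation"), use.names = FALSE)),
           test = sort(unlist(lapply(per, `[[`, "test"), use.names = FALSE)))
    } else {
      a <- alloc(seq_len(n))
      a[c("train", "validation", "test")]
    }
  })
  for (nm in c("train", "validation", "test"))
    if (fractions[match(nm, c("train", "validation", "test"))] > 0 &&
        length(parts[[nm]]) == 0)
      err_invalid_config("split '%s' would be empty (n = %d)", nm, n)
  parts
}

# Rank-free AUROC via pROC with a fixed orientation: scores are always
# "higher = more positive". Returns NA when only one class is present.
auroc_score <- function(truth, scores) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2) return(NA_real_)
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Area under the precision-recall curve as average precision:
# sum over ranked positives of precision at that rank, divided by the
# number of positives. NA when there are no positives or no negatives.
auprc_score <- function(truth, scores) {
  truth <- as.integer(truth)
  npos <- sum(truth == 1)
  if (npos == 0 || npos == length(truth)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- truth[ord]
  cum_tp <- cumsum(y)
  prec <- cum_tp / seq_along(y)
  sum(prec[y == 1]) / npos
}

binary_counts <- function(truth, pred) {
  c(tp = sum(truth == 1 & pred == 1), fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0), tn = sum(truth == 0 & pred == 0))
}

prf <- function(cts) {
  p <- if (cts["tp"] + cts["fp"] == 0) 0 else cts["tp"] / (cts["tp"] + cts["fp"])
  r <- if (cts["tp"] + cts["fn"] == 0) 0 else cts["tp"] / (cts["tp"] + cts["fn"])
  c(precision = unname(p), recall = unname(r))
}

#' Compute the six evaluation metrics
#'
#' Accuracy, AUPRC, AUROC, precision, recall and F-score. Binary decisions
#' use threshold 0.5; multiclass predictions are the arg-max class.
#' Multiclass and multilabel metrics are averaged across classes/labels in
#' `"macro"` (default), `"micro"` or `"weighted"` mode; ranking metrics
#' (AUROC, AUPRC) are macro-averaged one-vs-rest over the classes for which
#' they are defined. When the truth contains a single class, AUROC/AUPRC are
#' reported as `NA` rather than silently defaulting. The reported F-score is
#' the harmonic mean of the reported precision and recall.
#'
#' @param truth Binary 0/1 vector, integer classes `1..C`, or a binary
#'   label matrix (multilabel).
#' @param scores Score vector (binary) or samples x classes matrix.
#' @param task_kind `"binary"`, `"multiclass"` or `"multilabel"`.
#' @param average Averaging mode for multiclass/multilabel.
#' @param threshold Decision threshold for sigmoid scores (default 0.5).
#' @param split,seed Optional provenance fields echoed into the report.
#' @return Object of class `metrics_report` with fields `acc`, `auprc`,
#'   `auroc`, `precision`, `recall`, `f_score`, `averaging`, `threshold`,
#'   `task_kind`, `split`, `seed`.
#' @export
compute_metrics <- function(truth, scores,
                            task_kind = c("binary", "multiclass", "multilabel"),
                            average = c("macro", "micro", "weighted"),
                            threshold = 0.5, split = NA_character_,
                            seed = NA_integer_) {
  task_kind <- match.arg(task_kind)
  average <- match.arg(average)

  if (task_kind == "binary") {
    truth <- as.integer(truth)
    s <- if (is.matrix(scores)) scores[, ncol(scores)] else as.numeric(scores)
    if (length(s) != length(truth))
      err_invalid_input("truth and scores lengths differ (%d vs %d)",
                        length(truth), length(s))
    pred <- as.integer(s >= threshold)
    acc <- mean(pred == truth)
    pr <- prf(binary_counts(truth, pred))
    auroc <- auroc_score(truth, s)
    auprc <- auprc_score(truth, s)
  } else if (task_kind == "multiclass") {
    truth <- as.integer(truth)
    C <- ncol(scores)
    pred <- max.col(scores, ties.method = "first")
    acc <- mean(pred == truth)
    per <- t(vapply(seq_len(C), function(cl)
      c(prf(binary_counts(as.integer(truth == cl), as.integer(pred == cl))),
        n = sum(truth == cl)), numeric(3)))
    pr <- average_prf(per, average, truth, pred)
    aurocs <- vapply(seq_len(C), function(cl)
      auroc_score(as.integer(truth == cl), scores[, cl]), numeric(1))
    auprcs <- vapply(seq_len(C), function(cl)
      auprc_score(as.integer(truth == cl), scores[, cl]), numeric(1))
    auroc <- if (all(is.na(aurocs))) NA_real_ else mean(aurocs, na.rm = TRUE)
    auprc <- if (all(is.na(auprcs))) NA_real_ else mean(auprcs, na.rm = TRUE)
  } else {                                    # multilabel
    truth <- as.matrix(truth)
    L <- ncol(truth)
    pred <- matrix(as.integer(scores >= threshold), nrow(truth), L)
    acc <- mean(pred == truth)                # elementwise (Hamming) accuracy
    per <- t(vapply(seq_len(L), function(l)
      c(prf(binary_counts(truth[, l], pred[, l])), n = sum(truth[, l])),
      numeric(3)))
    pr <- average_prf(per, average, NULL, NULL, truth, pred)
    aurocs <- vapply(seq_len(L), function(l)
      auroc_score(truth[, l], scores[, l]), numeric(1))
    auprcs <- vapply(seq_len(L), function(l)
      auprc_score(truth[, l], scores[, l]), numeric(1))
    auroc <- if (all(is.na(aurocs))) NA_real_ else mean(aurocs, na.rm = TRUE)
    auprc <- if (all(is.na(auprcs))) NA_real_ else mean(auprcs, na.rm = TRUE)
  }

  p <- unname(pr["precision"]); r <- unname(pr["recall"])
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  structure(list(acc = acc, auprc = auprc, auroc = auroc, precision = p,
                 recall = r, f_score = f, averaging = average,
                 threshold = threshold, task_kind = task_kind,
                 split = split, seed = seed),
            class = "metrics_report")
}

average_prf <- function(per, average, truth, pred,
                        truth_mat = NULL, pred_mat = NULL) {
  if (average == "macro") {
    c(precision = mean(per[, "precision"]), recall = mean(per[, "recall"]))
  } else if (average == "weighted") {
    w <- per[, "n"] / sum(per[, "n"])
    c(precision = sum(w * per[, "precision"]), recall = sum(w * per[, "recall"]))
  } else {                                    # micro
    if (!is.null(truth_mat)) {
      cts <- binary_counts(as.vector(truth_mat), as.vector(pred_mat))
    } else {
      C <- nrow(per)
      cts <- Reduce(`+`, lapply(seq_len(C), function(cl)
        binary_counts(as.integer(truth == cl), as.integer(pred == cl))))
    }
    prf(cts)
  }
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> [%s, %s]\n", x$task_kind, x$averaging))
  for (m in c("acc", "auprc", "auroc", "precision", "recall", "f_score"))
    cat(sprintf("  %-9s %s\n", m,
                ifelse(is.na(x[[m]]), "NA", sprintf("%.4f", x[[m]]))))
  invisible(x)
}

#' Serialize a metrics report as JSON
#'
#' Includes the configuration echo (averaging mode, threshold, split id,
#' seed) for provenance.
#'
#' @param report A [compute_metrics()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}
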