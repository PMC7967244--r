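## Clinical indexes, ROC/AUC and the Mann-Whitney U comparison.

#' Clinical indexes from a binary confusion matrix
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN), all as percentages. Rows are true classes,
#' columns predicted. A zero denominator yields `NA` (explicit undefined),
#' never an error.
#'
#' @param cm 2 x 2 count matrix with matching row/column names.
#' @param positive Name of the positive class (default `"MI"`).
#' @return List with elements `acc`, `sen`, `spe`, `f1` (percent) and the
#'   counts `tp`, `tn`, `fp`, `fn`.
#' @export
clinical_indexes <- function(cm, positive = "MI") {
  cm <- as.matrix(unclass(cm))
  if (!all(dim(cm) == c(2, 2))) stop_ecgmi("clinical_indexes needs a 2 x 2 matrix")
  if (!is.null(rownames(cm)) && positive %in% rownames(cm)) {
    neg <- setdiff(rownames(cm), positive)
    cm <- cm[c(positive, neg), c(positive, neg)]
  }
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(acc = div(tp + tn, tp + tn + fp + fn),
       sen = div(tp, tp + fn),
       spe = div(tn, tn + fp),
       f1 = div(2 * tp, 2 * tp + fp + fn),
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Multiclass accuracy
#'
#' Trace over total of a C x C confusion matrix, in percent.
#'
#' @param cm Square count matrix (rows true, columns predicted).
#' @return Accuracy percentage.
#' @export
multiclass_accuracy <- function(cm) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) != ncol(cm) || nrow(cm) == 0) stop_ecgmi("need a non-empty square matrix")
  total <- sum(cm)
  if (total == 0) stop_ecgmi("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' ROC curve and AUC
#'
#' The AUC is computed as the rank statistic: the probability that a random
#' positive outscores a random negative, ties counted one half — identical
#' to U / (n_pos * n_neg) for the Mann-Whitney U of the positive scores.
#' The curve is the stepwise (FPR, TPR) path over decreasing score
#' thresholds.
#'
#' @param scores Predicted probability of the positive class.
#' @param labels Logical (or 0/1) vector, `TRUE` for positives.
#' @return List with `curve` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_curve_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_ecgmi("both classes must be present")
  r <- rank(scores)                       # midranks
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(curve = curve, auc = auc)
}

## Exact null distribution of the Mann-Whitney U statistic for sample sizes
## (n, m): frequency of each U value over all C(n+m, n) equally likely rank
## assignments, by subset-sum dynamic programming over the ranks 1..n+m.
u_null_frequencies <- function(n, m) {
  N <- n + m
  max_w <- sum((m + 1):N)                    # largest possible rank sum of a
  f <- matrix(0, n + 1, max_w + 1)
  f[1, 1] <- 1
  for (i in seq_len(N))
    for (j in min(i, n):1)
      f[j + 1, (i + 1):(max_w + 1)] <- f[j + 1, (i + 1):(max_w + 1)] +
        f[j, 1:(max_w + 1 - i)]
  offset <- n * (n + 1) / 2                  # U = rank sum - offset
  f[n + 1, (offset + 1):(offset + n * m + 1)]
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. The p-value is exact (full
#' enumeration of the null distribution of U) when both samples have at
#' most 20 observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Significance stars: p < 0.05 `*`, p < 0.01 `**`, p < 0.001 `***`.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `a`
#'   relative to `b`).
#' @return List with `u` (statistic of sample `a`), `p`, `method`
#'   (`"exact"` or `"normal"`) and `stars`.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop_ecgmi("both samples must be non-empty")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n <= 20 && m <= 20) {
    freq <- u_null_frequencies(n, m)
    total <- sum(freq)
    p_le <- sum(freq[seq_len(u + 1)]) / total
    p_ge <- sum(freq[(u + 1):length(freq)]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    method <- "exact"
  } else {
    mu <- n * m / 2
    tie_tab <- table(c(a, b))
    nt <- n + m
    sigma2 <- n * m / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      cc <- 0.5
      p <- switch(alternative,
        two.sided = 2 * stats::pnorm((max(abs(u - mu) - cc, 0)) / sigma,
                                     lower.tail = FALSE),
        less = stats::pnorm((u - mu + cc) / sigma),
        greater = stats::pnorm((u - mu - cc) / sigma, lower.tail = FALSE))
      p <- min(1, p)
    }
    method <- "normal"
  }
  list(u = u, p = p, method = method, stars = significance_stars(p))
}

#' Significance stars
#'
#' @param p p-value.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare two models over repeated-CV metric vectors
#'
#' Per clinical index (ACC for all tasks; SEN, SPE, F1 and AUC for
#' detection), reports mean, standard deviation, box-plot five-number
#' summary, and the Mann-Whitney U with p and star rating. Accepts
#' `cv_result` objects or plain data.frames / named lists of per-repeat
#' vectors, so externally produced accuracy vectors (e.g. published
#' comparator models rerun elsewhere) can be compared without
#' re-implementation.
#'
#' @param a,b `cv_result` objects or data.frames with per-repeat index
#'   columns (`acc`, and for detection `sen`, `spe`, `f1`, `auc`).
#' @param task `"detection"` or `"locating"`; inferred from `cv_result`
#'   inputs.
#' @return Object of class `model_comparison`: data.frame with one row per
#'   index.
#' @export
compare_models <- function(a, b, task = NULL) {
  get_tab <- function(x) {
    if (inherits(x, "cv_result")) x$metrics
    else as.data.frame(x)
  }
  if (is.null(task)) {
    task <- if (inherits(a, "cv_result")) a$task
            else if (inherits(b, "cv_result")) b$task
            else if (all(c("sen", "spe") %in% names(get_tab(a)))) "detection"
            else "locating"
  }
  ta <- get_tab(a); tb <- get_tab(b)
  if (nrow(ta) != nrow(tb))
    stop_ecgmi("repeat counts differ: %d vs %d", nrow(ta), nrow(tb))
  idx <- if (task == "detection") c("acc", "sen", "spe", "f1", "auc") else "acc"
  idx <- idx[idx %in% names(ta) & idx %in% names(tb)]
  rows <- lapply(idx, function(ix) {
    va <- ta[[ix]]; vb <- tb[[ix]]
    fa <- stats::fivenum(va); fb <- stats::fivenum(vb)
    u <- mann_whitney_u(va, vb)
    data.frame(index = ix,
               mean_a = mean(va), sd_a = stats::sd(va),
               mean_b = mean(vb), sd_b = stats::sd(vb),
               median_a = fa[3], iqr_lo_a = fa[2], iqr_hi_a = fa[4],
               median_b = fb[3], iqr_lo_b = fb[2], iqr_hi_b = fb[4],
               u = u$u, p = u$p, stars = u$stars,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("model_comparison", "data.frame"),
            task = task)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s task), Mann-Whitney U on per-repeat indexes:\n",
              attr(x, "task")))
  df <- as.data.frame(x)
  df$mean_a <- sprintf("%.2f", df$mean_a); df$mean_b <- sprintf("%.2f", df$mean_b)
  print(df[, c("index", "mean_a", "mean_b", "u", "p", "stars")], row.names = FALSE)
  invisible(x)
}
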