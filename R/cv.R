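## Repeated subject-disjoint cross-validation and the (scales x filters)
## grid search.

#' Repeated subject-based k-fold cross-validation
#'
#' For each repeat, a fresh subject-disjoint fold assignment is drawn
#' (seed `base_seed + repeat`), the network is trained on k-1 folds and
#' predictions on the held-out fold are pooled over folds into one
#' confusion matrix per repeat. Weight-initialization seeds differ across
#' repeats; the within-epoch data order for a given repeat is shared across
#' model configurations. A leakage audit runs on every split.
#'
#' @param config A [model_config()].
#' @param bundle An `ecg_bundle` (split optional: re-split per repeat).
#' @param k Folds (default 5).
#' @param repeats Number of repeated CV rounds (15 in the full protocol).
#' @param base_seed Base seed; repeat r uses `base_seed + r` for its split.
#' @param train A [train_config()].
#' @param resplit If `FALSE`, the bundle's existing fold assignment is
#'   reused in every repeat and only the weight initialization varies.
#' @param keep_scores Keep pooled positive-class scores per repeat (needed
#'   for ROC/AUC on detection tasks).
#' @return Object of class `cv_result`: per-repeat confusion matrices,
#'   per-repeat metric rows, and the configuration.
#' @export
repeated_cv <- function(config, bundle, k = 5, repeats = 1, base_seed = 1,
                        train = train_config(), resplit = TRUE,
                        keep_scores = TRUE) {
  stopifnot(inherits(bundle, "ecg_bundle"))
  classes <- bundle$classes
  meta <- bundle$beats$meta
  n <- nrow(meta)
  confusions <- vector("list", repeats)
  scores <- vector("list", repeats)
  metrics <- vector("list", repeats)
  positive <- if (bundle$task == "detection") "MI" else NA_character_

  for (r in seq_len(repeats)) {
    split_seed <- base_seed + r
    b <- if (resplit || is.null(bundle$folds))
      subject_kfold_split(bundle, k, seed = split_seed) else bundle
    audit_leakage(b)
    fold_of <- b$folds[meta$patient_id]
    pred <- character(n)
    score <- numeric(n)
    for (f in sort(unique(fold_of))) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      fit <- mi_net(bundle$beats$x[, , train_idx, drop = FALSE],
                    meta$label[train_idx], config = config, train = train,
                    seed = derive_seed(base_seed, "w", r, f),
                    order_seed = derive_seed(base_seed, "ord", r),
                    classes = classes)
      probs <- predict(fit, bundle$beats$x[, , test_idx, drop = FALSE])
      pred[test_idx] <- classes[max.col(probs, ties.method = "first")]
      if (!is.na(positive)) score[test_idx] <- probs[, positive]
    }
    cm <- table(factor(meta$label, classes), factor(pred, classes))
    confusions[[r]] <- unclass(cm)
    scores[[r]] <- if (keep_scores && !is.na(positive))
      data.frame(score = score, label = meta$label) else NULL
    row <- if (bundle$task == "detection") {
      ms <- clinical_indexes(cm, positive = positive)
      auc <- if (keep_scores)
        roc_curve_auc(score, meta$label == positive)$auc else NA_real_
      data.frame(repeat_id = r, acc = ms$acc, sen = ms$sen, spe = ms$spe,
                 f1 = ms$f1, auc = auc)
    } else {
      data.frame(repeat_id = r, acc = multiclass_accuracy(cm))
    }
    metrics[[r]] <- row
  }
  structure(list(config = config, task = bundle$task, k = as.integer(k),
                 repeats = as.integer(repeats), base_seed = base_seed,
                 confusions = confusions, metrics = do.call(rbind, metrics),
                 scores = scores, n_pieces = n), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result  %s  S=%d F=%d  %d-fold x %d repeats  mean ACC %.2f%% (sd %.2f)>\n",
              x$task, x$config$scales, x$config$filters, x$k, x$repeats,
              mean(x$metrics$acc), stats::sd(x$metrics$acc)))
  invisible(x)
}

#' Grid search over scales and filters
#'
#' Runs [repeated_cv()] for every configuration of [enumerate_grid()] (or a
#' restricted subgrid) and summarizes the per-repeat accuracy surface. The
#' best configuration maximizes mean accuracy; ties break toward fewer
#' parameters.
#'
#' @param task `"detection"` or `"locating"`; must match the bundle.
#' @param bundle An `ecg_bundle`.
#' @param k,repeats,base_seed,train As in [repeated_cv()].
#' @param scales,filters Optional subgrid restriction.
#' @return Object of class `grid_result`: `surface` (data.frame scales,
#'   filters, mean_acc, sd_acc, n_parameters), `best` (row of surface), and
#'   the per-config `cv` results.
#' @export
grid_search <- function(task, bundle, k = 5, repeats = 1, base_seed = 1,
                        train = train_config(), scales = NULL, filters = NULL) {
  task <- match.arg(task, c("detection", "locating"))
  if (task != bundle$task) stop_ecgmi("bundle task is %s, not %s", bundle$task, task)
  grid <- enumerate_grid(task, scales = scales, filters = filters)
  cvs <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    cv <- repeated_cv(cfg, bundle, k = k, repeats = repeats,
                      base_seed = base_seed, train = train, keep_scores = FALSE)
    cvs[[i]] <- cv
    rows[[i]] <- data.frame(scales = cfg$scales, filters = cfg$filters,
                            mean_acc = mean(cv$metrics$acc),
                            sd_acc = stats::sd(cv$metrics$acc),
                            n_parameters = count_parameters(cfg))
  }
  surface <- do.call(rbind, rows)
  ord <- order(-surface$mean_acc, surface$n_parameters)
  structure(list(task = task, surface = surface, best = surface[ord[1], ],
                 cv = cvs, k = k, repeats = repeats, base_seed = base_seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result  %s  %d configurations  best S=%d F=%d at %.2f%%>\n",
              x$task, nrow(x$surface), x$best$scales, x$best$filters,
              x$best$mean_acc))
  print(x$surface, row.names = FALSE)
  invisible(x)
}
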