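## Balanced dataset construction and subject-disjoint k-fold splitting.
##
## Random undersampling at two levels: a fixed number of records per class,
## then a fixed number of beat windows ("pieces") per record. The 6-class
## locating dataset keeps all classes; the 2-class detection dataset keeps
## every HC piece and a per-record subsample of each MI record so that
## HC and MI piece counts are equal.

#' Undersampling plan
#'
#' @param records_per_class Records retained per class (40 at full scale).
#' @param pieces_per_record Beat windows retained per record in the locating
#'   dataset (30 at full scale).
#' @param detection_pieces Windows retained per MI record in the detection
#'   dataset (6 at full scale). Class balance requires
#'   `detection_pieces * 5 == pieces_per_record`, because every HC piece is
#'   kept while the five MI classes are pooled.
#' @param seed Selection seed.
#' @return Object of class `selection_plan`.
#' @export
selection_plan <- function(records_per_class = 40, pieces_per_record = 30,
                           detection_pieces = 6, seed = 1) {
  stopifnot(records_per_class >= 1, pieces_per_record >= 1, detection_pieces >= 1)
  if (detection_pieces > pieces_per_record)
    stop_ecgmi("detection_pieces must be <= pieces_per_record")
  structure(list(records_per_class = as.integer(records_per_class),
                 pieces_per_record = as.integer(pieces_per_record),
                 detection_pieces = as.integer(detection_pieces),
                 seed = as.integer(seed)), class = "selection_plan")
}

#' Select records per class by seeded undersampling
#'
#' Uniform seeded selection of exactly `records_per_class` eligible records
#' in every class. A record is eligible when it has at least
#' `pieces_per_record` beat windows; ineligible records are logged in the
#' result. Records whose class is not one of the six study classes
#' (e.g. "excluded") never enter.
#'
#' @param beats A `beat_set` for the whole cohort.
#' @param plan A [selection_plan()].
#' @return List with `records` (data.frame record_id, patient_id, class,
#'   n_pieces of the selected records) and `ineligible` (same columns).
#' @export
select_records <- function(beats, plan) {
  meta <- beats$meta
  meta <- meta[meta$class %in% ECG_CLASSES, , drop = FALSE]
  tab <- unique(meta[, c("record_id", "patient_id", "class")])
  tab$n_pieces <- as.integer(table(meta$record_id)[tab$record_id])
  eligible <- tab[tab$n_pieces >= plan$pieces_per_record, , drop = FALSE]
  chosen <- list()
  for (cl in ECG_CLASSES) {
    cand <- eligible[eligible$class == cl, , drop = FALSE]
    if (nrow(cand) < plan$records_per_class)
      stop_ecgmi("class %s: only %d eligible records, need %d",
                 cl, nrow(cand), plan$records_per_class)
    idx <- with_seed(derive_seed(plan$seed, "records", match(cl, ECG_CLASSES)),
                     sample(nrow(cand), plan$records_per_class))
    chosen[[cl]] <- cand[sort(idx), , drop = FALSE]
  }
  list(records = do.call(rbind, chosen),
       ineligible = tab[tab$n_pieces < plan$pieces_per_record, , drop = FALSE])
}

## Subset a beat_set by row indices of its meta table.
subset_beats <- function(beats, idx) {
  structure(list(x = beats$x[, , idx, drop = FALSE],
                 meta = beats$meta[idx, , drop = FALSE],
                 n_dropped = beats$n_dropped,
                 r_in_segment = beats$r_in_segment), class = "beat_set")
}

#' Build the balanced 6-class locating dataset
#'
#' For every selected record, a seeded uniform choice of exactly
#' `pieces_per_record` beat windows. At full scale (6 classes x 40 records
#' x 30 pieces) this yields 7200 pieces, 1200 per class.
#'
#' @param beats Cohort `beat_set`.
#' @param plan A [selection_plan()].
#' @param selection Optional result of [select_records()]; computed if
#'   missing.
#' @return An `ecg_bundle` with task `"locating"`.
#' @export
build_locating_dataset <- function(beats, plan, selection = NULL) {
  if (is.null(selection)) selection <- select_records(beats, plan)
  recs <- selection$records
  keep <- integer(0)
  for (i in seq_len(nrow(recs))) {
    rows <- which(beats$meta$record_id == recs$record_id[i])
    if (length(rows) < plan$pieces_per_record)
      stop_ecgmi("record %s has %d pieces, need %d (should have been filtered)",
                 recs$record_id[i], length(rows), plan$pieces_per_record)
    sel <- with_seed(derive_seed(plan$seed, "pieces", i),
                     sample(length(rows), plan$pieces_per_record))
    keep <- c(keep, rows[sort(sel)])
  }
  bundle <- subset_beats(beats, keep)
  bundle$meta$label <- bundle$meta$class
  out <- structure(list(task = "locating", beats = bundle,
                        classes = ECG_CLASSES, plan = plan,
                        folds = NULL, k = NULL), class = "ecg_bundle")
  check_balance(out)
  out
}

#' Build the balanced 2-class detection dataset
#'
#' Reuses the locating selection: HC records keep all their pieces, every
#' MI record contributes a seeded uniform subsample of `detection_pieces`
#' windows, and labels collapse to HC vs MI. Class balance
#' (`|HC| == |MI|`) requires `detection_pieces * 5 == pieces_per_record`
#' and is asserted.
#'
#' @param locating An `ecg_bundle` with task `"locating"`.
#' @return An `ecg_bundle` with task `"detection"`.
#' @export
build_detection_dataset <- function(locating) {
  stopifnot(inherits(locating, "ecg_bundle"), locating$task == "locating")
  plan <- locating$plan
  meta <- locating$beats$meta
  keep <- which(meta$class == "HC")
  mi_records <- unique(meta$record_id[meta$class != "HC"])
  for (i in seq_along(mi_records)) {
    rows <- which(meta$record_id == mi_records[i])
    sel <- with_seed(derive_seed(plan$seed, "detect", i),
                     sample(length(rows), plan$detection_pieces))
    keep <- c(keep, rows[sort(sel)])
  }
  bundle <- subset_beats(locating$beats, sort(keep))
  bundle$meta$label <- ifelse(bundle$meta$class == "HC", "HC", "MI")
  n_hc <- sum(bundle$meta$label == "HC"); n_mi <- sum(bundle$meta$label == "MI")
  if (n_hc != n_mi)
    stop_ecgmi("detection dataset unbalanced: %d HC vs %d MI (need detection_pieces * 5 == pieces_per_record)",
               n_hc, n_mi)
  structure(list(task = "detection", beats = bundle, classes = c("HC", "MI"),
                 plan = plan, folds = NULL, k = NULL), class = "ecg_bundle")
}

check_balance <- function(bundle) {
  counts <- table(bundle$beats$meta$label)
  if (length(unique(as.integer(counts))) != 1)
    stop_ecgmi("class piece counts differ: %s",
               paste(names(counts), counts, sep = "=", collapse = ", "))
  invisible(TRUE)
}

#' Subject-disjoint k-fold assignment
#'
#' Assigns whole patients to folds: within each class, patients are shuffled
#' (seeded) and each is placed on the currently lightest fold by piece
#' count, so per-fold class piece counts differ by at most one patient's
#' contribution and no patient ever spans folds.
#'
#' @param bundle An `ecg_bundle`.
#' @param k Number of folds (>= 2); every class must have at least k
#'   patients.
#' @param seed Split seed.
#' @return The bundle with `folds` (named integer vector patient -> fold in
#'   0..k-1) and `k` set.
#' @export
subject_kfold_split <- function(bundle, k, seed = 1) {
  stopifnot(inherits(bundle, "ecg_bundle"), k >= 2)
  meta <- bundle$beats$meta
  folds <- integer(0)
  for (cl in unique(meta$class)) {
    sub <- meta[meta$class == cl, , drop = FALSE]
    pats <- unique(sub$patient_id)
    if (length(pats) < k)
      stop_ecgmi("class %s has %d patients, need at least k = %d", cl, length(pats), k)
    ord <- with_seed(derive_seed(seed, "fold", match(cl, c(ECG_CLASSES, "MI"))),
                     sample(length(pats)))
    load <- rep(0L, k)
    for (p in pats[ord]) {
      f <- which.min(load)
      folds[p] <- f - 1L
      load[f] <- load[f] + sum(sub$patient_id == p)
    }
  }
  bundle$folds <- folds
  bundle$k <- as.integer(k)
  bundle$split_seed <- as.integer(seed)
  audit_leakage(bundle)
  bundle
}

#' Leakage audit
#'
#' Asserts that every patient appears in exactly one fold and that for every
#' train/test fold pair the patient-ID intersection is empty. Run
#' automatically on every split; exported so pipelines can re-assert.
#'
#' @param bundle A split `ecg_bundle`.
#' @return `TRUE` invisibly; error on any leakage.
#' @export
audit_leakage <- function(bundle) {
  stopifnot(!is.null(bundle$folds))
  meta <- bundle$beats$meta
  pats <- unique(meta$patient_id)
  if (!all(pats %in% names(bundle$folds)))
    stop_ecgmi("patients missing from fold assignment")
  per_piece <- bundle$folds[meta$patient_id]
  for (f in sort(unique(bundle$folds))) {
    test_p <- unique(meta$patient_id[per_piece == f])
    train_p <- unique(meta$patient_id[per_piece != f])
    if (length(intersect(test_p, train_p)))
      stop_ecgmi("leakage: patients shared between fold %d and its complement", f)
  }
  invisible(TRUE)
}

#' @export
print.ecg_bundle <- function(x, ...) {
  counts <- table(x$beats$meta$label)
  cat(sprintf("<ecg_bundle  task %s  %d pieces (%s)  %d patients%s>\n",
              x$task, nrow(x$beats$meta),
              paste(names(counts), counts, sep = ":", collapse = " "),
              length(unique(x$beats$meta$patient_id)),
              if (!is.null(x$k)) sprintf("  k=%d folds", x$k) else ""))
  invisible(x)
}

#' One-call dataset construction from a cohort spec
#'
#' Generates the cohort, preprocesses it, undersamples to a balanced
#' dataset for the requested task and attaches a subject-disjoint k-fold
#' split.
#'
#' @param spec A [cohort_spec()].
#' @param task `"detection"` or `"locating"`.
#' @param plan A [selection_plan()].
#' @param k Folds (default 5).
#' @param seed Split seed.
#' @param config Preprocessing configuration.
#' @param beats Optional precomputed cohort `beat_set` (skips generation).
#' @return A split `ecg_bundle`.
#' @export
build_dataset <- function(spec, task = c("detection", "locating"),
                          plan = selection_plan(), k = 5, seed = 1,
                          config = preprocess_config(), beats = NULL) {
  task <- match.arg(task)
  if (is.null(beats)) beats <- cohort_segments(spec, config)
  loc <- build_locating_dataset(beats, plan)
  bundle <- if (task == "locating") loc else build_detection_dataset(loc)
  subject_kfold_split(bundle, k, seed)
}
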