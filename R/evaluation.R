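#' Tissue-type roster and annotation codes
#'
#' The twelve annotation classes and their integer mask codes: nine
#' cancerous Gleason-pattern / extension types and three non-cancerous
#' confounders. Code 0 is reserved for unannotated background.
#'
#' @return data frame with columns `code`, `type`, `cancerous`,
#'   `highgrade_g4` (positive source for the G4-vs-G3 experiment) and
#'   `highgrade_g45` (positive source for the G4&G5-vs-G3 experiment).
#' @export
tissue_types <- function() {
  data.frame(
    code = 1:12,
    type = c("G3", "G3+4", "G4+3", "G4", "G4+5", "G5+4", "G5", "G5+3",
             "EPE", "Atrophy", "PIN", "Healthy/BPH"),
    cancerous = c(rep(TRUE, 9), rep(FALSE, 3)),
    highgrade_g4 = c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, 8)),
    highgrade_g45 = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                      rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
}

#' Label ROIs from an annotation mask
#'
#' Tiles an integer annotation mask into ROIs (side `roi_size_um /
#' pixel_size_um` pixels; partial edge tiles dropped) and derives per-tile
#' labels by area fraction with the 0.5 rule:
#' * `detection_label` — TRUE iff the summed fraction of cancerous codes is
#'   at or above `label_threshold` (exact halves count as positive, so ties
#'   resolve deterministically);
#' * `grading_label_g4` — TRUE iff the G4 fraction reaches the threshold,
#'   FALSE iff the G3 fraction does, NA otherwise (ineligible; this
#'   excludes mixed G3+4 / G4+3 regions, which are used for detection only);
#' * `grading_label_g45` — as above with G4, G4+5, G5, G5+4 pooled as the
#'   positive source (G5+3 and EPE stay out of grading).
#'
#' `tissue_type` is the majority annotation code of the tile.
#'
#' @param annotation_mask integer matrix of codes (0 = background, 1..12 per
#'   [tissue_types()]), aligned to the slide at scan resolution.
#' @param config a [pipeline_config()].
#' @param patient_id,slide_id identifiers copied into the records.
#' @return data frame of ROI records, one row per complete tile, with tile
#'   origin columns `roi_row`, `roi_col` (0-based pixel offsets).
#' @export
label_rois <- function(annotation_mask, config = pipeline_config(),
                       patient_id = NA, slide_id = NA) {
  mask <- as.matrix(annotation_mask)
  codes <- sort(unique(as.integer(mask)))
  roster <- tissue_types()
  bad <- setdiff(codes, c(0L, roster$code))
  if (length(bad)) {
    stop("unknown annotation code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  side <- roi_side_px(config)
  grid <- tile_grid(dim(mask), side)
  thr <- config$label_threshold
  cancer_codes <- roster$code[roster$cancerous]
  g4_codes <- roster$code[roster$highgrade_g4]
  g45_codes <- roster$code[roster$highgrade_g45]
  g3_code <- roster$code[roster$type == "G3"]
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    r0 <- grid$roi_row[i]; c0 <- grid$roi_col[i]
    tile <- mask[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side)]
    f <- tabulate(tile + 1L, 13L) / length(tile)   # f[1] = background, f[c+1] = code c
    cancer_fr <- sum(f[cancer_codes + 1L])
    g4_fr <- sum(f[g4_codes + 1L])
    g45_fr <- sum(f[g45_codes + 1L])
    g3_fr <- f[g3_code + 1L]
    maj <- which.max(f[-1L])                        # majority non-background code
    data.frame(
      patient_id = patient_id, slide_id = slide_id,
      roi_row = r0, roi_col = c0,
      tissue_type = if (f[maj + 1L] > 0) roster$type[roster$code == maj] else NA_character_,
      cancer_fraction = cancer_fr,
      highgrade_fraction = g45_fr,
      detection_label = cancer_fr >= thr,
      grading_label_g4 = if (g4_fr >= thr) TRUE else if (g3_fr >= thr) FALSE else NA,
      grading_label_g45 = if (g45_fr >= thr) TRUE else if (g3_fr >= thr) FALSE else NA,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, recs)
}

tile_grid <- function(dims, side) {
  nr <- dims[1] %/% side
  nc <- dims[2] %/% side
  if (nr < 1L || nc < 1L) {
    stop(sprintf("slide (%d x %d) holds no complete %d px tile",
                 dims[1], dims[2], side), call. = FALSE)
  }
  expand.grid(roi_col = (seq_len(nc) - 1L) * side,
              roi_row = (seq_len(nr) - 1L) * side)[, 2:1]
}

#' Leave-one-patient-out folds
#'
#' One fold per patient: that patient's ROIs form the test set, all other
#' patients' the training set. Guarantees by construction that no patient
#' contributes to both sides of any fold.
#'
#' @param patient_ids vector, one id per ROI.
#' @return list of folds, each `list(patient, train, test)` with row
#'   indices.
#' @export
lopo_folds <- function(patient_ids) {
  ids <- unique(patient_ids)
  if (length(ids) < 2L) stop("leave-one-patient-out needs >= 2 patients", call. = FALSE)
  lapply(ids, function(p) {
    test <- which(patient_ids == p)
    list(patient = p, train = setdiff(seq_along(patient_ids), test), test = test)
  })
}

#' Assert patient integrity of a fold list
#'
#' Errors if any fold shares a patient between training and test rows, if a
#' ROI is tested more than once, or if any ROI is never tested.
#' @param folds list from [lopo_folds()].
#' @param patient_ids the id vector the folds were built from.
#' @return invisibly TRUE.
#' @export
assert_patient_integrity <- function(folds, patient_ids) {
  tested <- integer(0)
  for (f in folds) {
    overlap <- intersect(unique(patient_ids[f$train]), unique(patient_ids[f$test]))
    if (length(overlap)) {
      stop("patient(s) in both train and test: ", paste(overlap, collapse = ", "),
           call. = FALSE)
    }
    tested <- c(tested, f$test)
  }
  if (anyDuplicated(tested) || length(tested) != length(patient_ids)) {
    stop("each ROI must be tested exactly once", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pooled ROC curve and AUC
#'
#' Sweeps the unique confidence values as thresholds over the pooled
#' predictions (cumulative across folds, not averaged per fold) and
#' integrates the ROC by trapezoid, which handles tied scores by the
#' half-credit concordance convention.
#'
#' @param confidences numeric scores.
#' @param labels logical vector.
#' @return list with `auc` and `roc` (data frame of `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(confidences, labels) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) stop("both classes required for a ROC", call. = FALSE)
  if (length(confidences) != length(y)) stop("length mismatch", call. = FALSE)
  o <- order(confidences, decreasing = TRUE)
  s <- confidences[o]; ys <- y[o]
  keep <- c(diff(s) != 0, TRUE)          # last index of each tied block
  tp <- cumsum(ys)[keep]
  fp <- cumsum(!ys)[keep]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr))
}

#' Error metrics at a fixed operating point
#'
#' @param confidences numeric scores in [0, 1].
#' @param labels logical vector.
#' @param operating_point cutoff; predicted positive iff
#'   `confidence >= operating_point`.
#' @return list with `error_rate` = (FN+FP)/N, `fnr` = FN/(FN+TP),
#'   `fpr` = FP/(FP+TN) and the confusion counts.
#' @export
error_metrics <- function(confidences, labels, operating_point = 0.5) {
  y <- as.logical(labels)
  if (!length(y)) stop("empty input", call. = FALSE)
  pred <- confidences >= operating_point
  fn <- sum(y & !pred); fp <- sum(!y & pred)
  tp <- sum(y & pred); tn <- sum(!y & !pred)
  list(error_rate = (fn + fp) / length(y),
       fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Per-tissue-type error rates
#'
#' For each tissue type, the error rate of the detector restricted to that
#' type's ROIs: a false-negative rate for cancerous types (computed over
#' the type's label-positive ROIs) and a false-positive rate for
#' non-cancerous types (over its label-negative ROIs). `n` counts all ROIs
#' of the type, so the column sums to the cohort size.
#'
#' @param records ROI record data frame from [label_rois()] (needs
#'   `tissue_type` and `detection_label`).
#' @param confidences pooled confidences aligned to `records` rows.
#' @param operating_point hard-label cutoff.
#' @return data frame `tissue_type`, `metric`, `error_rate`, `n`.
#' @export
per_tissue_error <- function(records, confidences, operating_point = 0.5) {
  roster <- tissue_types()
  bad <- setdiff(unique(records$tissue_type), c(roster$type, NA))
  if (length(bad)) stop("unknown tissue type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  pred <- confidences >= operating_point
  types <- roster$type[roster$type %in% records$tissue_type]
  rows <- lapply(types, function(tt) {
    sel <- which(records$tissue_type == tt)
    canc <- roster$cancerous[roster$type == tt]
    eligible <- sel[records$detection_label[sel] == canc]
    err <- if (length(eligible)) mean(pred[eligible] != canc) else NA_real_
    data.frame(tissue_type = tt, metric = if (canc) "FNR" else "FPR",
               error_rate = err, n = length(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a leave-one-patient-out experiment
#'
#' The full evaluation loop: per fold, balance the training ROIs (negative
#' subsampling for detection, minority duplication for grading), train the
#' requested classifier and score every test ROI; then pool all confidences
#' into one ROC/AUC, the cumulative error metrics at the operating point,
#' and (when tissue types are available) the per-tissue-type error table.
#'
#' @param features numeric matrix (ROIs x features).
#' @param labels logical vector; rows with NA are used for neither training
#'   nor scoring.
#' @param patient_ids vector, one id per ROI.
#' @param kind classifier kind, see [train_classifier()].
#' @param task `"detection"` or `"grading"`; also selects the balancing rule.
#' @param records optional ROI record data frame for the per-tissue table.
#' @param operating_point hard-label cutoff.
#' @return object of class `eval_report`: list with `auc`, `roc`,
#'   `error_rate`, `fnr`, `fpr`, `counts`, `per_tissue`, `confidences`
#'   (NA for unscored rows), `fold_log`.
#' @export
evaluate_lopo <- function(features, labels, patient_ids,
                          kind = "fisher", task = c("detection", "grading"),
                          records = NULL, operating_point = 0.5) {
  task <- match.arg(task)
  x <- as.matrix(features)
  y <- as.logical(labels)
  usable <- which(!is.na(y))
  folds <- lopo_folds(patient_ids)
  assert_patient_integrity(folds, patient_ids)
  conf <- rep(NA_real_, length(y))
  fold_log <- data.frame(patient = character(0), n_train = integer(0),
                         n_test = integer(0), stringsAsFactors = FALSE)
  for (f in folds) {
    tr <- intersect(f$train, usable)
    te <- intersect(f$test, usable)
    if (!length(te)) next
    if (length(unique(y[tr])) < 2L) {
      warning(sprintf("fold for patient %s: single-class training data; skipped",
                      f$patient))
      next
    }
    bal <- suppressWarnings(
      if (task == "detection") balance_for_detection(y[tr]) else
        balance_for_grading(y[tr]))
    tr_bal <- tr[bal]
    # fold-level fit diagnostics (ridge fallback etc.) would repeat once per
    # patient; the fold log carries the information instead
    fit <- suppressWarnings(
      train_classifier(kind, x[tr_bal, , drop = FALSE], y[tr_bal], task = task))
    conf[te] <- predict(fit, x[te, , drop = FALSE])
    fold_log <- rbind(fold_log, data.frame(patient = as.character(f$patient),
                                           n_train = length(tr_bal),
                                           n_test = length(te)))
  }
  scored <- which(!is.na(conf))
  roc <- roc_auc(conf[scored], y[scored])
  em <- error_metrics(conf[scored], y[scored], operating_point)
  per_tissue <- if (!is.null(records)) {
    per_tissue_error(records[scored, , drop = FALSE], conf[scored], operating_point)
  } else NULL
  structure(list(kind = kind, task = task, auc = roc$auc, roc = roc$roc,
                 error_rate = em$error_rate, fnr = em$fnr, fpr = em$fpr,
                 counts = em$counts, per_tissue = per_tissue,
                 confidences = conf, fold_log = fold_log),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s/%s> AUC %.3f | error %.1f%% FNR %.1f%% FPR %.1f%% (n=%d)\n",
              x$kind, x$task, x$auc, 100 * x$error_rate, 100 * x$fnr,
              100 * x$fpr, sum(x$counts)))
  invisible(x)
}

#' Render predictions as a whole-slide label map
#'
#' Tile-mosaic rendering of hard predictions on one slide's ROI grid. For
#' detection: white = predicted cancerous, black = non-cancerous. For
#' grading: white = predicted high-grade, grey (0.5) = predicted low-grade,
#' black = ROIs outside the grading task.
#'
#' @param records ROI records of one slide (`roi_row`, `roi_col`).
#' @param confidences per-ROI confidences aligned to `records`; NA = not
#'   scored.
#' @param task `"detection"` or `"grading"`.
#' @param config a [pipeline_config()] (fixes the tile side).
#' @param operating_point hard-label cutoff.
#' @return numeric matrix in [0, 1], one cell per tile grid position.
#' @export
render_label_map <- function(records, confidences,
                             task = c("detection", "grading"),
                             config = pipeline_config(),
                             operating_point = 0.5) {
  task <- match.arg(task)
  side <- roi_side_px(config)
  ri <- records$roi_row / side
  ci <- records$roi_col / side
  stopifnot(all(abs(ri - round(ri)) < 1e-9), all(abs(ci - round(ci)) < 1e-9))
  out <- matrix(0, max(ri) + 1L, max(ci) + 1L)
  pos <- !is.na(confidences) & confidences >= operating_point
  neg <- !is.na(confidences) & confidences < operating_point
  out[cbind(ri + 1L, ci + 1L)[pos, , drop = FALSE]] <- 1
  if (task == "grading") {
    out[cbind(ri + 1L, ci + 1L)[neg, , drop = FALSE]] <- 0.5
  }
  out
}
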