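#' Leave-one-patient-out AUC of a Fisher linear discriminant
#'
#' The ranking criterion used by backward feature selection: for each
#' patient in turn, a Fisher least-squares discriminant is trained on all
#' other patients' ROIs (features standardized with training statistics) and
#' scores the held-out patient; pooled scores give one AUC. Folds whose
#' training data contain a single class are dropped with a warning.
#'
#' @param features numeric matrix (ROIs x features).
#' @param labels logical or 0/1 vector.
#' @param patient_ids vector, one id per ROI.
#' @return scalar AUC in [0, 1].
#' @export
fisher_lopo_auc <- function(features, labels, patient_ids) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  folds <- lopo_folds(patient_ids)
  scores <- rep(NA_real_, length(labels))
  for (f in folds) {
    y_tr <- labels[f$train]
    if (length(unique(y_tr)) < 2L) {
      warning(sprintf("fold for patient %s has single-class training data; excluded",
                      f$patient))
      next
    }
    w <- fisher_direction(features[f$train, , drop = FALSE], y_tr)
    scores[f$test] <- scale_apply(features[f$test, , drop = FALSE], w$center, w$scale) %*% w$w
  }
  keep <- !is.na(scores)
  roc_auc(scores[keep], labels[keep])$auc
}

# Fisher least-squares discriminant direction on standardized features:
# w = pooled-within-covariance^-1 (mu1 - mu0), ridge-regularized on failure.
fisher_direction <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- scale_apply(x, center, scale)
  x0 <- xs[!y, , drop = FALSE]
  x1 <- xs[y, , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1)
  sw <- (crossprod(sweep(x0, 2, colMeans(x0))) +
         crossprod(sweep(x1, 2, colMeans(x1)))) / max(1, n0 + n1 - 2)
  delta <- colMeans(x1) - colMeans(x0)
  w <- tryCatch(solve(sw, delta), error = function(e) {
    warning("degenerate pooled covariance; ridge-regularized (1e-6)")
    solve(sw + diag(ridge, ncol(sw)), delta)
  })
  list(w = w, center = center, scale = scale)
}

scale_apply <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, center), 2, scale, "/")
}

#' Backward feature selection by leave-one-patient-out AUC
#'
#' Starting from the full feature set, repeatedly removes the single feature
#' whose removal maximizes the Fisher LOPO-CV AUC on the tuning cohort,
#' down to one feature. The chosen subset is the AUC-maximizing point of the
#' trace; on ties the smallest subset wins. When several candidate removals
#' tie, the feature with the larger column index is removed (deterministic,
#' order-stable).
#'
#' @param features numeric matrix or data frame (ROIs x features); column
#'   names identify features.
#' @param labels logical or 0/1 vector.
#' @param patient_ids vector, one id per ROI.
#' @param verbose print progress per elimination step.
#' @return object of class `selection_trace`: list with `removed` (feature
#'   names in removal order), `trace` (data frame of subset size and AUC),
#'   `selected` (chosen feature names) and `auc` (its AUC).
#' @export
backward_select <- function(features, labels, patient_ids, verbose = FALSE) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  active <- seq_len(ncol(x))
  subsets <- list(active)
  aucs <- fisher_lopo_auc(x, y, patient_ids)
  removed <- integer(0)
  while (length(active) > 1L) {
    cand_auc <- vapply(seq_along(active), function(k) {
      fisher_lopo_auc(x[, active[-k], drop = FALSE], y, patient_ids)
    }, numeric(1))
    best <- max(cand_auc)
    k <- max(which(cand_auc >= best - 1e-12))  # tie -> larger column index goes
    removed <- c(removed, active[k])
    active <- active[-k]
    subsets <- c(subsets, list(active))
    aucs <- c(aucs, best)
    if (verbose) {
      message(sprintf("removed %s -> %d features, AUC %.4f",
                      colnames(x)[utils::tail(removed, 1)], length(active), best))
    }
  }
  removed <- c(removed, active)          # the survivor closes the permutation
  sizes <- lengths(subsets)
  best_auc <- max(aucs)
  chosen <- which(aucs >= best_auc - 1e-12)
  chosen <- chosen[which.min(sizes[chosen])]   # tie -> smallest subset
  structure(list(
    removed = colnames(x)[removed],
    trace = data.frame(size = sizes, auc = aucs),
    selected = colnames(x)[subsets[[chosen]]],
    auc = aucs[chosen]
  ), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d -> %d features, AUC %.4f\n",
              max(x$trace$size), length(x$selected), x$auc))
  invisible(x)
}
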