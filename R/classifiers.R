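#' Balance a detection training set by negative subsampling
#'
#' Cancer detection cohorts contain many more non-cancerous than cancerous
#' ROIs, so negatives are randomly subsampled without replacement down to
#' the positive count; positives are untouched. If positives already
#' outnumber negatives, the set is returned whole with a warning.
#'
#' @param labels logical vector (TRUE = positive).
#' @return integer row indices of the balanced set (original order).
#' @export
balance_for_detection <- function(labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  pos <- which(labels); neg <- which(!labels)
  if (length(pos) > length(neg)) {
    warning("positives outnumber negatives; returning the set unbalanced")
    return(sort(c(pos, neg)))
  }
  sort(c(pos, sample(neg, length(pos))))
}

#' Balance a grading training set by minority duplication
#'
#' High- and low-grade classes are balanced by randomly duplicating (sampling
#' with replacement) whichever class is smaller until the counts match; no
#' sample is ever removed.
#'
#' @param labels logical vector (TRUE = positive).
#' @return integer row indices (with repeats) of the balanced set.
#' @export
balance_for_grading <- function(labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  pos <- which(labels); neg <- which(!labels)
  if (length(pos) == length(neg)) return(seq_along(labels))
  minor <- if (length(pos) < length(neg)) pos else neg
  major <- if (length(pos) < length(neg)) neg else pos
  extra <- sample(minor, length(major) - length(minor), replace = TRUE)
  sort(c(pos, neg, extra))
}

#' Train a conventional classifier
#'
#' The three conventional arms of the pipeline, each emitting a confidence
#' in [0, 1]:
#' * `fisher` — Fisher's least-squares linear discriminant; confidences via
#'   a logistic link fitted on the training-set discriminant scores.
#' * `logistic` — linear logistic regression, fitted by weakly
#'   ridge-penalized likelihood (lambda 1e-3) so the fit stays defined when
#'   the training classes are linearly separable; with ample data the
#'   penalty is negligible and the fit is the ML solution.
#' * `svm` — for detection, a nu-SVM with radial basis kernel
#'   (gamma 0.50625, nu 0.5; the published cost 12.5 is stored verbatim —
#'   nu-SVMs are parameterized by nu, an inconsistency inherited from the
#'   source description); for grading, a C-SVC with linear kernel
#'   (cost 2.7; gamma 0.03375 stored, inert for a linear kernel).
#'   Confidences via a logistic link on decision values.
#'
#' Features are standardized to zero mean / unit variance with training
#' statistics before every classifier.
#'
#' @param kind one of `"fisher"`, `"logistic"`, `"svm"`.
#' @param features numeric matrix (samples x features), typically balanced.
#' @param labels logical vector (TRUE = positive).
#' @param task `"detection"` or `"grading"`; selects the SVM variant.
#' @param hyper optional list overriding SVM hyperparameters
#'   (`cost`, `gamma`, `nu`).
#' @return object of class `tcm_classifier` with a [predict()] method.
#' @export
train_classifier <- function(kind = c("fisher", "logistic", "svm"),
                             features, labels,
                             task = c("detection", "grading"),
                             hyper = list()) {
  kind <- match.arg(kind)
  task <- match.arg(task)
  x <- as.matrix(features)
  y <- as.logical(labels)
  if (sum(y) < 2L || sum(!y) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- scale_apply(x, center, scale)
  model <- switch(kind,
    fisher = {
      fd <- fisher_direction(x, y)
      score <- xs %*% fd$w
      list(w = fd$w, calib = fit_calibration(score, y))
    },
    logistic = {
      # weakly ridge-penalized likelihood: coincides with the ML fit when it
      # exists and stays well-posed when the classes are linearly separable
      fit <- glmnet::glmnet(xs, factor(y), family = "binomial", alpha = 0,
                            lambda = 1e-3, standardize = FALSE)
      list(beta = as.numeric(stats::coef(fit)))
    },
    svm = {
      hp <- svm_hyper(task, hyper)
      fit <- if (task == "detection") {
        e1071::svm(xs, factor(y), type = "nu-classification", kernel = "radial",
                   gamma = hp$gamma, nu = hp$nu, scale = FALSE)
      } else {
        e1071::svm(xs, factor(y), type = "C-classification", kernel = "linear",
                   cost = hp$cost, scale = FALSE)
      }
      dv <- attr(stats::predict(fit, xs, decision.values = TRUE), "decision.values")
      list(fit = fit, hyper = hp, calib = fit_calibration(as.numeric(dv), y))
    })
  structure(list(kind = kind, task = task, model = model,
                 center = center, scale = scale, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "tcm_classifier")
}

svm_hyper <- function(task, hyper) {
  def <- if (task == "detection") {
    list(cost = 12.5, gamma = 0.50625, nu = 0.5)
  } else {
    list(cost = 2.7, gamma = 0.03375, nu = 0.5)
  }
  utils::modifyList(def, hyper)
}

# logistic link mapping raw decision scores to [0, 1]; falls back to a
# steep fixed-slope link when ML estimation degenerates (perfect separation)
fit_calibration <- function(score, y) {
  fit <- suppressWarnings(stats::glm(y ~ score, family = stats::binomial()))
  co <- stats::coef(fit)
  if (any(!is.finite(co))) co <- c(0, 1)
  c(intercept = unname(co[1]), slope = unname(co[2]))
}

#' Predict confidences from a trained classifier
#'
#' @param object a `tcm_classifier`.
#' @param newdata numeric matrix (samples x features), same feature count
#'   and order as at training.
#' @param ... unused.
#' @return numeric vector of confidences in [0, 1]; the positive hard label
#'   is `confidence >= operating_point` (0.5 by default).
#' @export
predict.tcm_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features) {
    stop(sprintf("model expects %d features, got %d",
                 object$n_features, ncol(x)), call. = FALSE)
  }
  xs <- scale_apply(x, object$center, object$scale)
  m <- object$model
  conf <- switch(object$kind,
    fisher = {
      s <- as.numeric(xs %*% m$w)
      stats::plogis(m$calib["intercept"] + m$calib["slope"] * s)
    },
    logistic = {
      beta <- m$beta
      beta[!is.finite(beta)] <- 0
      as.numeric(stats::plogis(cbind(1, xs) %*% beta))
    },
    svm = {
      dv <- if (is.null(m$fit)) {
        # decision function recomputed from the serialized support vectors
        k <- if (m$kernel == "radial") {
          d2 <- outer(rowSums(xs^2), rowSums(m$sv^2), "+") - 2 * xs %*% t(m$sv)
          exp(-m$gamma * d2)
        } else {
          xs %*% t(m$sv)
        }
        as.numeric(k %*% m$coefs - m$rho)
      } else {
        as.numeric(attr(stats::predict(m$fit, xs, decision.values = TRUE),
                        "decision.values"))
      }
      stats::plogis(m$calib["intercept"] + m$calib["slope"] * dv)
    })
  unname(pmin(1, pmax(0, conf)))
}

#' @export
print.tcm_classifier <- function(x, ...) {
  cat(sprintf("<tcm_classifier %s/%s, %d features>\n",
              x$kind, x$task, x$n_features))
  invisible(x)
}
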