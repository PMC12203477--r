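#' Movement-window spike-count features
#'
#' For each trial, the total raw spike count of each active channel across
#' all bins of the response window of that trial's movement type.
#'
#' @param session A somatotopy-task `ibci_session`.
#' @param windows Named list of `"movement_window"`s, one per movement (e.g.
#'   `attr(map_tuning(session), "windows")`).
#' @param active Logical per-channel inclusion mask (default: channels active
#'   after z-scoring).
#' @return Integer matrix, trials x channels, with the trial's movement
#'   label in attribute `"labels"`.
#' @export
movement_features <- function(session, windows, active = NULL) {
  if (is.null(active)) active <- preprocess_session(session)$active
  tr <- session$trials
  miss <- setdiff(unique(tr$movement_label), names(windows))
  if (length(miss))
    stop("missing response window for movement(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ch <- which(active)
  br <- session$bin_rate
  feats <- matrix(0L, nrow(tr), length(ch))
  for (i in seq_len(nrow(tr))) {
    w <- windows[[tr$movement_label[i]]]
    cols <- onset_cols(tr$movement_onset_s[i], w$window_offsets, br)
    feats[i, ] <- as.integer(rowSums(session$counts[ch, cols, drop = FALSE]))
  }
  structure(feats, labels = tr$movement_label, channels = ch)
}

# Naive Bayes with equal class priors. Gaussian flavor uses per-class,
# per-feature means and variances with a floor of
# 1e-9 + 1e-3 * mean(feature variances); Poisson flavor uses per-class mean
# counts. Posterior ties go to the earliest label in `levels`.
nb_fit <- function(x, y, levels, flavor = c("gaussian", "poisson")) {
  flavor <- match.arg(flavor)
  mu <- do.call(rbind, lapply(levels, function(l)
    colMeans(x[y == l, , drop = FALSE])))
  if (flavor == "gaussian") {
    vr <- do.call(rbind, lapply(levels, function(l)
      apply(x[y == l, , drop = FALSE], 2L, stats::var)))
    floorv <- 1e-9 + 1e-3 * mean(apply(x, 2L, stats::var))
    vr <- pmax(vr, floorv)
    list(flavor = flavor, levels = levels, mu = mu, var = vr)
  } else {
    list(flavor = flavor, levels = levels, lambda = pmax(mu, 1e-6))
  }
}

nb_loglik <- function(fit, x) {
  if (fit$flavor == "gaussian") {
    t(apply(x, 1L, function(row) {
      rowSums(-0.5 * (log(2 * pi * fit$var) +
                        (matrix(row, nrow(fit$mu), length(row), byrow = TRUE) - fit$mu)^2 / fit$var))
    }))
  } else {
    t(apply(x, 1L, function(row) {
      rowSums(matrix(row, nrow(fit$lambda), length(row), byrow = TRUE) *
                log(fit$lambda) - fit$lambda -
                matrix(lgamma(row + 1), nrow(fit$lambda), length(row), byrow = TRUE))
    }))
  }
}

nb_predict <- function(fit, x) {
  ll <- nb_loglik(fit, x)
  fit$levels[max.col(ll, ties.method = "first")]
}

#' Leave-one-out naive Bayes classification
#'
#' Fits a naive Bayes classifier (equal class priors) on all trials but one,
#' predicts the left-out trial, and repeats for every trial; predictions are
#' concatenated into a confusion matrix. Posterior ties are broken in favour
#' of the earliest label in canonical movement order.
#'
#' @param features Trials x features matrix ([movement_features()]).
#' @param labels True labels per trial (defaults to the `"labels"` attribute
#'   of `features`).
#' @param flavor `"gaussian"` (default) or `"poisson"` emission model.
#' @param levels Label order used for the confusion matrix and tie-breaking.
#' @return A `"classification_result"`: list with `predicted`, `labels`,
#'   `confusion` (rows = true, columns = predicted), `overall_accuracy`, `n`.
#' @export
loocv_classify <- function(features, labels = attr(features, "labels"),
                           flavor = c("gaussian", "poisson"),
                           levels = intersect(movement_labels(), unique(labels))) {
  flavor <- match.arg(flavor)
  if (length(levels) == 0L) levels <- sort(unique(labels))
  stopifnot(nrow(features) == length(labels))
  if (any(table(factor(labels, levels)) < 2L))
    stop("need >= 2 trials per class for leave-one-out training", call. = FALSE)
  pred <- character(length(labels))
  for (i in seq_along(labels)) {
    tr_y <- labels[-i]
    if (!all(levels %in% tr_y))
      stop("a class is absent from a training fold", call. = FALSE)
    fit <- nb_fit(features[-i, , drop = FALSE], tr_y, levels, flavor)
    pred[i] <- nb_predict(fit, features[i, , drop = FALSE])
  }
  classification_result(pred, labels, levels)
}

classification_result <- function(predicted, labels, levels) {
  confusion <- table(true = factor(labels, levels),
                     predicted = factor(predicted, levels))
  structure(list(predicted = predicted, labels = labels,
                 confusion = unclass(confusion),
                 overall_accuracy = mean(predicted == labels),
                 n = length(labels)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("LOOCV classification: %d trials, accuracy %.1f%% (chance %.1f%%)\n",
              x$n, 100 * x$overall_accuracy, 100 / nrow(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Classify movement types of a somatotopy session
#'
#' Convenience wrapper: preprocess, locate response windows, extract
#' spike-count features and run [loocv_classify()].
#'
#' @inheritParams movement_features
#' @inheritParams loocv_classify
#' @param sm Optional precomputed [preprocess_session()] result.
#' @return A `"classification_result"`.
#' @export
classify_movements <- function(session, sm = NULL,
                               flavor = c("gaussian", "poisson")) {
  if (is.null(sm)) sm <- preprocess_session(session)
  windows <- lapply(stats::setNames(nm = movement_labels()),
                    function(m) find_movement_window(session, m, sm = sm))
  feats <- movement_features(session, windows, active = sm$active)
  loocv_classify(feats, flavor = flavor)
}

#' Pool classification results across sessions
#'
#' Element-wise sum of confusion matrices with the accuracy recomputed; the
#' pooled accuracy equals the trial-weighted mean of per-session accuracies.
#'
#' @param results List of `"classification_result"`s over the same label
#'   set.
#' @return A pooled `"classification_result"`.
#' @export
pool_confusions <- function(results) {
  stopifnot(length(results) >= 1L)
  lv <- rownames(results[[1]]$confusion)
  for (r in results)
    if (!identical(rownames(r$confusion), lv))
      stop("label sets differ across sessions", call. = FALSE)
  classification_result(unlist(lapply(results, `[[`, "predicted")),
                        unlist(lapply(results, `[[`, "labels")), lv)
}
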