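#' Fit per-channel linear velocity-encoding models
#'
#' Ridge least-squares fit, per channel, of the encoding model
#' `f = b0 + b' v` relating a channel's z-scored firing rate `f` to the
#' velocity vector `v` (e.g. `(vx, vy, vz, vg)`), over the masked bins. The
#' intercept is unpenalized. With `lambda = 0` this is ordinary least
#' squares and a rank-deficient design is an error.
#'
#' @param zrates Channels x bins matrix of z-scored rates.
#' @param velocities Bins x d matrix of velocities (named columns).
#' @param lambda Ridge penalty (>= 0) on the slope coefficients.
#' @param mask Optional logical bin mask restricting the fit.
#' @param channel_ids Optional channel identifiers stored with the model.
#' @return An `"encoding_model"`: coefficient matrix channels x (d+1)
#'   (column `b0` first), plus `lambda` and the channel ids. `coef()`
#'   returns the matrix; `predict(model, velocities)` returns the implied
#'   z-rates (channels x bins).
#' @export
fit_encoding <- function(zrates, velocities, lambda = 0, mask = NULL,
                         channel_ids = NULL) {
  if (is.vector(zrates)) zrates <- matrix(zrates, nrow = 1L)
  velocities <- as.matrix(velocities)
  if (is.null(colnames(velocities)))
    colnames(velocities) <- paste0("v", seq_len(ncol(velocities)))
  stopifnot(ncol(zrates) == nrow(velocities), lambda >= 0)
  if (is.null(mask)) mask <- rep(TRUE, nrow(velocities))
  if (sum(mask) < ncol(velocities) + 1L)
    stop("need at least d+1 masked bins", call. = FALSE)
  if (any(!is.finite(velocities[mask, ])))
    stop("velocities must be finite", call. = FALSE)
  X <- cbind(b0 = 1, velocities[mask, , drop = FALSE])
  if (lambda == 0 && qr(X)$rank < ncol(X))
    stop("rank-deficient design with lambda = 0; increase lambda", call. = FALSE)
  A <- crossprod(X) + lambda * diag(c(0, rep(1, ncol(velocities))))
  Y <- t(zrates[, mask, drop = FALSE])
  beta <- solve(A, crossprod(X, Y))
  coefs <- t(beta)
  colnames(coefs) <- c("b0", colnames(velocities))
  resid <- Y - X %*% beta
  df <- max(nrow(X) - ncol(X), 1L)
  resid_var <- colSums(resid^2) / df
  structure(list(coef = coefs, lambda = lambda, resid_var = resid_var,
                 channel_ids = if (is.null(channel_ids)) seq_len(nrow(coefs)) else channel_ids,
                 dims = colnames(velocities)),
            class = "encoding_model")
}

#' @export
coef.encoding_model <- function(object, ...) object$coef

#' @export
predict.encoding_model <- function(object, velocities, ...) {
  velocities <- as.matrix(velocities)
  object$coef[, 1] + object$coef[, -1, drop = FALSE] %*% t(velocities)
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("Encoding model: %d channels, dims (%s), lambda = %g\n",
              nrow(x$coef), paste(x$dims, collapse = ", "), x$lambda))
  invisible(x)
}

#' Indirect optimal-linear-estimation decode
#'
#' Inverts the stacked per-channel encoding model: with slope matrix `B`
#' (channels x d), intercepts `b0` and channel noise weights `W` (diagonal),
#' the decoded velocity at each bin is
#' `v = (B' W B + gamma I)^-1 B' W (f - b0)`.
#'
#' By default each channel is weighted by the inverse of its encoding-fit
#' residual variance (normalized to mean 1), the generalized-least-squares
#' weighting that makes the inversion "optimal": channels whose activity the
#' encoding model explains poorly contribute less. When all channels are
#' equally noisy — including the noiseless case, where residual variances
#' hit the common floor — the weights are all 1 and the estimator reduces to
#' the plain regularized pseudo-inverse `(B'B + gamma I)^-1 B' (f - b0)`.
#'
#' @param model An [fit_encoding()] model.
#' @param zrates Channels x bins z-scored rates (rows in model channel
#'   order).
#' @param gamma Inversion regularizer; default `1e-6 * trace(B'WB) / d`.
#' @param weights `"residual"` (inverse residual-variance weighting, default)
#'   or `"none"` (unit weights).
#' @return Bins x d matrix of decoded velocities.
#' @export
ole_decode <- function(model, zrates, gamma = NULL,
                       weights = c("residual", "none")) {
  weights <- match.arg(weights)
  if (is.vector(zrates)) zrates <- matrix(zrates, nrow = 1L)
  B <- model$coef[, -1, drop = FALSE]
  d <- ncol(B)
  if (nrow(B) < d)
    stop("need at least as many usable channels as decoded dimensions",
         call. = FALSE)
  stopifnot(nrow(zrates) == nrow(B))
  w <- if (weights == "residual" && !is.null(model$resid_var)) {
    rv <- pmax(model$resid_var, 1e-8)
    wv <- 1 / rv
    wv / mean(wv)
  } else rep(1, nrow(B))
  Bw <- B * w
  G0 <- crossprod(B, Bw)
  if (is.null(gamma)) gamma <- 1e-6 * sum(diag(G0)) / d
  out <- t(solve(G0 + gamma * diag(d), t(Bw) %*% (zrates - model$coef[, 1])))
  colnames(out) <- model$dims
  out
}

condition_channels <- function(map, condition = c("both", "medial", "lateral")) {
  condition <- match.arg(condition)
  if (condition == "both") map$channel_id
  else map$channel_id[map$array_id == condition]
}

# Bins of the kinematics grid belonging to given trials and phase labels.
phase_bins <- function(kin, trial_ids, phases) {
  which(kin$trial_id %in% trial_ids & kin$phase_label %in% phases)
}

# Inner cross-validated ridge-penalty selection on training trials: trials
# are split into up to 5 groups, each lambda on a log grid is scored by
# held-out encoding MSE averaged over channels.
select_lambda <- function(rates_raw, kin, trials_tr, phases, dims,
                          grid = 10^seq(-3, 3), k = 5L) {
  ids <- trials_tr$trial_id
  k <- min(k, length(ids) - 1L)
  groups <- split(ids, rep_len(seq_len(k), length(ids)))
  mse <- numeric(length(grid))
  for (g in groups) {
    fit_bins <- phase_bins(kin, setdiff(ids, g), phases)
    val_bins <- phase_bins(kin, g, phases)
    zm <- rowMeans(rates_raw[, fit_bins, drop = FALSE])
    zs <- apply(rates_raw[, fit_bins, drop = FALSE], 1L, stats::sd)
    ok <- zs > 1e-3
    zr_fit <- (rates_raw[ok, fit_bins, drop = FALSE] - zm[ok]) / zs[ok]
    zr_val <- (rates_raw[ok, val_bins, drop = FALSE] - zm[ok]) / zs[ok]
    V_fit <- as.matrix(kin[fit_bins, dims, drop = FALSE])
    V_val <- as.matrix(kin[val_bins, dims, drop = FALSE])
    for (j in seq_along(grid)) {
      m <- fit_encoding(zr_fit, V_fit, lambda = grid[j])
      mse[j] <- mse[j] + mean((predict(m, V_val) - zr_val)^2)
    }
  }
  grid[which.min(mse)]
}

#' Leave-one-trial-out velocity decoding of a session
#'
#' For each trial, per-channel encoding models are ridge-fit on the
#' remaining trials' task-phase bins (translation on reach/carry phases;
#' grasp separately on grasp/release phases), the held-out trial is decoded
#' by indirect optimal linear estimation, and held-out predictions are
#' concatenated. Performance is the squared Pearson correlation between
#' predicted and actual velocities over movement-period bins (speed above 1%
#' of the per-trial peak), averaged over X/Y/Z (or X/Y for the cursor task)
#' for translation and reported separately for grasp.
#'
#' Cross-validation hygiene: counts are smoothed per trial (the causal
#' kernel restarts at trial boundaries) and z-scoring constants are computed
#' from each fold's training bins only, so a held-out trial never influences
#' its own fold's model.
#'
#' @param session An `ibci_session` from the virtual-arm or cursor task.
#' @param condition Channel condition: `"both"` arrays, `"medial"` only or
#'   `"lateral"` only.
#' @param lambda Ridge penalty: `"cv"` (inner 5-fold selection on a log
#'   grid, the default) or a fixed non-negative number.
#' @param gamma Inversion regularizer passed to [ole_decode()].
#' @param mask_threshold Movement-mask speed threshold as a fraction of the
#'   per-trial peak speed.
#' @param keep_models Keep the per-fold encoding models (for audit).
#' @return A `"decoding_performance"` data frame row: `task`, `condition`,
#'   `translation_r2`, `grasp_r2` (NA for the cursor task), `n_bins`,
#'   `lambda`. Held-out predictions are attached as attributes.
#' @export
loocv_decode <- function(session, condition = c("both", "medial", "lateral"),
                         lambda = "cv", gamma = NULL, mask_threshold = 0.01,
                         keep_models = FALSE) {
  condition <- match.arg(condition)
  if (is.null(session$kinematics))
    stop("session has no kinematics; nothing to decode", call. = FALSE)
  chan <- condition_channels(session$array_map, condition)
  is_cursor <- grepl("^cursor", session$task)
  targets <- if (is_cursor) {
    list(translation = list(phases = c("reach", "drag", "return"),
                            dims = c("vx", "vy")))
  } else {
    list(translation = list(phases = c("reach", "carry"),
                            dims = c("vx", "vy", "vz")),
         grasp = list(phases = c("grasp", "release"), dims = "vg"))
  }

  rates_raw <- smooth_rates_by_trial(session$counts, session$trials,
                                     session$bin_rate)[chan, , drop = FALSE]
  kin <- session$kinematics
  out <- list()
  for (tg in names(targets)) {
    phases <- targets[[tg]]$phases
    dims <- targets[[tg]]$dims
    ids <- session$trials$trial_id
    lam_used <- numeric(0)
    pred <- actual <- NULL
    trial_of <- integer(0)
    models <- list()
    for (i in ids) {
      tr_ids <- setdiff(ids, i)
      train_bins <- phase_bins(kin, tr_ids, phases)
      test_bins <- phase_bins(kin, i, phases)
      if (!length(test_bins)) next
      zm <- rowMeans(rates_raw[, train_bins, drop = FALSE])
      zs <- apply(rates_raw[, train_bins, drop = FALSE], 1L, stats::sd)
      ok <- zs > 1e-3
      if (sum(ok) < length(dims))
        stop("fewer usable channels than decoded dimensions", call. = FALSE)
      lam <- if (identical(lambda, "cv")) {
        select_lambda(rates_raw, kin,
                      session$trials[session$trials$trial_id %in% tr_ids, ],
                      phases, dims)
      } else lambda
      lam_used <- c(lam_used, lam)
      zr_tr <- (rates_raw[ok, train_bins, drop = FALSE] - zm[ok]) / zs[ok]
      zr_te <- (rates_raw[ok, test_bins, drop = FALSE] - zm[ok]) / zs[ok]
      m <- fit_encoding(zr_tr, as.matrix(kin[train_bins, dims, drop = FALSE]),
                        lambda = lam, channel_ids = chan[ok])
      v <- ole_decode(m, zr_te, gamma = gamma)
      pred <- rbind(pred, v)
      actual <- rbind(actual, as.matrix(kin[test_bins, dims, drop = FALSE]))
      trial_of <- c(trial_of, rep(i, length(test_bins)))
      if (keep_models) models[[as.character(i)]] <- m
    }
    speed <- sqrt(rowSums(actual^2))
    peak <- stats::ave(speed, trial_of, FUN = max)
    mask <- speed > mask_threshold * peak
    r2 <- vapply(seq_along(dims), function(j) {
      a <- actual[mask, j]
      if (stats::sd(a) == 0) return(NA_real_)
      stats::cor(pred[mask, j], a)^2
    }, 0)
    out[[tg]] <- list(r2 = r2, pred = pred, actual = actual, mask = mask,
                      lambda = stats::median(lam_used), models = models)
  }

  perf <- data.frame(
    task = session$task, condition = condition,
    translation_r2 = mean(out$translation$r2, na.rm = TRUE),
    grasp_r2 = if (is.null(out$grasp)) NA_real_ else out$grasp$r2,
    n_bins = sum(out$translation$mask),
    lambda = out$translation$lambda)
  structure(perf, class = c("decoding_performance", "data.frame"),
            detail = out)
}
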