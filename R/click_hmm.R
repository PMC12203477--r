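#' Viterbi decoding of the most likely state path
#'
#' Exact dynamic-programming maximization of the joint path likelihood of a
#' discrete-state Markov chain given per-bin emission log-likelihoods.
#'
#' @param loglik Bins x states matrix of emission log-likelihoods.
#' @param transition States x states transition probability matrix (rows sum
#'   to 1).
#' @param init Initial state probabilities.
#' @return Integer vector of 1-based state indices, length `nrow(loglik)`.
#' @export
viterbi_path <- function(loglik, transition, init) {
  n <- nrow(loglik); s <- ncol(loglik)
  stopifnot(nrow(transition) == s, length(init) == s)
  lt <- log(transition); li <- log(init)
  delta <- matrix(-Inf, n, s)
  back <- matrix(0L, n, s)
  delta[1, ] <- li + loglik[1, ]
  for (t in seq_len(n)[-1]) {
    for (j in seq_len(s)) {
      cand <- delta[t - 1, ] + lt[, j]
      back[t, j] <- which.max(cand)
      delta[t, j] <- cand[back[t, j]] + loglik[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in rev(seq_len(n - 1L))) path[t] <- back[t + 1L, path[t + 1L]]
  path
}

#' Fit a two-state hidden Markov click classifier
#'
#' Projects the population activity onto the Fisher linear discriminant
#' between labeled clicked and unclicked bins, fits state-conditional
#' Gaussian emissions on that 1-D projection, and estimates the transition
#' matrix from label bigram frequencies with add-one smoothing.
#'
#' @param zrates Channels x bins z-scored rates.
#' @param click_labels Integer/logical vector per bin (1 = clicked).
#' @param ridge_frac Relative ridge added to the within-class covariance
#'   before inverting for the discriminant.
#' @return A `"click_hmm"`: projection weights `w`, per-state emission
#'   `means`/`vars`, `transition`, `init`.
#' @export
fit_click_hmm <- function(zrates, click_labels, ridge_frac = 1e-6) {
  if (is.vector(zrates)) zrates <- matrix(zrates, nrow = 1L)
  y <- as.integer(click_labels)
  stopifnot(ncol(zrates) == length(y))
  if (length(unique(y)) < 2L)
    stop("training labels contain a single state", call. = FALSE)
  X <- t(zrates)
  mu0 <- colMeans(X[y == 0L, , drop = FALSE])
  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  c0 <- stats::cov(X[y == 0L, , drop = FALSE])
  c1 <- stats::cov(X[y == 1L, , drop = FALSE])
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  Sw <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  Sw <- Sw + ridge_frac * mean(diag(Sw)) * diag(ncol(X)) + 1e-12 * diag(ncol(X))
  w <- solve(Sw, mu1 - mu0)
  x <- drop(X %*% w)
  means <- c(mean(x[y == 0L]), mean(x[y == 1L]))
  vars <- pmax(c(stats::var(x[y == 0L]), stats::var(x[y == 1L])), 1e-12)
  trans <- matrix(1, 2, 2)  # add-one smoothing
  pair <- table(factor(y[-length(y)], 0:1), factor(y[-1], 0:1))
  trans <- trans + unclass(pair)
  trans <- trans / rowSums(trans)
  init <- c(n0, n1) / (n0 + n1)
  structure(list(w = w, means = means, vars = vars, transition = trans,
                 init = init, states = c(0L, 1L)),
            class = "click_hmm")
}

#' @export
print.click_hmm <- function(x, ...) {
  cat(sprintf("Click HMM: emission means %.2f / %.2f (unclicked / clicked), P(stay) %.3f / %.3f\n",
              x$means[1], x$means[2], x$transition[1, 1], x$transition[2, 2]))
  invisible(x)
}

#' Classify clicked vs unclicked states
#'
#' Viterbi-decodes the state sequence of held-out activity under a fitted
#' [fit_click_hmm()] model.
#'
#' @param hmm A `"click_hmm"`.
#' @param zrates Channels x bins z-scored rates.
#' @param click_labels Optional true labels; when given, per-bin accuracy is
#'   returned alongside the states.
#' @return List with integer `states` (0/1 per bin) and, when labels were
#'   supplied, `accuracy` (fraction of matching bins).
#' @export
classify_click <- function(hmm, zrates, click_labels = NULL) {
  if (is.vector(zrates)) zrates <- matrix(zrates, nrow = 1L)
  x <- drop(t(zrates) %*% hmm$w)
  ll <- cbind(stats::dnorm(x, hmm$means[1], sqrt(hmm$vars[1]), log = TRUE),
              stats::dnorm(x, hmm$means[2], sqrt(hmm$vars[2]), log = TRUE))
  states <- viterbi_path(ll, hmm$transition, hmm$init) - 1L
  out <- list(states = states)
  if (!is.null(click_labels))
    out$accuracy <- mean(states == as.integer(click_labels))
  out
}

#' Leave-one-epoch-out click decoding of a session
#'
#' Each click-unclick epoch (one trial of the click-and-drag task) is held
#' out in turn; the HMM is trained on all bins of the remaining epochs and
#' the held-out epoch is Viterbi-decoded. Accuracy is the fraction of
#' correctly classified time points pooled over all held-out epochs (chance
#' is 50% for balanced state durations). Smoothing is restarted at epoch
#' boundaries and z-scoring uses each fold's training bins only.
#'
#' @param session A click-and-drag `ibci_session`.
#' @param condition Channel condition as in [loocv_decode()].
#' @return A `"click_decoding"`: list with pooled `accuracy`, `per_epoch`
#'   accuracies, decoded `states` and true `labels`.
#' @export
decode_click_session <- function(session, condition = c("both", "medial", "lateral")) {
  condition <- match.arg(condition)
  if (is.null(session$kinematics))
    stop("session has no kinematics", call. = FALSE)
  chan <- condition_channels(session$array_map, condition)
  rates <- smooth_rates_by_trial(session$counts, session$trials,
                                 session$bin_rate)[chan, , drop = FALSE]
  kin <- session$kinematics
  ids <- session$trials$trial_id
  states <- integer(nrow(kin)); labels <- as.integer(kin$click_state)
  per_epoch <- numeric(length(ids))
  for (k in seq_along(ids)) {
    test_bins <- which(kin$trial_id == ids[k])
    train_bins <- which(kin$trial_id != ids[k])
    zm <- rowMeans(rates[, train_bins, drop = FALSE])
    zs <- apply(rates[, train_bins, drop = FALSE], 1L, stats::sd)
    ok <- zs > 1e-3
    zr_tr <- (rates[ok, train_bins, drop = FALSE] - zm[ok]) / zs[ok]
    zr_te <- (rates[ok, test_bins, drop = FALSE] - zm[ok]) / zs[ok]
    hmm <- fit_click_hmm(zr_tr, labels[train_bins])
    cl <- classify_click(hmm, zr_te, labels[test_bins])
    states[test_bins] <- cl$states
    per_epoch[k] <- cl$accuracy
  }
  structure(list(accuracy = mean(states == labels), per_epoch = per_epoch,
                 states = states, labels = labels, condition = condition),
            class = "click_decoding")
}

#' @export
print.click_decoding <- function(x, ...) {
  cat(sprintf("Click decoding (%s arrays): %.1f%% of time points correct over %d epochs (chance 50%%)\n",
              x$condition, 100 * x$accuracy, length(x$per_epoch)))
  invisible(x)
}
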