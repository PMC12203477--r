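#' Bin spike-event times into counts
#'
#' Counts events per channel in half-open bins `[k/rate, (k+1)/rate)`.
#'
#' @param events List of numeric vectors of spike times (seconds), one per
#'   channel; all in `[0, duration_s)`.
#' @param duration_s Recording duration, seconds.
#' @param bin_rate Bin rate, Hz (default 50).
#' @return Integer matrix, channels x `ceiling(duration_s * bin_rate)` bins.
#' @export
bin_spikes <- function(events, duration_s, bin_rate = 50) {
  if (!is.list(events)) events <- list(events)
  nb <- ceiling(duration_s * bin_rate)
  counts <- vapply(events, function(tt) {
    if (length(tt) == 0L) return(integer(nb))
    if (any(tt < 0)) stop("negative spike times", call. = FALSE)
    if (any(tt >= duration_s)) stop("spike times beyond duration", call. = FALSE)
    tabulate(floor(tt * bin_rate) + 1L, nbins = nb)
  }, integer(nb))
  t(counts)
}

#' Causal exponential smoothing kernel
#'
#' A decaying exponential `exp(-j * dt / tau)` truncated at `window_ms` and
#' normalized to unit sum; with the default 440 ms window and
#' `tau = window / 4` the kernel decays by about `e^-4` across its support.
#'
#' @param window_ms Kernel support, milliseconds (default 440).
#' @param tau_ms Decay constant, milliseconds (default `window_ms / 4`).
#' @param bin_rate Bin rate, Hz.
#' @return Numeric kernel, oldest-lag last; `sum(kernel) == 1`.
#' @export
smoothing_kernel <- function(window_ms = 440, tau_ms = window_ms / 4,
                             bin_rate = 50) {
  dt_ms <- 1000 / bin_rate
  n <- floor(window_ms / dt_ms)
  if (n < 1L) stop("smoothing window smaller than one bin", call. = FALSE)
  k <- exp(-(seq_len(n) - 1L) * dt_ms / tau_ms)
  k / sum(k)
}

#' Smooth binned counts into firing rates
#'
#' Converts counts to instantaneous rates (`counts * bin_rate`, spikes/s) and
#' applies a causal convolution with the truncated exponential kernel of
#' [smoothing_kernel()]. Bins before the recording start are treated as
#' silent (zero-padded), so the smoother is linear and conserves the total
#' spike count up to truncation at the recording edge.
#'
#' @param counts Non-negative matrix, channels x bins (a vector is treated as
#'   one channel).
#' @param bin_rate Bin rate, Hz.
#' @param window_ms,tau_ms Kernel parameters, see [smoothing_kernel()].
#' @return Rate matrix, channels x bins, spikes/s.
#' @export
smooth_rates <- function(counts, bin_rate = 50, window_ms = 440,
                         tau_ms = window_ms / 4) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  k <- smoothing_kernel(window_ms, tau_ms, bin_rate)
  nb <- ncol(counts)
  out <- t(apply(counts * bin_rate, 1L, function(x) {
    y <- stats::filter(c(rep(0, length(k) - 1L), x), k, method = "convolution",
                       sides = 1L)
    as.numeric(y)[length(k) - 1L + seq_len(nb)]
  }))
  dimnames(out) <- dimnames(counts)
  out
}

#' Z-score firing rates per channel
#'
#' Normalizes each channel to zero mean and unit standard deviation over a
#' normalization epoch (the whole session by default). Channels whose
#' variance over the epoch falls below `var_floor` are flagged inactive and
#' excluded from downstream analyses; their z-rates are set to zero.
#'
#' @param rates Rate matrix, channels x bins (spikes/s).
#' @param epoch_mask Optional logical vector over bins selecting the
#'   normalization epoch (default: all bins).
#' @param var_floor Variance floor (z-units squared) below which a channel is
#'   inactive.
#' @return An object of class `"smoothed_rates"`: list with `rates`,
#'   `zrates`, `zmean`, `zsd`, logical `active`, and the normalization mask.
#' @export
zscore_rates <- function(rates, epoch_mask = NULL, var_floor = 1e-6) {
  if (is.vector(rates)) rates <- matrix(rates, nrow = 1L)
  if (is.null(epoch_mask)) epoch_mask <- rep(TRUE, ncol(rates))
  if (!any(epoch_mask)) stop("empty normalization epoch", call. = FALSE)
  if (sum(epoch_mask) < 2L) stop("normalization epoch needs >= 2 bins", call. = FALSE)
  sub <- rates[, epoch_mask, drop = FALSE]
  zmean <- rowMeans(sub)
  zsd <- sqrt(rowSums((sub - zmean)^2) / (ncol(sub) - 1L))
  active <- zsd^2 >= var_floor
  zsd_safe <- ifelse(active, zsd, 1)
  zrates <- (rates - zmean) / zsd_safe
  zrates[!active, ] <- 0
  structure(list(rates = rates, zrates = zrates, zmean = zmean, zsd = zsd,
                 active = active, epoch_mask = epoch_mask),
            class = "smoothed_rates")
}

#' @export
print.smoothed_rates <- function(x, ...) {
  cat(sprintf("Smoothed z-scored rates: %d channels x %d bins (%d active)\n",
              nrow(x$rates), ncol(x$rates), sum(x$active)))
  invisible(x)
}

#' Smooth and z-score a session's counts
#'
#' Convenience wrapper: [smooth_rates()] then [zscore_rates()] on a session's
#' count matrix.
#'
#' @param session An `ibci_session`.
#' @inheritParams smooth_rates
#' @inheritParams zscore_rates
#' @return A `"smoothed_rates"` object.
#' @export
preprocess_session <- function(session, window_ms = 440, tau_ms = window_ms / 4,
                               epoch_mask = NULL, var_floor = 1e-6) {
  r <- smooth_rates(session$counts, bin_rate = session$bin_rate,
                    window_ms = window_ms, tau_ms = tau_ms)
  zscore_rates(r, epoch_mask = epoch_mask, var_floor = var_floor)
}

# Per-trial-segment causal smoothing: the kernel is restarted at each trial
# boundary so no trial's activity leaks into another. Used by the
# cross-validated decoders, where fold independence must be exact.
smooth_rates_by_trial <- function(counts, trials, bin_rate = 50,
                                  window_ms = 440, tau_ms = window_ms / 4) {
  out <- matrix(0, nrow(counts), ncol(counts))
  for (i in seq_len(nrow(trials))) {
    bins <- trial_bins(trials[i, ], bin_rate, ncol(counts))
    out[, bins] <- smooth_rates(counts[, bins, drop = FALSE], bin_rate,
                                window_ms, tau_ms)
  }
  dimnames(out) <- dimnames(counts)
  out
}

trial_bins <- function(trial, bin_rate, nbins) {
  b0 <- round(trial$start_s * bin_rate) + 1L
  b1 <- min(round(trial$end_s * bin_rate), nbins)
  b0:b1
}
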