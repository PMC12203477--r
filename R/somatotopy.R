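movement_trials <- function(session, movement) {
  tr <- session$trials[session$trials$movement_label == movement, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no trials of movement '", movement, "'", call. = FALSE)
  tr
}

# Absolute column indices for 0-based offsets `offs` from a movement onset.
onset_cols <- function(onset_s, offs, bin_rate) round(onset_s * bin_rate) + 1L + offs

#' Locate the per-movement response window from population activity
#'
#' Trial-averages the z-scored firing rates of all active channels for one
#' movement type, aligned to Movement-phase onset, over the support from
#' 0.5 s before onset to the trial end. PCA (time bins as observations,
#' channels as variables) reduces this to the first principal component, a
#' proxy for overall population activity; the time of its peak magnitude
#' within the Movement phase is the response center `t_M`, and the response
#' window is 500 ms centered on `t_M`, shifted if needed to fit inside the
#' phase.
#'
#' @param session An `ibci_session` from the somatotopy-mapping task.
#' @param movement One of [movement_labels()].
#' @param sm Optional precomputed [preprocess_session()] result.
#' @param window_ms Response-window length, ms (default 500).
#' @param pre_s Pre-onset context included in the PCA support, seconds.
#' @return A `"movement_window"`: list with `movement`, `t_M` (s after
#'   Movement onset), `window_offsets` (0-based bin offsets from onset),
#'   `pc1` (score series) and `pc1_offsets`.
#' @export
find_movement_window <- function(session, movement, sm = NULL,
                                 window_ms = 500, pre_s = 0.5) {
  movement <- match.arg(movement, movement_labels())
  if (is.null(sm)) sm <- preprocess_session(session)
  if (!any(sm$active)) stop("all channels inactive", call. = FALSE)
  br <- session$bin_rate
  tr <- movement_trials(session, movement)
  if (nrow(tr) < 2L) stop("need >= 2 trials of '", movement, "'", call. = FALSE)

  mov_bins <- round((tr$rest_onset_s[1] - tr$movement_onset_s[1]) * br)
  post_bins <- round((tr$end_s[1] - tr$movement_onset_s[1]) * br)
  offs <- seq.int(-round(pre_s * br), post_bins - 1L)

  zr <- sm$zrates[sm$active, , drop = FALSE]
  avg <- matrix(0, length(offs), nrow(zr))
  for (i in seq_len(nrow(tr))) {
    cols <- onset_cols(tr$movement_onset_s[i], offs, br)
    avg <- avg + t(zr[, cols, drop = FALSE])
  }
  avg <- avg / nrow(tr)

  pc1 <- if (ncol(avg) == 1L) {
    avg[, 1] - mean(avg[, 1])
  } else {
    stats::prcomp(avg, center = TRUE, scale. = FALSE)$x[, 1]
  }

  in_phase <- offs >= 0L & offs < mov_bins
  peak_off <- offs[in_phase][which.max(abs(pc1[in_phase]))]
  t_M <- (peak_off + 0.5) / br

  nwin <- round(window_ms / 1000 * br)
  start <- peak_off - nwin %/% 2
  start <- max(0L, min(start, mov_bins - nwin))
  structure(list(movement = movement, t_M = t_M,
                 window_offsets = seq.int(start, start + nwin - 1L),
                 pc1 = pc1, pc1_offsets = offs, bin_rate = br),
            class = "movement_window")
}

#' @export
print.movement_window <- function(x, ...) {
  cat(sprintf("Movement window for '%s': t_M = %.2f s after onset, %d bins (%.0f ms)\n",
              x$movement, x$t_M, length(x$window_offsets),
              1000 * length(x$window_offsets) / x$bin_rate))
  invisible(x)
}

#' Per-trial Movement-minus-Baseline spike-count differences
#'
#' For each trial of the movement: total raw spike counts in the response
#' window minus total counts in the Baseline window (the 500 ms immediately
#' before Movement-phase onset).
#'
#' @inheritParams find_movement_window
#' @param window A `"movement_window"` for the movement.
#' @param channel Channel id(s).
#' @return Numeric vector of per-trial differences (one channel), or a
#'   trials x channels matrix.
#' @export
trial_deltas <- function(session, window, movement = window$movement,
                         channel) {
  tr <- movement_trials(session, movement)
  br <- session$bin_rate
  nwin <- length(window$window_offsets)
  base_offs <- seq.int(-nwin, -1L)
  out <- matrix(0, nrow(tr), length(channel))
  for (i in seq_len(nrow(tr))) {
    mc <- onset_cols(tr$movement_onset_s[i], window$window_offsets, br)
    bc <- onset_cols(tr$movement_onset_s[i], base_offs, br)
    if (min(bc) < 1L || max(mc) > ncol(session$counts))
      stop("analysis window exceeds session extent", call. = FALSE)
    out[i, ] <- rowSums(session$counts[channel, mc, drop = FALSE]) -
      rowSums(session$counts[channel, bc, drop = FALSE])
  }
  if (length(channel) == 1L) out[, 1] else out
}

#' One-sample tuning significance test
#'
#' Two-tailed one-sample t-test of the per-trial Movement-minus-Baseline
#' count differences against zero, at the Bonferroni-corrected per-movement
#' threshold (0.0125 at defaults). Zero-variance differences are degenerate:
#' the p-value is set to 1 and the channel is not significant.
#'
#' @param deltas Per-trial count differences ([trial_deltas()]).
#' @param config A [tuning_test_config()].
#' @return List with `t_stat`, `p_value`, `significant`, `degenerate`,
#'   `mean_delta`, `n`.
#' @export
test_tuning <- function(deltas, config = tuning_test_config()) {
  if (length(deltas) < 2L) stop("need >= 2 trials", call. = FALSE)
  if (stats::sd(deltas) == 0) {
    return(list(t_stat = NA_real_, p_value = 1, significant = FALSE,
                degenerate = TRUE, mean_delta = mean(deltas),
                n = length(deltas)))
  }
  tt <- stats::t.test(deltas, mu = 0, alternative = "two.sided")
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < config$alpha_per_test, degenerate = FALSE,
       mean_delta = mean(deltas), n = length(deltas))
}

#' Depth of modulation
#'
#' Per trial, the smoothed firing-rate series in the response window minus
#' that trial's mean Baseline-window rate; the excursion of greatest
#' magnitude (positive or negative) is retained with its sign, then averaged
#' across trials. Units: spikes/s.
#'
#' @inheritParams trial_deltas
#' @param sm Optional precomputed [preprocess_session()] result.
#' @return Numeric depth per channel.
#' @export
depth_of_modulation <- function(session, window, movement = window$movement,
                                channel, sm = NULL) {
  if (is.null(sm)) sm <- preprocess_session(session)
  tr <- movement_trials(session, movement)
  br <- session$bin_rate
  nwin <- length(window$window_offsets)
  base_offs <- seq.int(-nwin, -1L)
  acc <- matrix(0, nrow(tr), length(channel))
  for (i in seq_len(nrow(tr))) {
    mc <- onset_cols(tr$movement_onset_s[i], window$window_offsets, br)
    bc <- onset_cols(tr$movement_onset_s[i], base_offs, br)
    if (min(bc) < 1L || max(mc) > ncol(sm$rates))
      stop("analysis window exceeds session extent", call. = FALSE)
    dev <- sm$rates[channel, mc, drop = FALSE] -
      rowMeans(sm$rates[channel, bc, drop = FALSE])
    acc[i, ] <- dev[cbind(seq_len(nrow(dev)), max.col(abs(dev), ties.method = "first"))]
  }
  colMeans(acc)
}

#' Map per-channel movement tuning across a session
#'
#' Runs the full tuning analysis: response-window location per movement,
#' per-trial count differences, significance testing at the Bonferroni
#' threshold, and depth of modulation, for every channel and movement type.
#'
#' @inheritParams find_movement_window
#' @param config A [tuning_test_config()].
#' @return A data frame of class `"tuning_table"` with one row per
#'   channel x movement: `channel_id`, `array_id`, `movement`, `mean_delta`,
#'   `t_stat`, `p_value`, `significant`, `degenerate`, `depth`, `active`.
#'   The located windows are attached as attribute `"windows"`.
#' @export
map_tuning <- function(session, config = tuning_test_config(), sm = NULL,
                       window_ms = 500) {
  if (is.null(sm)) sm <- preprocess_session(session)
  ch <- session$array_map$channel_id
  res <- list(); windows <- list()
  for (m in movement_labels()) {
    w <- find_movement_window(session, m, sm = sm, window_ms = window_ms)
    windows[[m]] <- w
    deltas <- trial_deltas(session, w, m, channel = ch)
    tests <- apply(deltas, 2L, test_tuning, config = config)
    depth <- depth_of_modulation(session, w, m, channel = ch, sm = sm)
    res[[m]] <- data.frame(
      channel_id = ch,
      array_id = session$array_map$array_id,
      movement = m,
      mean_delta = vapply(tests, `[[`, 0, "mean_delta"),
      t_stat = vapply(tests, `[[`, 0, "t_stat"),
      p_value = vapply(tests, `[[`, 0, "p_value"),
      significant = vapply(tests, `[[`, TRUE, "significant"),
      degenerate = vapply(tests, `[[`, TRUE, "degenerate"),
      depth = depth,
      active = sm$active)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("tuning_table", "data.frame"),
            windows = windows, config = config,
            array_map = session$array_map)
}

#' @export
summary.tuning_table <- function(object, ...) {
  for (a in unique(object$array_id)) {
    sub <- object[object$array_id == a, ]
    any_sig <- tapply(sub$significant, sub$channel_id, any)
    cat(sprintf("%s array: %d/%d channels modulated by >= 1 movement\n",
                a, sum(any_sig), length(any_sig)))
  }
  invisible(proportions_by_array(object))
}

#' @export
print.tuning_table <- function(x, ...) {
  cat(sprintf("Tuning table: %d channels x %d movements; %d significant pairs\n",
              length(unique(x$channel_id)), length(unique(x$movement)),
              sum(x$significant)))
  invisible(x)
}

#' Proportion of tuned channels per array and movement
#'
#' For each array, the number of channels significantly tuned to a movement
#' type divided by the number of channels on that array significant for at
#' least one movement. Proportions can sum to more than 1 across movements
#' because channels are commonly tuned to several. Arrays with no modulated
#' channel get `NA`.
#'
#' @param results A `"tuning_table"`.
#' @param map Array map (defaults to the one attached to `results`).
#' @return Data frame: `array_id`, `movement`, `n_tuned`, `n_modulated`,
#'   `proportion`.
#' @export
proportions_by_array <- function(results, map = attr(results, "array_map")) {
  out <- list()
  for (a in unique(map$array_id)) {
    sub <- results[results$array_id == a, ]
    any_sig <- tapply(sub$significant, sub$channel_id, any)
    denom <- sum(any_sig)
    for (m in movement_labels()) {
      num <- sum(sub$significant[sub$movement == m])
      out[[length(out) + 1L]] <- data.frame(
        array_id = a, movement = m, n_tuned = num, n_modulated = denom,
        proportion = if (denom > 0L) num / denom else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Plot per-array modulation-depth heatmaps
#'
#' One panel per array x movement showing depth of modulation at each
#' channel's grid position; significantly tuned channels are dotted.
#'
#' @param x A `"tuning_table"`.
#' @param ... Unused.
#' @export
plot.tuning_table <- function(x, ...) {
  map <- attr(x, "array_map")
  arrays <- unique(map$array_id)
  movements <- movement_labels()
  op <- graphics::par(mfrow = c(length(arrays), length(movements)),
                      mar = c(1.5, 1.5, 2, 0.5))
  on.exit(graphics::par(op))
  lim <- max(abs(x$depth), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(64)
  for (a in arrays) for (m in movements) {
    sub <- merge(x[x$movement == m & x$array_id == a, ], map)
    z <- matrix(NA_real_, 10, 10)
    z[cbind(sub$grid_row + 1L, sub$grid_col + 1L)] <- sub$depth
    graphics::image(0:9, 0:9, t(z)[, 10:1], zlim = c(-lim, lim), col = pal,
                    axes = FALSE, xlab = "", ylab = "",
                    main = sprintf("%s / %s", a, m))
    sig <- sub[sub$significant, ]
    if (nrow(sig))
      graphics::points(sig$grid_col, 9 - sig$grid_row, pch = 16, cex = 0.6)
  }
  invisible(x)
}
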