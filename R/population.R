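#' Expected absolute modulation depth of a tuned channel
#'
#' The generator places channels on a mediolateral axis (`pos`, 0 = most
#' lateral, 1 = most medial) and scales the expected modulation depth of each
#' movement linearly along it: distal movements (grasp, wrist) are strongest
#' laterally, proximal movements (elbow, shoulder) medially. With slope `s`
#' the expectation for a tuned channel is
#' `depth_scale * (1 + s * (pos - 1/2))` for proximal movements and
#' `depth_scale * (1 + s * (1/2 - pos))` for distal ones, so a zero slope is
#' a flat (gradient-free) cortex.
#'
#' @param config A [generator_config()].
#' @param pos Mediolateral position(s) in `[0, 1]`.
#' @param movement One of [movement_labels()].
#' @return Expected absolute depth in spikes/s for a tuned channel.
#' @export
expected_depth <- function(config, pos, movement) {
  movement <- match.arg(movement, movement_labels())
  stopifnot(all(pos >= 0 & pos <= 1))
  s <- config$gradient_slope
  grad <- if (movement %in% PROXIMAL_MOVEMENTS) pos - 0.5 else 0.5 - pos
  config$depth_scale * (1 + s * grad)
}

# 10x10 grid cells in deterministic order, unwired corners last so the default
# 96-channel array matches the usual corner-free layout.
array_grid_cells <- function(n) {
  cells <- expand.grid(grid_row = 0:9, grid_col = 0:9)
  corner <- (cells$grid_row %in% c(0L, 9L)) & (cells$grid_col %in% c(0L, 9L))
  cells <- rbind(cells[!corner, ], cells[corner, ])
  cells[seq_len(n), , drop = FALSE]
}

#' Generate a ground-truth synthetic cortical population
#'
#' Draws per-channel tuning and encoding parameters for two electrode arrays
#' (`medial`, `lateral`) laid out on 10 x 10 grids. Each channel gets a
#' baseline rate, a signed modulation depth per movement type following the
#' mediolateral somatotopic gradient (see [expected_depth()]), and linear
#' velocity-encoding coefficients: a 3-D translation coefficient vector whose
#' magnitude follows the proximal gradient, a grasp-velocity coefficient
#' following the distal gradient, and a 2-D wrist-imagery cursor coefficient
#' pair following the distal gradient. A configurable fraction of channels is
#' untuned (all depths and coefficients zero). Deterministic given
#' `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the population is reproducible from
#'   `(config, seed)`.
#' @return A data frame of class `"ibci_population"`, one row per channel,
#'   with columns `channel_id`, `array_id`, `grid_row`, `grid_col`,
#'   `mediolateral_pos`, `baseline_rate`, `tuned`,
#'   `depth_grasp`/`_wrist`/`_elbow`/`_shoulder`, encoding coefficients
#'   `enc_b0`, `enc_bx`, `enc_by`, `enc_bz`, `enc_bg`, wrist-imagery cursor
#'   coefficients `enc_wx`, `enc_wy`, and `noise_scale`.
#' @export
make_population <- function(config = generator_config(), seed = 1L) {
  validate_generator_config(config)
  set.seed(as.integer(seed))
  n <- config$n_channels_per_array

  pop_one <- function(array_id) {
    cells <- array_grid_cells(n)
    # grid_col is the mediolateral axis of each array; the lateral array spans
    # positions [0, 0.4], the medial array [0.6, 1].
    frac <- cells$grid_col / 9
    pos <- if (array_id == "lateral") 0.4 * frac else 0.6 + 0.4 * frac
    data.frame(array_id = array_id, cells, mediolateral_pos = pos)
  }
  pop <- rbind(pop_one("lateral"), pop_one("medial"))
  pop <- data.frame(channel_id = seq_len(nrow(pop)), pop)

  nc <- nrow(pop)
  pop$baseline_rate <- if (config$baseline_cv > 0) {
    shape <- 1 / config$baseline_cv^2
    stats::rgamma(nc, shape = shape, rate = shape / config$baseline_rate)
  } else rep(config$baseline_rate, nc)

  pop$tuned <- stats::runif(nc) >= config$untuned_fraction

  sample_depth <- function(movement) {
    e <- expected_depth(config, pop$mediolateral_pos, movement)
    mag <- if (config$depth_cv > 0) {
      shape <- 1 / config$depth_cv^2
      stats::rgamma(nc, shape = shape, rate = shape) * e
    } else e
    sgn <- ifelse(stats::runif(nc) < config$prop_negative, -1, 1)
    ifelse(pop$tuned, sgn * mag, 0)
  }
  for (m in movement_labels()) pop[[paste0("depth_", m)]] <- sample_depth(m)

  # Translation encoding: random preferred direction on the unit sphere,
  # magnitude proximal-weighted; grasp and wrist-cursor coefficients
  # distal-weighted.
  u <- matrix(stats::rnorm(3 * nc), nc, 3)
  u <- u / sqrt(rowSums(u^2))
  prox_gain <- 1 + config$gradient_slope * (pop$mediolateral_pos - 0.5)
  dist_gain <- 1 + config$gradient_slope * (0.5 - pop$mediolateral_pos)
  gain_jitter <- function() if (config$depth_cv > 0) {
    shape <- 1 / config$depth_cv^2
    stats::rgamma(nc, shape = shape, rate = shape)
  } else rep(1, nc)

  tmag <- config$enc_translation_scale * prox_gain * gain_jitter()
  pop$enc_b0 <- 0
  pop$enc_bx <- ifelse(pop$tuned, tmag * u[, 1], 0)
  pop$enc_by <- ifelse(pop$tuned, tmag * u[, 2], 0)
  pop$enc_bz <- ifelse(pop$tuned, tmag * u[, 3], 0)

  gsgn <- ifelse(stats::runif(nc) < config$prop_negative, -1, 1)
  pop$enc_bg <- ifelse(pop$tuned,
                       gsgn * config$enc_grasp_scale * dist_gain * gain_jitter(), 0)

  w <- matrix(stats::rnorm(2 * nc), nc, 2)
  w <- w / sqrt(rowSums(w^2))
  wmag <- config$enc_translation_scale * dist_gain * gain_jitter()
  pop$enc_wx <- ifelse(pop$tuned, wmag * w[, 1], 0)
  pop$enc_wy <- ifelse(pop$tuned, wmag * w[, 2], 0)

  pop$noise_scale <- rep(config$noise_scale, nc)

  structure(pop, class = c("ibci_population", "data.frame"),
            config = config, seed = as.integer(seed))
}

#' @export
print.ibci_population <- function(x, ...) {
  cat(sprintf("Synthetic cortical population: %d channels on 2 arrays (seed %d)\n",
              nrow(x), attr(x, "seed")))
  cat(sprintf("  tuned channels: %d (%.0f%%)\n", sum(x$tuned),
              100 * mean(x$tuned)))
  for (m in movement_labels()) {
    d <- x[[paste0("depth_", m)]][x$tuned]
    cat(sprintf("  %-8s mean |depth| %5.2f sp/s\n", m, mean(abs(d))))
  }
  invisible(x)
}

#' Array map of a population or session
#'
#' @param x An `ibci_population` or `ibci_session`.
#' @return Data frame with `channel_id`, `array_id`, `grid_row`, `grid_col`,
#'   `mediolateral_pos`.
#' @export
array_map <- function(x) {
  if (inherits(x, "ibci_session")) return(x$array_map)
  x[, c("channel_id", "array_id", "grid_row", "grid_col", "mediolateral_pos")]
}
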