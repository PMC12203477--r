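#' Minimum-jerk speed profile
#'
#' Speed along a straight minimum-jerk point-to-point movement of distance
#' `distance` and duration `duration`, evaluated at times `t` from movement
#' onset: `v(t) = (distance / duration) * 30 * (tau^2 - 2 tau^3 + tau^4)`
#' with `tau = t / duration`. The peak speed is `1.875 * distance / duration`
#' at the movement midpoint.
#'
#' @param t Times from segment onset, seconds.
#' @param distance Path length.
#' @param duration Segment duration, seconds.
#' @return Speeds (same units as `distance` per second); 0 outside
#'   `[0, duration]`.
#' @export
min_jerk_speed <- function(t, distance, duration) {
  tau <- t / duration
  v <- (distance / duration) * 30 * (tau^2 - 2 * tau^3 + tau^4)
  v[tau < 0 | tau > 1] <- 0
  v
}

# Raised-cosine modulation bump: 0 at the phase edges, 1 at its center.
raised_cosine <- function(t, duration) {
  tau <- t / duration
  w <- 0.5 * (1 - cos(2 * pi * tau))
  w[tau < 0 | tau > 1] <- 0
  w
}

#' Unit direction vectors of an n-target center-out layout
#'
#' @param n Number of equally spaced peripheral targets (default 8).
#' @return `n x 2` matrix of unit vectors; for equal spacing they sum to the
#'   zero vector.
#' @export
cursor_target_directions <- function(n = 8L) {
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = cos(ang), y = sin(ang))
}

# Counts from a non-negative rate matrix (channels x bins). Poisson draws, or
# deterministic cumulative rounding (integral-conserving) when poisson = FALSE.
draw_counts <- function(rate, dt, poisson) {
  if (poisson) {
    matrix(stats::rpois(length(rate), lambda = rate * dt),
           nrow(rate), ncol(rate))
  } else {
    t(apply(rate * dt, 1L, function(r) diff(c(0, round(cumsum(r))))))
  }
}

new_session <- function(counts, trials, array_mp, seed, task, config,
                        kinematics = NULL, truth = NULL) {
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, bin_rate = config$bin_rate, trials = trials,
                 kinematics = kinematics, array_map = array_mp,
                 seed = as.integer(seed), task = task, config = config,
                 truth = truth),
            class = "ibci_session")
}

#' @export
print.ibci_session <- function(x, ...) {
  cat(sprintf("iBCI session (%s task): %d channels x %d bins at %g Hz, %d trials, seed %d\n",
              x$task, nrow(x$counts), ncol(x$counts), x$bin_rate,
              nrow(x$trials), x$seed))
  if (!is.null(x$kinematics))
    cat(sprintf("  kinematics: %d samples, %d click epochs\n",
                nrow(x$kinematics), count_click_epochs(x)))
  invisible(x)
}

session_duration <- function(session) ncol(session$counts) / session$bin_rate

#' Simulate a somatotopy-mapping session
#'
#' Block-randomized trials of four attempted movements (grasp, wrist
#' extension, elbow flexion, shoulder elevation), each trial a
#' Baseline/Movement/Rest phase sequence. During the Movement phase of a
#' trial of movement `m`, channel rates follow
#' `baseline + depth_m * w(t)` where `w(t)` is a raised-cosine bump peaking
#' at the phase center; rates are at baseline elsewhere. Gaussian rate noise
#' of standard deviation `noise_scale * rate_sd` spikes/s is added, rates are
#' clamped at zero, and counts are drawn per 20 ms bin.
#'
#' @param pop An [make_population()] population.
#' @param config The [generator_config()] used to build `pop` (trial
#'   structure and noise are read from it).
#' @param seed Integer session seed.
#' @param keep_truth Store the pre-noise rate matrix in `$truth$rate` (for
#'   parameter-recovery tests; off by default to save memory).
#' @return An `ibci_session`: integer `counts` (channels x bins), `trials`
#'   table with phase onsets, `array_map`, `seed`.
#' @export
simulate_somatotopy_session <- function(pop, config = attr(pop, "config"),
                                        seed = 1L, keep_truth = FALSE) {
  set.seed(as.integer(seed))
  br <- config$bin_rate
  dt <- 1 / br
  ph <- config$phase_durations_s
  trial_dur <- sum(ph)
  bins_per_trial <- round(trial_dur * br)
  n_trials <- 4L * config$n_blocks
  nb <- n_trials * bins_per_trial
  nc <- nrow(pop)

  order_lab <- unlist(lapply(seq_len(config$n_blocks),
                             function(i) sample(movement_labels())))
  start_s <- (seq_len(n_trials) - 1L) * trial_dur
  trials <- data.frame(trial_id = seq_len(n_trials), movement_label = order_lab,
                       start_s = start_s,
                       baseline_onset_s = start_s,
                       movement_onset_s = start_s + ph[["baseline"]],
                       rest_onset_s = start_s + ph[["baseline"]] + ph[["movement"]],
                       end_s = start_s + trial_dur)

  depth <- as.matrix(pop[, paste0("depth_", movement_labels())])
  colnames(depth) <- movement_labels()

  rate <- matrix(pop$baseline_rate, nc, nb)
  mov_bins <- round(ph[["movement"]] * br)
  rel_t <- (seq_len(mov_bins) - 0.5) * dt
  w <- raised_cosine(rel_t, ph[["movement"]])
  for (i in seq_len(n_trials)) {
    if (!order_lab[i] %in% movement_labels())
      stop("unknown movement label: ", order_lab[i], call. = FALSE)
    cols <- round(trials$movement_onset_s[i] * br) + seq_len(mov_bins)
    rate[, cols] <- rate[, cols] + outer(depth[, order_lab[i]], w)
  }
  truth <- if (keep_truth) list(rate = rate) else NULL

  if (config$noise_scale > 0)
    rate <- rate + matrix(stats::rnorm(nc * nb, 0, config$noise_scale * config$rate_sd), nc, nb)
  rate <- pmax(rate, 0)
  counts <- draw_counts(rate, dt, config$poisson)

  new_session(counts, trials, array_map(pop), seed, "somatotopy", config,
              truth = truth)
}

# Append one kinematic segment (constant-direction velocity profile) to the
# per-bin velocity accumulator. `speed` has one entry per bin of the segment.
seg_bins <- function(t0, dur, br) round(t0 * br) + seq_len(round(dur * br))

#' Simulate a virtual arm-and-hand (reach and grasp) session
#'
#' Each trial reaches to a target (3-D minimum-jerk translation), closes the
#' hand (1-D grasp velocity), carries the object to a new location, and
#' releases it, with short holds between segments. Channel activity follows
#' the linear encoding model `f = b0 + bx vx + by vy + bz vz + bg vg`
#' (z-units), plus Gaussian noise of scale `noise_scale`; z-drive is
#' converted to rate via `max(0, baseline + z * rate_sd)` and counts drawn
#' per bin.
#'
#' @inheritParams simulate_somatotopy_session
#' @param n_trials Number of trials (default `config$arm_n_trials`;
#'   calibration sessions typically hold 18-36).
#' @return An `ibci_session` with a `kinematics` table (`time_s`, `vx`, `vy`,
#'   `vz`, `vg`, `phase_label`, `click_state`, `trial_id`). With
#'   `keep_truth = TRUE`, `$truth$latent` holds the pre-noise z-rates and
#'   `$truth$rate` the pre-count rates.
#' @export
simulate_reach_grasp_session <- function(pop, config = attr(pop, "config"),
                                         seed = 1L,
                                         n_trials = config$arm_n_trials,
                                         keep_truth = FALSE) {
  enc <- as.matrix(pop[, c("enc_bx", "enc_by", "enc_bz", "enc_bg")])
  if (any(!is.finite(enc)))
    stop("population is missing finite encoding coefficients", call. = FALSE)
  set.seed(as.integer(seed))
  br <- config$bin_rate
  hold <- config$hold_duration_s
  rd <- config$reach_duration_s
  gd <- config$grasp_duration_s
  segs <- c(hold, rd, hold, gd, hold, rd, hold, gd, hold)
  labs <- c("pause", "reach", "pause", "grasp", "pause", "carry", "pause",
            "release", "pause")
  trial_dur <- sum(segs)
  bins_per_trial <- round(trial_dur * br)
  nb <- n_trials * bins_per_trial

  V <- matrix(0, nb, 4, dimnames = list(NULL, c("vx", "vy", "vz", "vg")))
  phase <- rep("pause", nb)
  trial_of_bin <- rep(seq_len(n_trials), each = bins_per_trial)
  start_s <- (seq_len(n_trials) - 1L) * trial_dur

  for (i in seq_len(n_trials)) {
    t0 <- start_s[i]
    off <- cumsum(c(0, segs))
    for (k in seq_along(segs)) {
      lab <- labs[k]
      if (lab == "pause") next
      bins <- seg_bins(t0 + off[k], segs[k], br)
      tc <- (seq_along(bins) - 0.5) / br
      phase[bins] <- lab
      if (lab %in% c("reach", "carry")) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        sp <- min_jerk_speed(tc, config$target_distance, rd)
        V[bins, 1:3] <- outer(sp, u)
      } else {
        sgn <- if (lab == "grasp") 1 else -1
        V[bins, 4] <- sgn * min_jerk_speed(tc, config$grasp_distance, gd)
      }
    }
  }

  trials <- data.frame(trial_id = seq_len(n_trials),
                       movement_label = "reach_grasp",
                       start_s = start_s, end_s = start_s + trial_dur)
  kin <- data.frame(time_s = (seq_len(nb) - 0.5) / br,
                    vx = V[, 1], vy = V[, 2], vz = V[, 3], vg = V[, 4],
                    phase_label = phase, click_state = 0L,
                    trial_id = trial_of_bin)
  build_encoded_session(pop, config, seed, V, trials, kin, "reach_grasp",
                        keep_truth)
}

# Shared tail of the encoding-model-driven simulators: latent z-rates from
# coefficients, additive Gaussian noise, z-to-rate conversion, count draws.
build_encoded_session <- function(pop, config, seed, V, trials, kin, task,
                                  keep_truth, coef_cols = c("enc_bx", "enc_by", "enc_bz", "enc_bg")) {
  B <- as.matrix(pop[, coef_cols])
  latent <- pop$enc_b0 + B %*% t(V)       # channels x bins, pre-noise z-rates
  z <- latent
  nc <- nrow(pop); nb <- ncol(latent)
  if (config$noise_scale > 0)
    z <- z + matrix(stats::rnorm(nc * nb, 0, 1), nc, nb) * pop$noise_scale
  rate <- pmax(pop$baseline_rate + z * config$rate_sd, 0)
  counts <- draw_counts(rate, 1 / config$bin_rate, config$poisson)
  truth <- if (keep_truth) list(latent = latent, rate = rate) else NULL
  new_session(counts, trials, array_map(pop), seed, task, config,
              kinematics = kin, truth = truth)
}

#' Simulate a 2-D center-out cursor session
#'
#' Center-out trials to 8 equally spaced peripheral targets. In a plain
#' translation session (`clicks = FALSE`, e.g. wrist-imagery calibration)
#' each trial is hold / reach out / return. In a click-and-drag session
#' (`clicks = TRUE`) each trial is one click-unclick epoch: an unclicked
#' reach to the target, then a clicked drag back to center with a clicked
#' hold, so clicked and unclicked durations are balanced by construction.
#' While clicked, the grasp-velocity channel `vg` carries a sustained hold
#' drive (`config$click_hold_drive`) with minimum-jerk ramps, modelling
#' continued grasp effort; click information therefore lives only in
#' grasp-tuned channels.
#'
#' The `imagery` mode selects which ground-truth coefficients drive
#' translation-related activity: `"abstract"` uses the proximal-weighted
#' reach coefficients (`enc_bx`, `enc_by`), `"wrist"` the distal-weighted
#' wrist-joystick coefficients (`enc_wx`, `enc_wy`).
#'
#' @inheritParams simulate_somatotopy_session
#' @param imagery `"abstract"` (whole-arm reach imagery) or `"wrist"`
#'   (wrist-as-joystick imagery).
#' @param clicks Generate click-and-drag epochs.
#' @param n_trials Number of trials; defaults to `config$cursor_n_trials`
#'   (40) without clicks, or to `config$n_click_epochs` (12 or 13, drawn at
#'   random when unset) with clicks.
#' @return An `ibci_session` with kinematics including `click_state`.
#' @export
simulate_cursor_session <- function(pop, config = attr(pop, "config"),
                                    seed = 1L,
                                    imagery = c("abstract", "wrist"),
                                    clicks = FALSE, n_trials = NULL,
                                    keep_truth = FALSE) {
  imagery <- match.arg(imagery)
  set.seed(as.integer(seed))
  br <- config$bin_rate
  hold <- config$hold_duration_s
  rd <- config$reach_duration_s
  if (is.null(n_trials)) {
    n_trials <- if (clicks) {
      if (is.null(config$n_click_epochs)) sample(12:13, 1L) else config$n_click_epochs
    } else config$cursor_n_trials
  }
  n_trials <- as.integer(n_trials)

  # hold + reach out (unclicked) then return (clicked drag + clicked hold, or
  # unclicked return + hold): both state totals are hold + rd seconds.
  segs <- c(hold, rd, rd, hold)
  labs <- c("hold", "reach", "return", "hold")
  trial_dur <- sum(segs)
  bins_per_trial <- round(trial_dur * br)
  nb <- n_trials * bins_per_trial

  dirs <- cursor_target_directions(8L)
  target_seq <- unlist(lapply(seq_len(ceiling(n_trials / 8)),
                              function(i) sample.int(8L)))[seq_len(n_trials)]

  V <- matrix(0, nb, 4, dimnames = list(NULL, c("vx", "vy", "vz", "vg")))
  click <- integer(nb)
  phase <- rep("hold", nb)
  start_s <- (seq_len(n_trials) - 1L) * trial_dur
  ramp <- 0.2  # s, minimum-jerk press/release ramp of the click hold drive

  for (i in seq_len(n_trials)) {
    t0 <- start_s[i]
    off <- cumsum(c(0, segs))
    u <- dirs[target_seq[i], ]
    out_bins <- seg_bins(t0 + off[2], rd, br)
    tc <- (seq_along(out_bins) - 0.5) / br
    V[out_bins, 1:2] <- outer(min_jerk_speed(tc, config$target_distance, rd), u)
    phase[out_bins] <- "reach"
    back_bins <- seg_bins(t0 + off[3], rd, br)
    V[back_bins, 1:2] <- outer(min_jerk_speed(tc, config$target_distance, rd), -u)
    phase[back_bins] <- if (clicks) "drag" else "return"
    if (clicks) {
      cl_bins <- c(back_bins, seg_bins(t0 + off[4], hold, br))
      click[cl_bins] <- 1L
      tcl <- (seq_along(cl_bins) - 0.5) / br
      dur_cl <- length(cl_bins) / br
      vg <- rep(config$click_hold_drive, length(cl_bins))
      vg[tcl < ramp] <- config$click_hold_drive *
        ramp_shape(tcl[tcl < ramp] / ramp)
      tail_sel <- tcl > dur_cl - ramp
      vg[tail_sel] <- config$click_hold_drive *
        ramp_shape((dur_cl - tcl[tail_sel]) / ramp)
      V[cl_bins, 4] <- vg
    }
  }

  trials <- data.frame(trial_id = seq_len(n_trials),
                       movement_label = paste0("target_", target_seq),
                       start_s = start_s, end_s = start_s + trial_dur)
  kin <- data.frame(time_s = (seq_len(nb) - 0.5) / br,
                    vx = V[, 1], vy = V[, 2], vz = V[, 3], vg = V[, 4],
                    phase_label = phase, click_state = click,
                    trial_id = rep(seq_len(n_trials), each = bins_per_trial))
  cc <- if (imagery == "abstract") c("enc_bx", "enc_by") else c("enc_wx", "enc_wy")
  sess <- build_encoded_session(pop, config, seed, V, trials, kin,
                                paste0("cursor_", imagery), keep_truth,
                                coef_cols = c(cc[1], cc[2], "enc_bz", "enc_bg"))
  # vz is identically zero in the cursor task, so enc_bz never contributes.
  sess$imagery <- imagery
  sess
}

# Smoothstep ramp on [0,1] (minimum-jerk position profile).
ramp_shape <- function(x) x^3 * (10 - 15 * x + 6 * x^2)

#' Count click-unclick epochs in a session
#'
#' @param session An `ibci_session` with kinematics.
#' @return Number of contiguous clicked runs.
#' @export
count_click_epochs <- function(session) {
  stopifnot(!is.null(session$kinematics))
  r <- rle(session$kinematics$click_state)
  sum(r$values == 1L)
}

#' Materialize spike-event times from binned counts
#'
#' Draws `counts[c, k]` event times uniformly within bin `k`'s half-open
#' interval, per channel. The total number of events equals the total count.
#'
#' @param session An `ibci_session`.
#' @param seed Seed for the within-bin placement.
#' @return List of sorted numeric vectors of event times (seconds), one per
#'   channel.
#' @export
materialize_events <- function(session, seed = 1L) {
  set.seed(as.integer(seed))
  dt <- 1 / session$bin_rate
  lapply(seq_len(nrow(session$counts)), function(c) {
    k <- session$counts[c, ]
    nz <- which(k > 0L)
    if (!length(nz)) return(numeric(0))
    starts <- rep((nz - 1L) * dt, k[nz])
    sort(starts + stats::runif(length(starts)) * dt * (1 - 1e-12))
  })
}
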