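#' Canonical movement labels
#'
#' The four attempted movements of the somatotopy-mapping task, ordered
#' distal to proximal. This ordering is also the tie-break order used by the
#' movement classifier.
#'
#' @return Character vector `c("grasp", "wrist", "elbow", "shoulder")`.
#' @export
movement_labels <- function() c("grasp", "wrist", "elbow", "shoulder")

# Movements driven by distal (hand/wrist) vs proximal (elbow/shoulder) musculature.
DISTAL_MOVEMENTS   <- c("grasp", "wrist")
PROXIMAL_MOVEMENTS <- c("elbow", "shoulder")

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha_family Family-wise error rate.
#' @param n_tests Number of tests in the family.
#' @return `alpha_family / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 4)  # 0.0125, the per-movement tuning threshold
#' bonferroni_alpha(0.05, 3)  # ~0.0167, the post-hoc pairwise threshold
#' @export
bonferroni_alpha <- function(alpha_family = 0.05, n_tests = 1L) {
  stopifnot(is.numeric(alpha_family), alpha_family > 0, alpha_family < 1,
            n_tests >= 1)
  alpha_family / n_tests
}

#' Configuration of the per-channel tuning significance test
#'
#' Four movement types are tested per channel, so the family-wise alpha of
#' 0.05 is Bonferroni-divided into a per-test threshold of 0.0125.
#'
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param n_tests Number of movement types tested per channel (default 4).
#' @return A list of class `"tuning_test_config"` with elements
#'   `alpha_family`, `n_tests` and `alpha_per_test`.
#' @export
tuning_test_config <- function(alpha_family = 0.05, n_tests = 4L) {
  structure(
    list(alpha_family = alpha_family,
         n_tests = as.integer(n_tests),
         alpha_per_test = bonferroni_alpha(alpha_family, n_tests)),
    class = "tuning_test_config")
}

#' Synthetic cortical population and task generator configuration
#'
#' Collects every knob of the synthetic generator: array geometry, the
#' mediolateral tuning gradient, trial/phase structure of the
#' somatotopy-mapping task, kinematics of the virtual-arm and cursor tasks,
#' and the noise model. Defaults mirror the recording and task conditions of
#' a two-array human intracortical session: two 96-channel arrays binned at
#' 50 Hz, trials of Baseline 3 s / Movement 3 s / Rest 2 s in 20
#' block-randomized blocks (80 trials), 18-36 virtual-arm trials, 40
#' wrist-imagery cursor trials, and 12-13 click-unclick epochs per
#' click-and-drag session.
#'
#' @param n_channels_per_array Channels per array (<= 100 on a 10 x 10 grid;
#'   default 96, the four grid corners left unwired).
#' @param baseline_rate Mean baseline firing rate, spikes/s.
#' @param baseline_cv Coefficient of variation of per-channel baseline rates
#'   (gamma-distributed; 0 gives identical baselines).
#' @param depth_scale Mean absolute modulation depth of a tuned channel at
#'   the gradient-neutral position, spikes/s.
#' @param depth_cv Coefficient of variation of sampled depths around their
#'   position-dependent expectation.
#' @param gradient_slope Strength of the mediolateral somatotopic gradient.
#'   0 is flat; at the default the expected depth varies by a factor
#'   (1 +/- slope/2) between the array extremes, distal movements stronger
#'   laterally, proximal stronger medially.
#' @param untuned_fraction Fraction of channels with zero depth for every
#'   movement (and zero encoding coefficients).
#' @param prop_negative Fraction of tuned (channel, movement) depths that are
#'   suppressive (negative).
#' @param phase_durations_s Named numeric `(baseline, movement, rest)` phase
#'   durations in seconds.
#' @param n_blocks Number of 4-trial blocks in a somatotopy session.
#' @param poisson Draw Poisson counts (`TRUE`) or use deterministic
#'   cumulative-rounding counts (`FALSE`).
#' @param noise_scale Standard deviation (z-units) of per-bin Gaussian rate
#'   noise added on top of the tuning/encoding signal.
#' @param rate_sd Spikes/s per z-unit when converting z-scale drive to firing
#'   rate (`rate = max(0, baseline + z * rate_sd)`).
#' @param enc_translation_scale Mean magnitude of the 3-D translation
#'   encoding coefficient vector (z-units per workspace-unit/s).
#' @param enc_grasp_scale Mean magnitude of the grasp-velocity encoding
#'   coefficient (z-units per aperture-unit/s).
#' @param arm_n_trials Trials per virtual-arm session.
#' @param cursor_n_trials Trials per wrist/abstract-imagery cursor session.
#' @param target_distance Reach distance, workspace units.
#' @param reach_duration_s Duration of one minimum-jerk translation segment.
#' @param grasp_duration_s Duration of one grasp open/close segment.
#' @param hold_duration_s Inter-segment hold duration.
#' @param grasp_distance Aperture excursion of a grasp segment.
#' @param click_hold_drive Sustained grasp drive (aperture-units/s
#'   equivalent) while the clicked state is held; what makes click state
#'   decodable from grasp-tuned channels.
#' @param n_click_epochs Click-unclick epochs per click-and-drag session;
#'   `NULL` draws 12 or 13 at random as in the historical sessions.
#' @param bin_rate Count bin rate, Hz (fixed at 50 for all analyses).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_channels_per_array = 96L,
                             baseline_rate = 10,
                             baseline_cv = 0.5,
                             depth_scale = 8,
                             depth_cv = 0.3,
                             gradient_slope = 1.2,
                             untuned_fraction = 0.5,
                             prop_negative = 0.15,
                             phase_durations_s = c(baseline = 3, movement = 3, rest = 2),
                             n_blocks = 20L,
                             poisson = TRUE,
                             noise_scale = 0.3,
                             rate_sd = 4,
                             enc_translation_scale = 3,
                             enc_grasp_scale = 0.8,
                             arm_n_trials = 24L,
                             cursor_n_trials = 40L,
                             target_distance = 0.3,
                             reach_duration_s = 1.2,
                             grasp_duration_s = 0.8,
                             hold_duration_s = 0.4,
                             grasp_distance = 1,
                             click_hold_drive = 1,
                             n_click_epochs = NULL,
                             bin_rate = 50) {
  cfg <- list(n_channels_per_array = as.integer(n_channels_per_array),
              baseline_rate = baseline_rate, baseline_cv = baseline_cv,
              depth_scale = depth_scale, depth_cv = depth_cv,
              gradient_slope = gradient_slope,
              untuned_fraction = untuned_fraction,
              prop_negative = prop_negative,
              phase_durations_s = phase_durations_s,
              n_blocks = as.integer(n_blocks),
              poisson = isTRUE(poisson),
              noise_scale = noise_scale, rate_sd = rate_sd,
              enc_translation_scale = enc_translation_scale,
              enc_grasp_scale = enc_grasp_scale,
              arm_n_trials = as.integer(arm_n_trials),
              cursor_n_trials = as.integer(cursor_n_trials),
              target_distance = target_distance,
              reach_duration_s = reach_duration_s,
              grasp_duration_s = grasp_duration_s,
              hold_duration_s = hold_duration_s,
              grasp_distance = grasp_distance,
              click_hold_drive = click_hold_drive,
              n_click_epochs = if (is.null(n_click_epochs)) NULL else as.integer(n_click_epochs),
              bin_rate = bin_rate)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_channels_per_array < 1L)
    stop("configuration error: n_channels_per_array must be positive", call. = FALSE)
  if (cfg$n_channels_per_array > 100L)
    stop("configuration error: at most 100 channels fit a 10 x 10 grid", call. = FALSE)
  if (any(cfg$phase_durations_s <= 0))
    stop("configuration error: phase durations must be positive", call. = FALSE)
  if (cfg$n_blocks < 1L)
    stop("configuration error: n_blocks must be >= 1", call. = FALSE)
  if (cfg$baseline_rate < 0 || cfg$noise_scale < 0 || cfg$rate_sd <= 0)
    stop("configuration error: rates and noise scales must be non-negative", call. = FALSE)
  if (cfg$untuned_fraction < 0 || cfg$untuned_fraction > 1)
    stop("configuration error: untuned_fraction must lie in [0, 1]", call. = FALSE)
  if (abs(cfg$gradient_slope) > 2)
    stop("configuration error: |gradient_slope| > 2 makes expected depths negative", call. = FALSE)
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cortex generator configuration\n")
  cat(sprintf("  %d channels/array on two arrays (medial, lateral), %g Hz bins\n",
              x$n_channels_per_array, x$bin_rate))
  cat(sprintf("  baseline %g sp/s, tuned depth %g sp/s, gradient slope %g, untuned %g\n",
              x$baseline_rate, x$depth_scale, x$gradient_slope, x$untuned_fraction))
  cat(sprintf("  phases (s): baseline %g / movement %g / rest %g; %d blocks (%d trials)\n",
              x$phase_durations_s[["baseline"]], x$phase_durations_s[["movement"]],
              x$phase_durations_s[["rest"]], x$n_blocks, 4L * x$n_blocks))
  invisible(x)
}
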