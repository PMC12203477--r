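# Shared fixture builders. Sessions are generated at reduced size where the
# assertion does not depend on the full 96-channel, 20-block geometry.

config_with <- function(defaults, dots) {
  defaults[names(dots)] <- dots
  do.call(generator_config, defaults)
}

small_config <- function(...) {
  config_with(list(n_channels_per_array = 16L, n_blocks = 5L), list(...))
}

# All modulation depths zero: movement carries no information.
null_config <- function(...) {
  config_with(list(depth_scale = 0, untuned_fraction = 1, baseline_cv = 0),
              list(...))
}

# Deterministic strongly tuned population: every channel tuned with the same
# positive depth, no gradient, no rate jitter.
flat_tuned_config <- function(depth, ...) {
  config_with(list(depth_scale = depth, depth_cv = 0, gradient_slope = 0,
                   untuned_fraction = 0, prop_negative = 0, baseline_cv = 0),
              list(...))
}

# Minimal hand-built somatotopy-like session around an explicit counts
# matrix, for window-arithmetic tests that need exact rates.
manual_session <- function(counts, trials, bin_rate = 50) {
  nch <- nrow(counts)
  map <- data.frame(channel_id = seq_len(nch),
                    array_id = rep(c("lateral", "medial"), length.out = nch),
                    grid_row = 0L, grid_col = seq_len(nch) - 1L,
                    mediolateral_pos = 0.5)
  structure(list(counts = counts, bin_rate = bin_rate, trials = trials,
                 kinematics = NULL, array_map = map, seed = 0L,
                 task = "somatotopy", config = generator_config(),
                 truth = NULL),
            class = "ibci_session")
}

manual_window <- function(offsets, movement = "grasp", bin_rate = 50) {
  structure(list(movement = movement,
                 t_M = (offsets[(length(offsets) + 1) %/% 2] + 0.5) / bin_rate,
                 window_offsets = as.integer(offsets), pc1 = NULL,
                 pc1_offsets = NULL, bin_rate = bin_rate),
            class = "movement_window")
}
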