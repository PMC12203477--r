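test_that("somatotopy sessions have the standard block-randomized structure", {
  cfg <- generator_config(n_channels_per_array = 8L)
  pop <- make_population(cfg, seed = 1)
  s <- simulate_somatotopy_session(pop, cfg, seed = 2)
  expect_equal(nrow(s$trials), 80L)  # 20 blocks of 4
  # each consecutive block of 4 trials is a permutation of the movements
  for (b in seq_len(20L)) {
    block <- s$trials$movement_label[(b - 1L) * 4L + 1:4]
    expect_setequal(block, movement_labels())
  }
  # phase onsets strictly increasing within each trial
  expect_true(all(s$trials$baseline_onset_s < s$trials$movement_onset_s))
  expect_true(all(s$trials$movement_onset_s < s$trials$rest_onset_s))
  expect_true(all(s$trials$rest_onset_s < s$trials$end_s))
  expect_true(all(s$counts >= 0L))
  expect_equal(ncol(s$counts), 80L * 400L)
})

test_that("sessions are bit-identical given the same population and seed", {
  cfg <- small_config()
  pop <- make_population(cfg, seed = 5)
  s1 <- simulate_somatotopy_session(pop, cfg, seed = 7)
  s2 <- simulate_somatotopy_session(pop, cfg, seed = 7)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$trials, s2$trials)
  a1 <- simulate_reach_grasp_session(pop, cfg, seed = 8)
  a2 <- simulate_reach_grasp_session(pop, cfg, seed = 8)
  expect_identical(a1$counts, a2$counts)
  expect_identical(a1$kinematics, a2$kinematics)
})

test_that("null populations show no movement-window excess counts", {
  cfg <- null_config(n_channels_per_array = 24L, n_blocks = 10L)
  pop <- make_population(cfg, seed = 3)
  s <- simulate_somatotopy_session(pop, cfg, seed = 4)
  br <- s$bin_rate
  mov <- base <- NULL
  for (i in seq_len(nrow(s$trials))) {
    mb <- round(s$trials$movement_onset_s[i] * br) + 1:25
    bb <- round(s$trials$movement_onset_s[i] * br) - 24:0
    mov <- c(mov, sum(s$counts[, mb]))
    base <- c(base, sum(s$counts[, bb]))
  }
  # equal means within Poisson sampling error (3 SE of the difference)
  se <- sqrt(mean(mov) + mean(base)) / sqrt(length(mov))
  expect_lt(abs(mean(mov) - mean(base)), 3 * se)
})

test_that("noiseless deterministic rates equal baseline plus the tuning bump", {
  cfg <- generator_config(n_channels_per_array = 4L, n_blocks = 1L,
                          depth_scale = 12, depth_cv = 0, gradient_slope = 0,
                          untuned_fraction = 0, prop_negative = 0,
                          baseline_cv = 0, noise_scale = 0, poisson = FALSE)
  pop <- make_population(cfg, seed = 1)
  s <- simulate_somatotopy_session(pop, cfg, seed = 2, keep_truth = TRUE)
  tr <- s$trials[s$trials$movement_label == "grasp", ][1, ]
  bins <- round(tr$movement_onset_s * 50) + 1:150
  peak <- max(s$truth$rate[1, bins])
  expect_equal(peak, cfg$baseline_rate + 12, tolerance = 1e-3)
  # outside the movement phase the rate is the baseline
  bb <- round(tr$baseline_onset_s * 50) + 1:150
  expect_equal(unique(s$truth$rate[1, bb]), cfg$baseline_rate)
})

test_that("minimum-jerk segments peak at 1.875 * distance / duration", {
  D <- 0.3; T <- 1.2
  tt <- seq(0, T, by = 1e-4)
  v <- min_jerk_speed(tt, D, T)
  expect_equal(max(v), 1.875 * D / T, tolerance = 1e-6)  # closed form
  expect_equal(tt[which.max(v)], T / 2, tolerance = 1e-3)
  # displacement integrates to the distance
  expect_equal(sum(v) * 1e-4, D, tolerance = 1e-4)
  expect_equal(min_jerk_speed(c(-0.1, T + 0.1), D, T), c(0, 0))
})

test_that("encoding-driven sessions satisfy the generative identity", {
  cfg <- generator_config(n_channels_per_array = 8L, noise_scale = 0,
                          poisson = FALSE, arm_n_trials = 4L)
  pop <- make_population(cfg, seed = 11)
  s <- simulate_reach_grasp_session(pop, cfg, seed = 12, keep_truth = TRUE)
  V <- as.matrix(s$kinematics[, c("vx", "vy", "vz", "vg")])
  B <- as.matrix(pop[, c("enc_bx", "enc_by", "enc_bz", "enc_bg")])
  f <- pop$enc_b0 + B %*% t(V)
  expect_equal(unname(f), unname(s$truth$latent), tolerance = 1e-12)
  # velocities identically zero leave every channel at its intercept
  pop0 <- pop
  s0 <- simulate_reach_grasp_session(pop0, cfg, seed = 13, keep_truth = TRUE)
  still <- s0$kinematics$phase_label == "pause"
  expect_true(all(abs(s0$truth$latent[, still] - pop$enc_b0) < 1e-12))
})

test_that("reach-grasp sessions require encoding coefficients", {
  cfg <- small_config()
  pop <- make_population(cfg, seed = 1)
  pop$enc_bx <- NA_real_
  expect_error(simulate_reach_grasp_session(pop, cfg, seed = 1), "coefficient")
})

test_that("cursor sessions have the documented trial and epoch counts", {
  cfg <- generator_config(n_channels_per_array = 8L)
  pop <- make_population(cfg, seed = 21)
  s <- simulate_cursor_session(pop, cfg, seed = 22, imagery = "wrist")
  expect_equal(nrow(s$trials), 40L)
  epochs <- vapply(1:6, function(k) {
    cs <- simulate_cursor_session(pop, cfg, seed = 30 + k,
                                  imagery = "abstract", clicks = TRUE)
    count_click_epochs(cs)
  }, 0L)
  expect_true(all(epochs %in% c(12L, 13L)))
  expect_equal(sort(unique(epochs)), c(12L, 13L))
  # clicked and unclicked durations balanced by construction
  cs <- simulate_cursor_session(pop, cfg, seed = 30, imagery = "abstract",
                                clicks = TRUE)
  expect_equal(mean(cs$kinematics$click_state), 0.5, tolerance = 1e-6)
  expect_error(simulate_cursor_session(pop, cfg, seed = 1, imagery = "leg"),
               "arg")
})

test_that("center-out target layout is symmetric", {
  d <- cursor_target_directions(8L)
  expect_equal(colSums(d), c(x = 0, y = 0), tolerance = 1e-12)
  expect_equal(rowSums(d^2), rep(1, 8), tolerance = 1e-12)
})

test_that("materialized events conserve the total count and re-bin exactly", {
  cfg <- small_config(n_blocks = 1L)
  pop <- make_population(cfg, seed = 31)
  s <- simulate_somatotopy_session(pop, cfg, seed = 32)
  ev <- materialize_events(s, seed = 33)
  expect_equal(sum(lengths(ev)), sum(s$counts))
  rebinned <- bin_spikes(ev, duration_s = ncol(s$counts) / s$bin_rate)
  expect_identical(unname(rebinned), unname(s$counts))
})
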