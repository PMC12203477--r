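test_that("response windows are 500 ms, inside the phase, at the population peak", {
  cfg <- generator_config(n_channels_per_array = 16L, n_blocks = 5L,
                          depth_scale = 15, depth_cv = 0, gradient_slope = 0,
                          untuned_fraction = 0, prop_negative = 0,
                          baseline_cv = 0, noise_scale = 0, poisson = FALSE)
  pop <- make_population(cfg, seed = 1)
  s <- simulate_somatotopy_session(pop, cfg, seed = 2)
  w <- find_movement_window(s, "grasp")
  expect_length(w$window_offsets, 25L)      # 500 ms at 50 Hz
  expect_true(all(w$window_offsets >= 0 & w$window_offsets < 150))
  # raised-cosine bump peaks at the phase center (1.5 s); smoothing delays
  # the smoothed peak, so allow the causal-kernel lag (~100 ms)
  expect_lt(abs(w$t_M - 1.5), 0.12 + 0.02)
})

test_that("a single-channel session reduces PCA to the channel itself", {
  cfg <- generator_config(n_channels_per_array = 16L, n_blocks = 3L,
                          depth_scale = 20, depth_cv = 0, gradient_slope = 0,
                          untuned_fraction = 0, prop_negative = 0,
                          baseline_cv = 0)
  pop <- make_population(cfg, seed = 5)
  s <- simulate_somatotopy_session(pop, cfg, seed = 6)
  sm <- preprocess_session(s)
  sm1 <- sm
  sm1$active <- c(TRUE, rep(FALSE, length(sm$active) - 1L))
  w <- find_movement_window(s, "wrist", sm = sm1)
  # PC1 of one variable is the (centered) variable: locate its peak directly
  tr <- s$trials[s$trials$movement_label == "wrist", ]
  offs <- w$pc1_offsets
  avg <- rowMeans(sapply(tr$movement_onset_s, function(on)
    sm$zrates[1, round(on * 50) + 1 + offs]))
  in_phase <- offs >= 0 & offs < 150
  manual <- offs[in_phase][which.max(abs((avg - mean(avg))[in_phase]))]
  expect_equal((manual + 0.5) / 50, w$t_M)
})

test_that("trial deltas integrate the rate difference between windows", {
  # step rate 10 -> 30 spikes/s across the movement window; deterministic
  # cumulative-rounding counts conserve the integral
  br <- 50
  nb <- 400L
  rate <- rep(10, nb)
  rate[151:300] <- 30  # movement phase bins of a single trial
  counts1 <- diff(c(0, round(cumsum(rate / br))))
  counts <- matrix(rep(counts1, 2), 1)   # two identical 8 s trials
  trials <- data.frame(trial_id = 1:2, movement_label = "grasp",
                       start_s = c(0, 8), baseline_onset_s = c(0, 8),
                       movement_onset_s = c(3, 11), rest_onset_s = c(6, 14),
                       end_s = c(8, 16))
  s <- manual_session(counts, trials)
  w <- manual_window(62:86)              # 500 ms inside the movement phase
  d <- trial_deltas(s, w, "grasp", channel = 1)
  expect_equal(d, rep((30 - 10) * 0.5, 2), tolerance = 0.1)
  # identical rate in both windows gives zero delta (baseline vs early rest)
  wr <- manual_window(175:199)           # within rest, rate back at 10
  expect_true(all(trial_deltas(s, wr, "grasp", 1) == 0))
  # window beyond the recording errors
  expect_error(trial_deltas(s, manual_window(500:524), "grasp", 1), "extent")
})

test_that("deltas on a Poisson null population average to zero", {
  cfg <- null_config(n_channels_per_array = 8L, n_blocks = 20L)
  pop <- make_population(cfg, seed = 7)
  s <- simulate_somatotopy_session(pop, cfg, seed = 8)
  w <- manual_window(60:84)
  d <- trial_deltas(s, w, "grasp", channel = seq_len(nrow(s$counts)))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * se)
})

test_that("the tuning t-test matches the from-scratch formula and degenerates safely", {
  cfg <- tuning_test_config()
  expect_equal(cfg$alpha_per_test, 0.0125)
  deltas <- c(3, 5, 4, 6, 2, 5, 4, 5, 3, 4, 5, 4, 6, 3, 4, 5, 4, 3, 5, 4)
  res <- test_tuning(deltas, cfg)
  t_manual <- mean(deltas) / (sd(deltas) / sqrt(length(deltas)))
  p_manual <- 2 * pt(-abs(t_manual), length(deltas) - 1)
  expect_equal(res$t_stat, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_true(res$significant)

  z <- test_tuning(rep(0, 10), cfg)
  expect_false(z$significant)
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  cz <- test_tuning(rep(3, 10), cfg)   # constant non-zero is also degenerate
  expect_true(cz$degenerate)
  expect_error(test_tuning(1), "trials")
})

test_that("depth of modulation keeps the signed largest excursion", {
  # hand-built smoothed rates: flat baseline 10, excursions -5 and +3 in the
  # movement window
  nb <- 400L
  rates <- matrix(10, 1, nb)
  rates[1, 160:170] <- 5    # -5 excursion
  rates[1, 200:210] <- 13   # +3 excursion
  counts <- matrix(0L, 1, nb)
  trials <- data.frame(trial_id = 1L, movement_label = "grasp", start_s = 0,
                       baseline_onset_s = 0, movement_onset_s = 3,
                       rest_onset_s = 6, end_s = 8)
  s <- manual_session(counts, trials)
  sm <- list(rates = rates, zrates = rates, zmean = 0, zsd = 1, active = TRUE)
  w <- manual_window(0:80)
  w$window_offsets <- 0:80  # wide window covering both excursions
  d <- depth_of_modulation(s, w, "grasp", channel = 1, sm = sm)
  expect_equal(d, -5)
  # flat rates give zero depth
  szero <- manual_session(counts, trials)
  smf <- list(rates = matrix(10, 1, nb), zrates = NULL, active = TRUE)
  expect_equal(depth_of_modulation(szero, w, "grasp", 1, sm = smf), 0)
})

test_that("high-SNR tuning recovers the generated tuned subsets", {
  cfg <- generator_config(n_channels_per_array = 24L, depth_scale = 15,
                          depth_cv = 0, gradient_slope = 0,
                          untuned_fraction = 0.5, prop_negative = 0,
                          baseline_cv = 0)
  pop <- make_population(cfg, seed = 21)
  s <- simulate_somatotopy_session(pop, cfg, seed = 22)
  tt <- map_tuning(s)
  any_sig <- tapply(tt$significant, tt$channel_id, any)
  truth <- pop$tuned[match(as.integer(names(any_sig)), pop$channel_id)]
  expect_gt(mean(any_sig == truth), 0.95)
  pr <- proportions_by_array(tt)
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1, na.rm = TRUE))
})

test_that("channels tuned at depth 10 are detected with power above 0.95", {
  # 20 trials per movement, baseline 10 spikes/s, |depth| = 10 on every
  # channel; nominal power at alpha 0.0125 is ~0.998 (Monte-Carlo on the
  # window-count t-test)
  cfg <- flat_tuned_config(10, n_channels_per_array = 48L)
  pop <- make_population(cfg, seed = 31)
  sig <- unlist(lapply(1:2, function(i) {
    s <- simulate_somatotopy_session(pop, cfg, seed = 310 + i)
    map_tuning(s)$significant
  }))
  expect_gt(mean(sig), 0.95)
})

test_that("tuning proportions handle the all-significant and none-significant cases", {
  tt <- data.frame(channel_id = rep(1:4, each = 4),
                   array_id = "medial",
                   movement = rep(movement_labels(), 4),
                   significant = TRUE)
  map <- data.frame(channel_id = 1:4, array_id = "medial")
  pr <- proportions_by_array(tt, map)
  expect_equal(pr$proportion, rep(1, 4))
  tt$significant <- FALSE
  pr0 <- proportions_by_array(tt, map)
  expect_true(all(is.na(pr0$proportion)))
})

test_that("tuning heatmaps place every channel at its grid position", {
  cfg <- small_config()
  pop <- make_population(cfg, seed = 41)
  s <- simulate_somatotopy_session(pop, cfg, seed = 42)
  tt <- map_tuning(s)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(tt))
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
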