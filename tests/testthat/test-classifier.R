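test_that("features sum window counts and respect the channel mask", {
  cfg <- small_config(n_blocks = 2L)
  pop <- make_population(cfg, seed = 1)
  s <- simulate_somatotopy_session(pop, cfg, seed = 2)
  sm <- preprocess_session(s)
  windows <- lapply(stats::setNames(nm = movement_labels()),
                    function(m) find_movement_window(s, m, sm = sm))
  f <- movement_features(s, windows, active = sm$active)
  expect_equal(nrow(f), nrow(s$trials))
  expect_equal(ncol(f), sum(sm$active))
  expect_true(all(f >= 0))
  # two-path consistency: features from materialized events equal features
  # from the counts matrix
  ev <- materialize_events(s, seed = 3)
  s2 <- s
  s2$counts <- bin_spikes(ev, duration_s = ncol(s$counts) / s$bin_rate)
  f2 <- movement_features(s2, windows, active = sm$active)
  expect_identical(unname(f), unname(f2))
  expect_error(movement_features(s, windows[1:2]), "missing response window")
  # a window of 25 bins each holding one count gives feature 25
  szero <- s
  szero$counts[] <- 1L
  fz <- movement_features(szero, windows, active = sm$active)
  expect_true(all(fz == 25L))
})

test_that("LOOCV naive Bayes is perfect on separated classes and errors on bad folds", {
  set.seed(4)
  x <- rbind(matrix(rpois(40, 5), 10), matrix(rpois(40, 60), 10),
             matrix(rpois(40, 200), 10), matrix(rpois(40, 500), 10))
  y <- rep(movement_labels(), each = 10)
  res <- loocv_classify(x, y)
  expect_equal(res$overall_accuracy, 1)
  expect_equal(unname(rowSums(res$confusion)), rep(10, 4))
  expect_equal(sum(res$confusion), res$n)
  expect_error(loocv_classify(x[c(1, 11:40), ], y[c(1, 11:40)]), "2 trials")
})

test_that("Gaussian LOOCV decisions equal the closed-form likelihood-ratio rule", {
  set.seed(5)
  n <- 15
  x <- matrix(c(rnorm(n, 0, 1), rnorm(n, 1.2, 1)), ncol = 1)
  y <- rep(c("a", "b"), each = n)
  res <- loocv_classify(x, y)
  floorv <- function(tr) 1e-9 + 1e-3 * mean(apply(tr, 2, var))
  oracle <- vapply(seq_along(y), function(i) {
    tr <- x[-i, , drop = FALSE]; ty <- y[-i]
    fl <- floorv(tr)
    ll <- vapply(c("a", "b"), function(l) {
      m <- mean(tr[ty == l, 1]); v <- max(var(tr[ty == l, 1]), fl)
      dnorm(x[i, 1], m, sqrt(v), log = TRUE)
    }, 0)
    c("a", "b")[which.max(ll)]
  }, "")
  expect_identical(res$predicted, oracle)
})

test_that("Gaussian naive Bayes agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(6)
  n <- 10
  x <- rbind(matrix(rnorm(3 * n, 0), ncol = 3),
             matrix(rnorm(3 * n, 2), ncol = 3),
             matrix(rnorm(3 * n, 4), ncol = 3),
             matrix(rnorm(3 * n, 6), ncol = 3))
  colnames(x) <- paste0("f", 1:3)
  y <- rep(movement_labels(), each = n)
  res <- loocv_classify(x, y)
  ref <- vapply(seq_along(y), function(i) {
    fit <- e1071::naiveBayes(x[-i, ], factor(y[-i], movement_labels()))
    as.character(predict(fit, x[i, , drop = FALSE]))
  }, "")
  expect_identical(res$predicted, ref)
})

test_that("the Poisson flavor classifies count features", {
  set.seed(7)
  x <- rbind(matrix(rpois(30, 3), 10), matrix(rpois(30, 30), 10))
  y <- rep(c("grasp", "wrist"), each = 10)
  res <- loocv_classify(x, y, flavor = "poisson")
  expect_equal(res$overall_accuracy, 1)
})

test_that("pooled confusions sum element-wise and preserve accuracy identities", {
  cfg <- small_config(n_blocks = 3L, depth_scale = 12, untuned_fraction = 0.3)
  pop <- make_population(cfg, seed = 8)
  r1 <- classify_movements(simulate_somatotopy_session(pop, cfg, seed = 9))
  r2 <- classify_movements(simulate_somatotopy_session(pop, cfg, seed = 10))
  pooled <- pool_confusions(list(r1, r2))
  expect_equal(pooled$confusion, r1$confusion + r2$confusion)
  # pooling a session with itself doubles every cell
  dbl <- pool_confusions(list(r1, r1))
  expect_equal(dbl$confusion, 2 * r1$confusion)
  # pooled accuracy is the trial-weighted mean of per-session accuracies
  expect_equal(pooled$overall_accuracy,
               (r1$n * r1$overall_accuracy + r2$n * r2$overall_accuracy) /
                 (r1$n + r2$n), tolerance = 1e-12)
})

test_that("accuracy rises monotonically with generated tuning depth", {
  # depth scales the per-movement differential tuning (channels draw
  # independent depths per movement, so movement identity is encoded in the
  # across-channel pattern); at 0 there is no information at all
  depths <- c(0, 5, 10, 20)
  acc <- vapply(depths, function(d) {
    per_seed <- vapply(1:3, function(k) {
      cfg <- generator_config(n_channels_per_array = 24L, n_blocks = 5L,
                              depth_scale = d,
                              untuned_fraction = if (d == 0) 1 else 0.3)
      pop <- make_population(cfg, seed = 100 + k)
      classify_movements(simulate_somatotopy_session(pop, cfg, seed = 200 + k))$overall_accuracy
    }, 0)
    mean(per_seed)
  }, 0)
  expect_true(all(diff(acc) >= 0))
})

test_that("label-permuted data classifies at chance", {
  cfg <- generator_config(n_channels_per_array = 24L, depth_scale = 12,
                          untuned_fraction = 0.3)
  pop <- make_population(cfg, seed = 11)
  res <- lapply(1:5, function(k) {
    s <- simulate_somatotopy_session(pop, cfg, seed = 300 + k)
    set.seed(400 + k)
    s$trials$movement_label <- sample(s$trials$movement_label)
    classify_movements(s)
  })
  pooled <- pool_confusions(res)
  half <- 2.576 * sqrt(0.25 * 0.75 / pooled$n)
  expect_lt(abs(pooled$overall_accuracy - 0.25), half + 1e-12)
})
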