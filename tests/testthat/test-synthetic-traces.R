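test_that("an absorbing start state yields one segment spanning the window", {
  m <- rate_model(matrix(c(0, 0, 0.5, -0.5), 2, byrow = TRUE),
                  emission_level = c(0, 0.75))
  p <- sample_state_path(m, duration = 100, start = 1, seed = 1)
  expect_equal(length(p$states), 1L)
  expect_equal(p$states, 1L)
  expect_equal(path_dwells(p)$duration, 100)
})

test_that("sampled dwell times reproduce the exponential means of the generator", {
  m <- two_state_model(k_on = 0.0296, k_off = 0.051)
  p <- sample_state_path(m, duration = 1e5, start = 1, seed = 42)
  d <- path_dwells(p)
  d <- d[!d$truncated, ]
  d0 <- d$duration[d$state == 1]
  mean_expected <- 1 / 0.0296  # 33.8 s
  se <- mean_expected / sqrt(length(d0))
  expect_gt(length(d0), 500)
  expect_lt(abs(mean(d0) - mean_expected), 3 * se)

  d1 <- d$duration[d$state == 2]
  expect_lt(abs(mean(d1) - 1 / 0.051), 3 * (1 / 0.051) / sqrt(length(d1)))
})

test_that("ground-truth dwells are exponential by a KS test", {
  m <- two_state_model(0.5, 0.5)
  p <- sample_state_path(m, duration = 4e4, start = 1, seed = 7)
  d <- path_dwells(p)
  d0 <- d$duration[d$state == 1 & !d$truncated]
  expect_gt(length(d0), 5000)
  expect_gt(stats::ks.test(d0, "pexp", rate = 0.5)$p.value, 0.01)
})

test_that("long-run occupancy matches the stationary distribution", {
  m3 <- ebs1_rate_models()$ibs1_mg$model
  pi <- stationary_distribution(m3)
  p <- sample_state_path(m3, duration = 2e5, start = "stationary", seed = 5)
  d <- path_dwells(p)
  t_bound <- sum(d$duration[d$state %in% c(2, 3)])
  frac <- t_bound / p$duration
  expected <- pi[["1"]] + pi[["2"]]
  # binomial-style error from the number of independent bound periods
  n_per <- sum(d$state == 1)
  se <- sqrt(expected * (1 - expected) / n_per)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("camera binning averages emission levels by occupancy", {
  m <- two_state_model(0.1, 0.1)
  # entirely in state 0
  p0 <- make_path(0, 1L, 10)
  f0 <- bin_to_frames(p0, dt = 0.2, m)
  expect_equal(nrow(f0), 50L)
  expect_true(all(f0$fret_ideal == 0))
  expect_true(all(f0$state == 1L))
  # transition exactly at mid-frame: that frame averages the two levels
  p <- make_path(c(0, 0.3), c(1L, 2L), 0.6)
  f <- bin_to_frames(p, dt = 0.2, m)
  expect_equal(f$fret_ideal, c(0, 0.375, 0.75))
})

test_that("degenerate states bin identically to their merged two-state version", {
  m3 <- three_state_model(0.1, 0.2, 0.3, 0.4)
  m2 <- two_state_model(0.1, 0.2)
  p3 <- make_path(c(0, 1.1, 2.7, 3.3, 7.9), c(1L, 2L, 3L, 2L, 1L), 10)
  p2 <- make_path(c(0, 1.1, 7.9), c(1L, 2L, 1L), 10)  # merge-then-bin oracle
  expect_equal(bin_to_frames(p3, 0.2, m3)$fret_ideal,
               bin_to_frames(p2, 0.2, m2)$fret_ideal)
})

test_that("noise-free emission round-trips the ideal FRET exactly", {
  m <- two_state_model(0.05, 0.05)
  p <- sample_state_path(m, 50, start = 1, seed = 3)
  frames <- bin_to_frames(p, 0.2, m)
  em0 <- emission_model(total_intensity = 500, fret_noise_sd = 0,
                        background_donor = 0, background_acceptor = 0,
                        bleedthrough = 0)
  tr <- emit_intensities(frames, em0, dt = 0.2, seed = 1)
  expect_equal(tr$fret, frames$fret_ideal, tolerance = 1e-12)

  # with background and bleedthrough the matching correction restores it
  em1 <- emission_model(total_intensity = 500, fret_noise_sd = 0,
                        background_donor = 80, background_acceptor = 120,
                        bleedthrough = 0.12)
  tr1 <- emit_intensities(frames, em1, dt = 0.2, seed = 1)
  corr <- correct_intensities(tr1$donor, tr1$acceptor,
                              correction_params_for(em1))
  expect_equal(compute_fret(corr$donor, corr$acceptor), frames$fret_ideal,
               tolerance = 1e-9)
})

test_that("emitted FRET noise has the requested standard deviation", {
  m <- rate_model(matrix(0.0, 1, 1), emission_level = 0.75)
  p <- make_path(0, 1L, 2000)
  frames <- bin_to_frames(p, 0.2, m)
  tr <- emit_intensities(frames, emission_model(fret_noise_sd = 0.1),
                         dt = 0.2, seed = 2)
  expect_equal(stats::sd(tr$fret - 0.75) /
                 sqrt(1 - 1 / length(tr$fret)), 0.1, tolerance = 0.05)
})

test_that("ensembles are reproducible and degeneracy-invariant", {
  m3 <- three_state_model(0.05, 0.2, 0.3, 0.1)
  e1 <- simulate_ensemble(m3, emission_model(), 3, duration = 50, dt = 0.2,
                          seed = 123)
  e2 <- simulate_ensemble(m3, emission_model(), 3, duration = 50, dt = 0.2,
                          seed = 123)
  expect_identical(lapply(e1, as.data.frame), lapply(e2, as.data.frame))

  # relabeling within the degenerate group leaves emitted traces unchanged
  m3_swapped <- rate_model(
    m3$K[c(1, 3, 2), c(1, 3, 2)],
    emission_level = m3$emission_level[c(1, 3, 2)],
    state_labels = c("0", "2", "1"),
    degenerate_groups = list(1L, c(2L, 3L)))
  e3 <- simulate_ensemble(m3_swapped, emission_model(), 3, duration = 50,
                          dt = 0.2, seed = 123)
  for (i in 1:3) {
    expect_equal(e3[[i]]$donor, e1[[i]]$donor)
    expect_equal(e3[[i]]$acceptor, e1[[i]]$acceptor)
  }
})

test_that("ensemble high-FRET occupancy matches the stationary prediction", {
  m <- two_state_model(0.1, 0.05)
  pi <- stationary_distribution(m)
  ens <- simulate_ensemble(m, emission_model(), 30, duration = 400, dt = 0.2,
                           seed = 9)
  frac_high <- mean(unlist(lapply(ens, function(tr) tr$truth_state == 2)))
  # s.e. from the number of independent bound periods across the ensemble
  n_periods <- sum(vapply(ens, function(tr)
    sum(diff(tr$truth_state) == 1), numeric(1)))
  se <- sqrt(pi[2] * (1 - pi[2]) / n_periods)
  expect_lt(abs(frac_high - pi[2]), 3 * se)
})

test_that("photobleaching truncates the signal to background only", {
  m <- rate_model(matrix(0.0, 1, 1), emission_level = 0.75)
  frames <- bin_to_frames(make_path(0, 1L, 100), 0.2, m)
  em <- emission_model(fret_noise_sd = 0, background_donor = 50,
                       background_acceptor = 50, bleach_rate = 0.5)
  tr <- emit_intensities(frames, em, dt = 0.2, seed = 4)
  bleached <- tr$donor == 50 & tr$acceptor == 50
  expect_true(any(bleached))
  expect_true(all(diff(bleached) >= 0))  # once bleached, stays bleached
  # bleach_rate -> NULL limit: no truncation
  em0 <- emission_model(fret_noise_sd = 0, background_donor = 50,
                        background_acceptor = 50)
  tr0 <- emit_intensities(frames, em0, dt = 0.2, seed = 4)
  expect_false(any(tr0$donor == 50 & tr0$acceptor == 50))
})
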