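test_that("threshold discretization is exact on noiseless traces", {
  m <- two_state_model(0.05, 0.05)
  p <- sample_state_path(m, 200, start = 1, seed = 10)
  frames <- bin_to_frames(p, 0.2, m)
  tr <- emit_intensities(frames, emission_model(fret_noise_sd = 0,
                                                background_donor = 0,
                                                background_acceptor = 0),
                         dt = 0.2, seed = 1)
  s <- discretize_threshold(tr$fret, 0.375)
  expect_equal(s, c("zero", "high")[frames$state])
  expect_error(discretize_threshold(tr$fret, 1.2), "strictly inside")
  expect_equal(unique(discretize_threshold(rep(0.1, 20), 0.375)), "zero")
})

test_that("frame misclassification stays below the Gaussian tail bound", {
  m <- two_state_model(0.03, 0.05)
  ens <- simulate_ensemble(m, emission_model(fret_noise_sd = 0.1), 20,
                           duration = 400, dt = 0.2, seed = 13)
  err <- vapply(ens, function(tr) {
    s <- discretize_threshold(tr$fret, 0.375)
    mean(s != c("zero", "high", "high")[tr$truth_state])
  }, numeric(1))
  expect_lt(mean(err), 0.01)  # Phi(-3.75) plus blurred transition frames
})

test_that("dwell extraction converts runs to flagged durations", {
  dw <- extract_dwells(c("zero", "zero", "high", "high", "high", "zero"),
                       dt = 0.2)
  expect_equal(dw$duration, c(0.4, 0.6, 0.2))
  expect_equal(dw$state, c("zero", "high", "zero"))
  expect_equal(dw$truncated_start, c(TRUE, FALSE, FALSE))
  expect_equal(dw$truncated_end, c(FALSE, FALSE, TRUE))
  # constant trace: one fully truncated dwell, nothing usable
  dw2 <- extract_dwells(rep("zero", 7), dt = 0.2)
  expect_equal(nrow(dw2), 1L)
  expect_true(dw2$truncated_start & dw2$truncated_end)
})

test_that("usable high dwells of a simulated ensemble average to 1/k_off", {
  m <- two_state_model(0.2, 0.1)
  ens <- simulate_ensemble(m, emission_model(fret_noise_sd = 0), 40,
                           duration = 1000, dt = 0.1, seed = 17)
  dw <- ensemble_dwells(ens, threshold = 0.375)
  high <- dw[dw$state == "high" & !dw$truncated_start & !dw$truncated_end, ]
  expect_gt(nrow(high), 1000)
  se <- (1 / 0.1) / sqrt(nrow(high))
  expect_lt(abs(mean(high$duration) - 1 / 0.1), 3 * se)
})

test_that("trace summaries report per-state means and ranges", {
  dw <- data.frame(trace_id = "t", state = c("zero", "high", "zero", "high",
                                             "zero"),
                   duration = c(1, 2, 5, 4, 2),
                   truncated_start = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                   truncated_end = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  s <- summarize_trace(dw)
  expect_equal(s$t_high_mean, 3)
  expect_equal(s$delta_t_high, 2)
  expect_equal(s$t_zero_mean, 5)
  expect_equal(s$delta_t_zero, 0)  # single usable zero dwell
  expect_equal(s$n_transitions, 4L)
})

test_that("cluster centres behave as k-means centroids", {
  sm <- data.frame(t_zero_mean = c(1, 2, 3, 10, 11, 12),
                   t_high_mean = c(2, 2, 2, 9, 10, 11))
  c1 <- cluster_center(sm, k = 1)
  expect_equal(as.numeric(c1), c(mean(sm$t_zero_mean), mean(sm$t_high_mean)))
  c2 <- cluster_center(sm, k = 2, seed = 4)
  expect_equal(as.numeric(c2[1, ]), c(2, 2), tolerance = 1e-8)
  expect_equal(as.numeric(c2[2, ]), c(11, 10), tolerance = 1e-8)
  # duplicating the data set leaves centroids unchanged
  c2d <- cluster_center(rbind(sm, sm), k = 2, seed = 4)
  expect_equal(c2d, c2)
  expect_error(cluster_center(sm[1:2, ], k = 3), "fewer points")
})

test_that("per-molecule Kd is the dwell ratio scaled by concentration", {
  sm <- data.frame(t_zero_mean = c(10, 40), t_high_mean = c(10, 20))
  expect_equal(per_molecule_kd(sm, 35), c(35, 70))
  expect_equal(per_molecule_kd(sm, 70), 2 * per_molecule_kd(sm, 35))
  sm$t_high_mean[2] <- NA
  expect_true(is.na(per_molecule_kd(sm, 35)[2]))
})

test_that("logistic fit recovers the transition point of a Kd distribution", {
  set.seed(5)
  kd_true <- 29; p_true <- 2
  u <- stats::runif(200, 0.02, 0.98)
  kd_n <- kd_true * (u / (1 - u))^(1 / p_true)  # inverse of the logistic cdf
  fit <- fit_logistic_cdf(kd_n, n_boot = 20, seed = 3)
  expect_equal(fit$kd, kd_true, tolerance = 0.1)
  expect_equal(fit$p, p_true, tolerance = 0.25)
  # P evaluated at the transition point is one half
  P <- function(x) 1 / (1 + (fit$kd / x)^fit$p)
  expect_equal(P(fit$kd), 0.5)
  expect_error(fit_logistic_cdf(rep(5, 20)), "identical")
})

test_that("survival curves count the fraction of dwells at least t long", {
  dw <- data.frame(trace_id = "t",
                   state = rep("high", 5), duration = c(0.5, 1, 2, 4, 9),
                   truncated_start = c(TRUE, rep(FALSE, 4)),
                   truncated_end = c(rep(FALSE, 4), TRUE))
  sc <- survival_curve(dw, "high")
  expect_equal(sc$surv[sc$time == 0], 1)
  expect_equal(sc$surv[sc$time == 2], 2 / 3)
  expect_equal(attr(sc, "durations"), c(1, 2, 4))
})

test_that("biexponential survival fits recover a two-component decay", {
  set.seed(8)
  n <- 2000
  fast <- stats::runif(n) < 0.96
  d <- ifelse(fast, stats::rexp(n, 0.5), stats::rexp(n, 0.02))
  dw <- data.frame(trace_id = "t", state = "high", duration = d,
                   truncated_start = FALSE, truncated_end = FALSE)
  fit <- fit_biexponential(survival_curve(dw, "high"), n_boot = 10, seed = 1)
  expect_equal(fit$model, "biexp")
  expect_equal(fit$w, 0.96, tolerance = 0.1)
  expect_equal(fit$k1, 0.5, tolerance = 0.1)
  expect_equal(fit$k2, 0.02, tolerance = 0.2)
  expect_gte(fit$k1, fit$k2)

  # pure single exponential degrades gracefully to the "single" tag
  d1 <- stats::rexp(1500, 0.2)
  dw1 <- data.frame(trace_id = "t", state = "high", duration = d1,
                    truncated_start = FALSE, truncated_end = FALSE)
  fit1 <- fit_biexponential(survival_curve(dw1, "high"), n_boot = 5, seed = 1)
  expect_equal(fit1$model, "single")
})

test_that("stretched-exponential fits recover tau and beta", {
  set.seed(9)
  # beta = 1 reduces to a pure exponential with tau = 1/k
  d1 <- stats::rexp(1500, 0.1)
  dw1 <- data.frame(trace_id = "t", state = "high", duration = d1,
                    truncated_start = FALSE, truncated_end = FALSE)
  fit1 <- fit_stretched_exp(survival_curve(dw1, "high"), n_boot = 5, seed = 1)
  expect_equal(fit1$tau, 10, tolerance = 0.1)
  expect_gt(fit1$beta, 0.95)

  # Weibull dwells with beta = 0.8, tau = 30
  u <- stats::runif(2000)
  d <- 30 * (-log(u))^(1 / 0.8)
  dw <- data.frame(trace_id = "t", state = "high", duration = d,
                   truncated_start = FALSE, truncated_end = FALSE)
  fit <- fit_stretched_exp(survival_curve(dw, "high"), n_boot = 5, seed = 1)
  expect_equal(fit$tau, 30, tolerance = 0.1)
  expect_equal(fit$beta, 0.8, tolerance = 0.1)

  # a genuine rate mixture is fitted with beta < 1
  fast <- stats::runif(2000) < 0.6
  dmix <- ifelse(fast, stats::rexp(2000, 0.5), stats::rexp(2000, 0.05))
  dwm <- data.frame(trace_id = "t", state = "high", duration = dmix,
                    truncated_start = FALSE, truncated_end = FALSE)
  fitm <- fit_stretched_exp(survival_curve(dwm, "high"), n_boot = 5, seed = 1)
  expect_lt(fitm$beta, 0.9)
})

test_that("heterogeneous three-state ensembles couple dwell mean and range", {
  # three-state with slow exchange: long and short bound dwells mix per trace
  m3 <- three_state_model(k_on = 0.05, k_off = 0.4, k12 = 0.2, k21 = 0.02)
  e3 <- simulate_ensemble(m3, emission_model(), 60, duration = 400, dt = 0.2,
                          seed = 23)
  s3 <- summarize_ensemble(e3)
  ok3 <- stats::complete.cases(s3[, c("t_high_mean", "delta_t_high")])
  r3 <- stats::cor(s3$t_high_mean[ok3], s3$delta_t_high[ok3])
  expect_gt(r3, 0.5)
})
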