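test_that("forward likelihood equals brute-force path enumeration", {
  set.seed(61)
  spec3 <- spec_three_state_degenerate()
  means <- c(0, 0.75); sds <- c(0.1, 0.12)
  A <- matrix(c(0.9, 0.1, 0,
                0.05, 0.85, 0.1,
                0, 0.2, 0.8), 3, byrow = TRUE)
  start <- c(0.5, 0.3, 0.2)
  for (T_ in c(1, 4, 8)) {
    x <- stats::rnorm(T_, sample(c(0, 0.75), T_, replace = TRUE), 0.1)
    B <- fretkin:::make_B(x, spec3, means, sds)
    ll <- fretkin:::hmm_loglik(B, A, start)
    expect_equal(ll, brute_force_loglik(x, A, start, means, sds,
                                        spec3$emission_map),
                 tolerance = 1e-10)
    fb <- fretkin:::hmm_forward_backward(B, A, start)
    expect_equal(fb$loglik, ll, tolerance = 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, T_), tolerance = 1e-10)
  }
})

test_that("Viterbi path score matches exhaustive enumeration", {
  set.seed(62)
  spec3 <- spec_three_state_degenerate()
  means <- c(0, 0.75); sds <- c(0.1, 0.12)
  A <- matrix(c(0.9, 0.1, 0,
                0.05, 0.85, 0.1,
                0, 0.2, 0.8), 3, byrow = TRUE)
  start <- c(0.6, 0.2, 0.2)
  params <- fake_params(A, means, sds, spec3, start)
  for (rep in 1:3) {
    x <- stats::rnorm(7, sample(c(0, 0.75), 7, replace = TRUE), 0.12)
    v <- viterbi_path(x, params)
    expect_equal(v$logprob,
                 brute_force_viterbi(x, A, start, means, sds,
                                     spec3$emission_map),
                 tolerance = 1e-10)
  }
})

test_that("Viterbi decodes a noiseless trace exactly and respects emission support", {
  spec2 <- spec_two_state()
  A <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE)
  params <- fake_params(A, c(0, 0.75), c(0.05, 0.05), spec2)
  truth <- c(1, 1, 2, 2, 2, 1, 2, 1, 1)
  x <- c(0, 0.75)[truth]
  expect_equal(viterbi_path(x, params)$path, truth)

  # degenerate three-state params: zero-FRET frames decode to state 1
  spec3 <- spec_three_state_degenerate()
  A3 <- matrix(c(0.9, 0.1, 0, 0.05, 0.85, 0.1, 0, 0.2, 0.8), 3, byrow = TRUE)
  p3 <- fake_params(A3, c(0, 0.75), c(0.05, 0.05), spec3)
  path3 <- viterbi_path(c(0, 0, 0.75, 0.75, 0, 0), p3)$path
  expect_true(all(path3[c(1, 2, 5, 6)] == 1))
  expect_true(all(path3[c(3, 4)] %in% c(2, 3)))
})

test_that("per-trace EM reproduces the count-based MLE on noiseless traces", {
  set.seed(63)
  truth <- rep(rep(1:2, 8), times = rep(c(6, 4), 8))
  x <- c(0, 0.75)[truth]
  fit <- train_trace_hmm(x, spec_two_state(), n_restarts = 2, seed = 1)
  ord <- order(fit$means)
  expect_equal(fit$means[ord], c(0, 0.75), tolerance = 1e-6)
  # closed-form MLE of the transition matrix from observed state counts
  cnt <- matrix(0, 2, 2)
  for (t in 2:length(truth)) cnt[truth[t - 1], truth[t]] <-
      cnt[truth[t - 1], truth[t]] + 1
  A_mle <- cnt / rowSums(cnt)
  A_fit <- fit$A[ord, ord]
  expect_equal(A_fit, A_mle, tolerance = 1e-4)
})

test_that("a single-state spec yields the trace mean and a unit chain", {
  x <- stats::rnorm(200, 0.4, 0.05)
  fit <- train_trace_hmm(x, hmm_spec(1), n_restarts = 1, seed = 1)
  expect_equal(fit$A, matrix(1, 1, 1))
  expect_equal(fit$means, mean(x), tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(64)
  x <- stats::rnorm(300, sample(c(0, 0.75), 300, TRUE), 0.15)
  fit <- train_trace_hmm(x, spec_two_state(), n_restarts = 1, seed = 2,
                         tol = 1e-10, max_iter = 60)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("global fits match single-trace fits on replicated data and ignore order", {
  set.seed(65)
  m <- two_state_model(0.05, 0.08)
  ens <- simulate_ensemble(m, emission_model(), 6, duration = 150, dt = 0.2,
                           seed = 31)
  em <- list(means = c(0, 0.75), sds = c(0.1, 0.1))
  # an ensemble of identical traces equals the per-trace fit with fixed emissions
  one <- ens[[1]]$fret
  g1 <- train_global_hmm(list(one, one), spec_two_state(), em, seed = 1,
                         blur = FALSE)  # same likelihood as the trace stage
  s1 <- train_trace_hmm(one, spec_two_state(), fixed_emissions = em, seed = 1)
  expect_equal(g1$A, s1$A, tolerance = 1e-5)
  # permutation invariance of the summed likelihood
  ga <- train_global_hmm(ens, spec_two_state(), em, seed = 1)
  gb <- train_global_hmm(rev(ens), spec_two_state(), em, seed = 1)
  expect_equal(ga$loglik, gb$loglik, tolerance = 1e-6)
  expect_equal(ga$A, gb$A, tolerance = 1e-6)
})

test_that("BIC arithmetic and parameter-count penalties are exact", {
  expect_equal(compute_bic(0, 0, 100), 0)
  n <- 5000
  expect_equal(compute_bic(-100, 3, n) - compute_bic(-100, 2, n), log(n))
})

test_that("BIC selects the true kinetic network order", {
  set.seed(66)
  em <- list(means = c(0, 0.75), sds = c(0.1, 0.1))
  specs <- list(spec_two_state(), spec_three_state_degenerate())
  # two-state truth
  m2 <- two_state_model(0.05, 0.1)
  e2 <- simulate_ensemble(m2, emission_model(), 15, duration = 300, dt = 0.2,
                          seed = 41)
  sel2 <- select_model(e2, specs, em, seed = 1, n_restarts = 2)
  expect_equal(sel2$name[1], "two-state")
  # strongly heterogeneous degenerate three-state truth
  m3 <- three_state_model(k_on = 0.05, k_off = 0.5, k12 = 0.35, k21 = 0.03)
  e3 <- simulate_ensemble(m3, emission_model(), 40, duration = 400, dt = 0.2,
                          seed = 43)
  sel3 <- select_model(e3, specs, em, seed = 1, n_restarts = 2)
  expect_equal(sel3$name[1], "three-state degenerate")
  expect_true(all(c("bic", "delta_bic", "converged") %in% names(sel3)))
  expect_equal(sel3$delta_bic[1], 0)
})

test_that("transition probabilities convert to rates by both conventions", {
  A <- matrix(c(1 - 0.00592, 0.00592, 0.0102, 1 - 0.0102), 2, byrow = TRUE)
  K <- transition_to_rates(A, 0.2)
  expect_equal(K[1, 2], 2.96e-2)
  expect_equal(transition_to_rates(diag(3), 0.1),
               matrix(0, 3, 3))
  # matrix-log inverts the exact exponential for slow rates
  m <- two_state_model(0.01, 0.02)
  A_exact <- as.matrix(Matrix::expm(m$K * 0.2))
  K_back <- transition_to_rates(A_exact, 0.2, method = "logm")
  expect_equal(K_back, m$K, tolerance = 1e-6)
  # fast transitions trigger the linear-approximation warning
  A_fast <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  expect_warning(transition_to_rates(A_fast, 0.2), "0.1")
})

test_that("state populations aggregate degeneracy and give the footnote Kd", {
  spec3 <- spec_three_state_degenerate()
  # equal bound/unbound occupancy: Kd equals the ligand concentration
  A_eq <- matrix(c(0.9, 0.1, 0, 0.18, 0.72, 0.1, 0, 0.05, 0.95),
                 3, byrow = TRUE)
  p <- fake_params(A_eq, c(0, 0.75), c(0.1, 0.1), spec3)
  pops <- state_population_kd(p, ligand_conc = 35)
  expect_equal(sum(pops$populations), 1)
  expect_equal(pops$bound + pops$unbound, 1)

  # two-state at the high-salt RNA rates: Kd ~ c * k_off / k'_on ~ 60 nM
  m <- two_state_model(0.0296, 0.051)
  A2 <- as.matrix(Matrix::expm(m$K * 0.2))
  p2 <- fake_params(A2, c(0, 0.75), c(0.1, 0.1), spec_two_state())
  kd <- state_population_kd(p2, ligand_conc = 35)$kd
  expect_equal(kd, 35 * 0.051 / 0.0296, tolerance = 1e-6)

  # Viterbi-occupancy alternative agrees with stationarity on long traces
  set.seed(67)
  ens <- simulate_ensemble(m, emission_model(), 10, duration = 400, dt = 0.2,
                           seed = 51)
  kd_vit <- state_population_kd(p2, 35, method = "viterbi", traces = ens)$kd
  expect_equal(kd_vit, kd, tolerance = 0.3)
})

test_that("likelihood-ratio profiling brackets the estimate asymmetrically", {
  set.seed(68)
  m <- two_state_model(0.05, 0.1)
  ens <- simulate_ensemble(m, emission_model(), 8, duration = 200, dt = 0.2,
                           seed = 53)
  em <- list(means = c(0, 0.75), sds = c(0.1, 0.1))
  fit <- train_global_hmm(ens, spec_two_state(), em, seed = 1, tol = 1e-8)
  lr <- likelihood_ratio_errors(ens, fit, from = 2, to = 1, dt = 0.2)
  expect_false(lr$one_sided)
  expect_lt(lr$lower, lr$estimate)
  expect_gt(lr$upper, lr$estimate)
  # interval width is a few relative percent at ~1500 observed transitions
  expect_lt((lr$upper - lr$lower) / lr$estimate, 0.5)
  # confidence -> 0 collapses the interval onto the estimate
  lr0 <- likelihood_ratio_errors(ens, fit, from = 2, to = 1, confidence = 0)
  expect_equal(lr0$lower, lr0$estimate)
  expect_equal(lr0$upper, lr0$estimate)
})
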