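test_that("built rings round-trip phase and amplitude across the mode grid", {
  for (amp in c(20, 38)) {
    for (P in seq(0, 324, by = 36)) {
      ring <- build_sugar_ring(P, amp)
      st <- pseudorotation(ring)
      dphi <- min(abs(st$phase - P), 360 - abs(st$phase - P))
      expect_lt(dphi, 1)
      expect_lt(abs(st$amplitude - amp), 1)
      # sum identity of the torsion wave
      expect_lt(abs(sum(ring_torsions(ring))), 5)
    }
  }
})

test_that("canonical sugars classify to C3'-endo and C2'-endo", {
  north <- pseudorotation(build_sugar_ring(18, 38))
  expect_equal(north$phase, 18, tolerance = 0.03)
  expect_equal(north$mode, "C3'-endo")
  south <- pseudorotation(build_sugar_ring(162, 38))
  expect_equal(south$phase, 162, tolerance = 0.005)
  expect_equal(south$mode, "C2'-endo")
})

test_that("phase bins are 36 degrees wide with C3'-endo covering [0, 36)", {
  expect_equal(classify_pucker(18), "C3'-endo")
  expect_equal(classify_pucker(162), "C2'-endo")
  expect_equal(classify_pucker(0), "C3'-endo")
  expect_equal(classify_pucker(359.9), "C2'-exo")
  expect_equal(classify_pucker(c(36, 72, 108, 144)),
               c("C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo"))
  expect_true(is.na(classify_pucker(NA)))
})

test_that("planar rings have zero amplitude and undefined phase", {
  j <- 0:4
  flat <- sugar_ring(cbind(1.2 * cos(2 * pi * j / 5),
                           1.2 * sin(2 * pi * j / 5), 0))
  expect_equal(unname(ring_torsions(flat)), rep(0, 5), tolerance = 1e-10)
  st <- pseudorotation(flat)
  expect_lt(st$amplitude, 1e-6)
  expect_true(is.na(st$phase))
  expect_true(is.na(st$mode))
})

test_that("mirror reflection negates all torsions and shifts the phase by 180", {
  ring <- build_sugar_ring(18, 38)
  mirrored <- sugar_ring(ring$coords %*% diag(c(1, 1, -1)))
  expect_equal(unname(ring_torsions(mirrored)), unname(-ring_torsions(ring)),
               tolerance = 1e-9)
  st <- pseudorotation(mirrored)
  expect_equal(st$phase, (18 + 180) %% 360, tolerance = 0.05)
  expect_equal(st$mode, "C3'-exo")
})

test_that("phase measurement is rotation and translation invariant", {
  ring <- build_sugar_ring(126, 30)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sugar_ring(sweep(ring$coords %*% R, 2, c(5, -3, 12), "+"))
  st0 <- pseudorotation(ring)
  st1 <- pseudorotation(moved)
  expect_equal(st1$phase, st0$phase, tolerance = 1e-6)
  expect_equal(st1$amplitude, st0$amplitude, tolerance = 1e-6)
})

test_that("the torsion and Cartesian phase definitions agree", {
  for (P in seq(9, 351, by = 36)) {
    st <- pseudorotation(build_sugar_ring(P, 38))
    dphi <- min(abs(st$phase - st$phase_cart),
                360 - abs(st$phase - st$phase_cart))
    expect_lt(dphi, 2)
  }
})

test_that("circular histograms count phases and locate the circular median", {
  h1 <- pucker_histogram(rep(18, 50))
  expect_equal(sum(h1$counts > 0), 1L)
  expect_equal(h1$median, 18)
  set.seed(12)
  # bimodal north/south mixture: mass ratio of the two halves ~ 70/30
  P <- c(stats::rnorm(700, 18, 10), stats::rnorm(300, 162, 10)) %% 360
  h <- pucker_histogram(P, n_bins = 10)
  north_mass <- sum(h$counts[h$centres < 90 | h$centres > 270])
  expect_equal(north_mass / sum(h$counts), 0.7, tolerance = 0.05)
  expect_error(pucker_histogram(NA_real_), "no defined phase")
})

test_that("telegraph-process pucker trajectories yield the closed-form correlation time", {
  set.seed(77)
  k <- 0.01  # per ps, both directions: tau = 1/(2k) = 50 ps
  n <- 60000
  s <- integer(n); s[1] <- 1L
  flip <- stats::runif(n - 1) < k
  s <- as.integer(cumsum(c(s[1], flip)) %% 2)
  P <- ifelse(s == 1, 18, 162)  # north / south
  out <- repucker_correlation_time(P, dt_ps = 1)
  expect_equal(out$tau_ps, 50, tolerance = 0.25)
  expect_equal(out$mean_dwell_N_ps, 100, tolerance = 0.15)
  expect_equal(out$k_NS_per_ps, 0.01, tolerance = 0.15)
  # time reversal leaves the autocorrelation, hence tau, unchanged
  out_rev <- repucker_correlation_time(rev(P), dt_ps = 1)
  expect_equal(out_rev$tau_ps, out$tau_ps, tolerance = 1e-8)
  # constant trajectory reports the one-sided branch
  out0 <- repucker_correlation_time(rep(18, 500), dt_ps = 1)
  expect_true(out0$one_sided)
  expect_equal(out0$k_NS_per_ps, 1 / 500)
})

test_that("torsion time series files convert to phase trajectories", {
  path <- tempfile(fileext = ".tsv")
  j <- 0:4
  rows <- do.call(rbind, lapply(c(18, 162, 90), function(P)
    data.frame(time_ps = P, residue = "U1",
               t(stats::setNames(38 * cos((P + 144 * (j - 2)) * pi / 180),
                                 paste0("nu", 0:4))))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ts <- read_torsion_series(path)
  expect_equal(ts$phase, c(18, 162, 90), tolerance = 1e-6)
  expect_equal(ts$amplitude, rep(38, 3), tolerance = 1e-6)
  # phase-only variant
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(time_ps = 1:3, residue = "U1",
                                P = c(-10, 20, 400)),
                     path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_torsion_series(path2)$phase, c(350, 20, 40))
  expect_error(read_torsion_series(
    {p <- tempfile(); writeLines("a\tb\n1\t2", p); p}), "time_ps")
})

test_that("PDB reading extracts rings per model and skips incomplete residues", {
  path <- tempfile(fileext = ".pdb")
  rings <- list(
    list(build_sugar_ring(18, 38, resid = 1),
         build_sugar_ring(162, 36, resid = 2, deoxy = TRUE)),
    list(build_sugar_ring(20, 38, resid = 1),
         build_sugar_ring(150, 36, resid = 2, deoxy = TRUE)),
    list(build_sugar_ring(16, 38, resid = 1),
         build_sugar_ring(170, 36, resid = 2, deoxy = TRUE)))
  # append a protein residue that must be skipped
  extra <- sprintf(
    "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    90:93, c("N", "CA", "C", "O"), 9, 20 + runif(4), 20 + runif(4),
    20 + runif(4))
  write_ring_pdb(rings, path, extra_lines = extra)
  expect_warning(models <- read_structure(path), "skipped")
  expect_length(models, 3L)
  expect_length(models[[1]], 2L)
  st <- pseudorotation(models[[1]][[1]])
  expect_equal(st$mode, "C3'-endo")
  expect_equal(st$phase, 18, tolerance = 0.5)
  expect_true(models[[1]][[2]]$deoxy)
  expect_false(models[[1]][[1]]$deoxy)
})
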