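#' Exact-event state path of a continuous-time Markov chain
#'
#' Gillespie-style simulation: the dwell in state \eqn{i} is drawn from
#' Exponential\eqn{(-K_{ii})} and the successor is chosen with probability
#' proportional to \eqn{k_{ij}}. A state with zero exit rate is absorbing and
#' yields a single segment spanning the full duration.
#'
#' @param model A [rate_model()].
#' @param duration Total path duration (s).
#' @param start Starting state: 1-based index, state label, or `"stationary"`
#'   to draw from [stationary_distribution()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `state_path`: list with `times` (segment onset times, s, starting
#'   at 0), `states` (1-based state index per segment), `duration`.
#' @export
sample_state_path <- function(model, duration, start = "stationary",
                              seed = NULL) {
  stopifnot(inherits(model, "rate_model"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(model$K)
  if (identical(start, "stationary")) {
    pi <- stationary_distribution(model)
    s <- sample.int(n, 1, prob = pi)
  } else if (is.character(start)) {
    s <- match(start, model$state_labels)
    if (is.na(s)) stop("unknown start state label: ", start)
  } else {
    s <- as.integer(start)
    if (s < 1 || s > n) stop("start state index out of range")
  }
  times <- numeric(0)
  states <- integer(0)
  t <- 0
  while (t < duration) {
    times <- c(times, t)
    states <- c(states, s)
    exit <- -model$K[s, s]
    if (exit <= 0) break  # absorbing: segment runs to the end
    t <- t + stats::rexp(1, rate = exit)
    if (t >= duration) break
    rates <- model$K[s, ]
    rates[s] <- 0
    s <- sample.int(n, 1, prob = rates)
  }
  structure(list(times = times, states = states, duration = duration),
            class = "state_path")
}

#' Segment durations of a state path
#' @param path A `state_path`.
#' @return Data frame with `state` (1-based index), `duration` (s), and
#'   `truncated` (TRUE for the final segment, cut by the observation window,
#'   and for the first segment, whose entry time is unobserved).
#' @export
path_dwells <- function(path) {
  stopifnot(inherits(path, "state_path"))
  k <- length(path$times)
  ends <- c(path$times[-1], path$duration)
  data.frame(state = path$states,
             duration = ends - path$times,
             truncated = seq_len(k) %in% c(1L, k))
}

#' Bin a continuous-time state path into camera frames
#'
#' The camera integrates photons over each frame, so the ideal frame value is
#' the occupancy-weighted average of the emission levels of the states visited
#' during the frame. The state occupying the largest share of the frame is
#' kept as the ground-truth label (useful for benchmarking discretizers).
#'
#' @param path A `state_path` from [sample_state_path()].
#' @param dt Frame interval (s), e.g. 0.2 s (5 Hz) or 0.1 s (10 Hz).
#' @param model The generating [rate_model()] supplying emission levels.
#' @return Data frame with `frame` (0-based), `time_s` (frame start),
#'   `fret_ideal`, `state` (dominant state, 1-based index).
#' @export
bin_to_frames <- function(path, dt, model) {
  stopifnot(inherits(path, "state_path"), dt > 0)
  n_frames <- floor(path$duration / dt + 1e-9)
  if (n_frames < 1) stop("duration shorter than one frame")
  levels <- model$emission_level
  n_states <- length(levels)
  starts <- path$times
  ends <- c(path$times[-1], path$duration)
  fret <- numeric(n_frames)
  dom <- integer(n_frames)
  # indices of segments overlapping each frame; segments are few relative to
  # frames for slow kinetics, so iterate over segments
  occ <- matrix(0, n_frames, n_states)
  for (j in seq_along(starts)) {
    f0 <- floor(starts[j] / dt)
    f1 <- min(ceiling(ends[j] / dt) - 1, n_frames - 1)
    if (f1 < f0) next
    for (f in f0:f1) {
      if (f >= n_frames) break
      lo <- max(starts[j], f * dt)
      hi <- min(ends[j], (f + 1) * dt)
      if (hi > lo) occ[f + 1, path$states[j]] <- occ[f + 1, path$states[j]] + (hi - lo)
    }
  }
  fret <- as.numeric(occ %*% levels) / dt
  dom <- max.col(occ, ties.method = "first")
  data.frame(frame = seq_len(n_frames) - 1L,
             time_s = (seq_len(n_frames) - 1L) * dt,
             fret_ideal = fret, state = dom)
}

#' Camera emission model for simulated traces
#'
#' Describes how ideal FRET levels are turned into noisy two-channel count
#' traces: a fixed total intensity split between acceptor and donor, Gaussian
#' FRET noise, additive channel backgrounds, donor bleedthrough into the
#' acceptor channel, and an optional exponential photobleaching time after
#' which both channels contain background only.
#'
#' @param total_intensity Summed donor + acceptor counts per frame.
#' @param fret_noise_sd Standard deviation of the apparent FRET efficiency.
#' @param background_donor,background_acceptor Counts per frame added to each
#'   channel. The defaults are large enough relative to the channel noise
#'   (`fret_noise_sd * total_intensity`) that clipping raw counts at zero is
#'   a rare event, keeping the corrected FRET noise effectively Gaussian.
#' @param bleedthrough Fraction of the donor signal leaking into the acceptor
#'   channel (in `[0, 1)`).
#' @param bleach_rate Optional photobleaching rate (\eqn{s^{-1}}); `NULL`
#'   disables bleaching.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(total_intensity = 500, fret_noise_sd = 0.1,
                           background_donor = 150, background_acceptor = 150,
                           bleedthrough = 0, bleach_rate = NULL) {
  stopifnot(total_intensity >= 0, fret_noise_sd >= 0,
            background_donor >= 0, background_acceptor >= 0,
            bleedthrough >= 0, bleedthrough < 1,
            is.null(bleach_rate) || bleach_rate >= 0)
  structure(list(total_intensity = total_intensity,
                 fret_noise_sd = fret_noise_sd,
                 background_donor = background_donor,
                 background_acceptor = background_acceptor,
                 bleedthrough = bleedthrough,
                 bleach_rate = bleach_rate),
            class = "emission_model")
}

#' Single-molecule FRET trace container
#'
#' @param donor,acceptor Per-frame channel intensities (counts).
#' @param dt Frame interval (s).
#' @param fret Optional per-frame FRET efficiency; computed with
#'   [compute_fret()] if omitted.
#' @param truth_state Optional ground-truth dominant state per frame.
#' @param trace_id Optional identifier.
#' @return Object of class `fret_trace`: data frame with columns
#'   `time_s`, `donor`, `acceptor`, `fret` (and `truth_state` if given),
#'   with attributes `dt` and `trace_id`.
#' @export
fret_trace <- function(donor, acceptor, dt, fret = NULL, truth_state = NULL,
                       trace_id = "trace_1") {
  stopifnot(length(donor) == length(acceptor), dt > 0)
  if (is.null(fret)) fret <- compute_fret(donor, acceptor)
  stopifnot(length(fret) == length(donor))
  df <- data.frame(time_s = (seq_along(donor) - 1) * dt,
                   donor = donor, acceptor = acceptor, fret = fret)
  if (!is.null(truth_state)) {
    stopifnot(length(truth_state) == length(donor))
    df$truth_state <- truth_state
  }
  structure(df, dt = dt, trace_id = trace_id,
            class = c("fret_trace", "data.frame"))
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("FRET trace '%s': %d frames at dt = %g s (%.1f s)\n",
              attr(x, "trace_id"), nrow(x), attr(x, "dt"),
              nrow(x) * attr(x, "dt")))
  invisible(x)
}

#' Emit noisy two-channel intensities for binned frames
#'
#' The ideal split is \eqn{I_A = E I_{tot}}, \eqn{I_D = (1-E) I_{tot}}.
#' Gaussian noise is applied on the FRET axis so that the apparent FRET
#' recomputed from the noisy channels has standard deviation equal to
#' `fret_noise_sd` (before background and bleedthrough). Background counts
#' are then added to both channels and a `bleedthrough` fraction of the
#' corrected donor signal is added to the acceptor channel — the algebraic
#' inverse of [correct_intensities()]. If `bleach_rate` is set, a bleaching
#' time is drawn from Exponential(`bleach_rate`) and frames after it carry
#' background only. Negative raw counts are clipped at zero (rare when the
#' backgrounds dominate the channel noise).
#'
#' The returned trace stores the *raw* channels in `donor`/`acceptor`, while
#' its `fret` column holds the efficiency recomputed from the channels after
#' applying [correct_intensities()] with the matching parameters — i.e. what
#' a standard processing pipeline would extract. Without clipping this
#' equals the ideal level plus the Gaussian FRET noise exactly.
#'
#' @param frames Data frame from [bin_to_frames()].
#' @param emission An [emission_model()].
#' @param dt Frame interval (s).
#' @param seed Optional integer seed.
#' @param trace_id Identifier passed to [fret_trace()].
#' @return A [fret_trace()] carrying `truth_state`.
#' @export
emit_intensities <- function(frames, emission, dt, seed = NULL,
                             trace_id = "trace_1") {
  stopifnot(inherits(emission, "emission_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(frames)
  E <- frames$fret_ideal
  if (emission$fret_noise_sd > 0)
    E <- E + stats::rnorm(n, sd = emission$fret_noise_sd)
  I_tot <- emission$total_intensity
  I_A <- E * I_tot
  I_D <- (1 - E) * I_tot
  if (!is.null(emission$bleach_rate) && emission$bleach_rate > 0) {
    t_bleach <- stats::rexp(1, emission$bleach_rate)
    bleached <- frames$time_s >= t_bleach
    I_A[bleached] <- 0
    I_D[bleached] <- 0
  }
  I_A <- I_A + emission$background_acceptor + emission$bleedthrough * I_D
  I_D <- I_D + emission$background_donor
  I_A[I_A < 0] <- 0
  I_D[I_D < 0] <- 0
  corr <- correct_intensities(I_D, I_A, correction_params_for(emission))
  fret <- compute_fret(corr$donor, corr$acceptor)
  fret_trace(donor = I_D, acceptor = I_A, dt = dt, fret = fret,
             truth_state = frames$state, trace_id = trace_id)
}

#' Simulate an ensemble of noisy FRET traces
#'
#' Draws independent continuous-time state paths from `model`, bins them into
#' camera frames, and emits noisy intensities. Per-trace seeds are derived
#' from the master seed by a counter scheme (`seed + 2*i` for the path,
#' `seed + 2*i + 1` for the emission noise of trace `i`), so an ensemble is
#' reproducible as a whole and per trace.
#'
#' @param model A [rate_model()].
#' @param emission An [emission_model()].
#' @param n_traces Number of molecules.
#' @param duration Observation window per molecule (s); 400 s by default.
#' @param dt Frame interval (s); 0.2 s (5 Hz) by default.
#' @param seed Master integer seed.
#' @param start Start state passed to [sample_state_path()].
#' @return Object of class `fret_ensemble`: a list of [fret_trace()] objects
#'   with attributes `model`, `emission`, `dt`, `seed`.
#' @export
simulate_ensemble <- function(model, emission = emission_model(),
                              n_traces, duration = 400, dt = 0.2,
                              seed = 1L, start = "stationary") {
  stopifnot(n_traces >= 1)
  seed <- as.integer(seed)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    path <- sample_state_path(model, duration, start = start,
                              seed = (seed + 2L * i) %% .Machine$integer.max)
    frames <- bin_to_frames(path, dt, model)
    traces[[i]] <- emit_intensities(
      frames, emission, dt,
      seed = (seed + 2L * i + 1L) %% .Machine$integer.max,
      trace_id = sprintf("trace_%03d", i))
  }
  structure(traces, model = model, emission = emission, dt = dt, seed = seed,
            class = "fret_ensemble")
}

#' @export
print.fret_ensemble <- function(x, ...) {
  cat(sprintf("FRET ensemble: %d traces, dt = %g s, master seed %d\n",
              length(x), attr(x, "dt"), attr(x, "seed")))
  invisible(x)
}
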