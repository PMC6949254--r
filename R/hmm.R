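#' Hidden Markov model specification with degenerate emission states
#'
#' Defines the kinetic network for HMM training: the number of hidden states,
#' the allowed transitions (adjacency), and the mapping from hidden states to
#' Gaussian emission components. Several hidden states may share one
#' component — a *degenerate* FRET state resolvable only through its exit
#' kinetics.
#'
#' @param n_states Number of hidden states.
#' @param adjacency Logical `n_states x n_states` matrix of allowed
#'   transitions (diagonal is always allowed). Default: fully connected.
#' @param emission_map Integer vector mapping each hidden state to an
#'   emission component index.
#' @param name Optional label used in model-selection tables.
#' @return Object of class `hmm_spec`.
#' @export
hmm_spec <- function(n_states, adjacency = NULL,
                     emission_map = seq_len(n_states), name = NULL) {
  if (is.null(adjacency))
    adjacency <- matrix(TRUE, n_states, n_states)
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == n_states, ncol(adjacency) == n_states,
            length(emission_map) == n_states)
  diag(adjacency) <- TRUE
  emission_map <- as.integer(emission_map)
  if (any(emission_map < 1))
    stop("emission_map must contain positive component indices")
  if (is.null(name))
    name <- sprintf("%d-state/%d-component", n_states,
                    length(unique(emission_map)))
  structure(list(n_states = n_states, adjacency = adjacency,
                 emission_map = emission_map,
                 n_components = max(emission_map), name = name),
            class = "hmm_spec")
}

#' Two-state binding network (zero and high FRET)
#' @return An [hmm_spec()] with two states and two emission components.
#' @export
spec_two_state <- function() {
  hmm_spec(2, emission_map = c(1L, 2L), name = "two-state")
}

#' Sequential three-state network with a twofold degenerate high-FRET state
#'
#' States 0 <-> 1 <-> 2 with the 0 <-> 2 link forbidden; states 1 and 2 share
#' the high-FRET emission component. State 1 is by construction the bound
#' state with a direct path to the unbound state.
#'
#' @return An [hmm_spec()].
#' @export
spec_three_state_degenerate <- function() {
  adj <- matrix(c(TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE,
                  FALSE, TRUE, TRUE), 3, byrow = TRUE)
  hmm_spec(3, adjacency = adj, emission_map = c(1L, 2L, 2L),
           name = "three-state degenerate")
}

trace_fret <- function(x) {
  if (inherits(x, "fret_trace")) x$fret else as.numeric(x)
}

make_B <- function(fret, spec, means, sds) {
  comp <- spec$emission_map
  B <- matrix(1, length(fret), spec$n_states)
  for (s in seq_len(spec$n_states))
    B[, s] <- stats::dnorm(fret, means[comp[s]], sds[comp[s]])
  B[!is.finite(fret), ] <- 1  # undefined frames carry no evidence
  B[B < 1e-300] <- 1e-300
  B
}

make_logB <- function(fret, spec, means, sds) log(make_B(fret, spec, means, sds))

# pair-emission densities for the camera-blur-aware likelihood: column
# (i-1)*N + j holds p(x_t | s_{t-1} = i, s_t = j). A frame spanning a jump
# between different FRET levels integrates part of each level; with the jump
# time uniform within the frame the observed value is distributed as
# N(lambda a + (1-lambda) b, sigma), lambda ~ U(0,1), i.e. a box convolved
# with the Gaussian noise.
make_B_pair <- function(fret, spec, means, sds) {
  n <- spec$n_states
  lev <- means[spec$emission_map]
  sd_s <- sds[spec$emission_map]
  Bd <- make_B(fret, spec, means, sds)
  Bp <- matrix(1, length(fret), n * n)
  ok <- is.finite(fret)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    col <- (i - 1) * n + j
    if (lev[i] == lev[j]) {
      Bp[, col] <- Bd[, j]
    } else {
      a <- min(lev[i], lev[j]); b <- max(lev[i], lev[j])
      s <- (sd_s[i] + sd_s[j]) / 2
      v <- (stats::pnorm((fret - a) / s) - stats::pnorm((fret - b) / s)) /
        (b - a)
      v[!ok] <- 1
      v[v < 1e-300] <- 1e-300
      Bp[, col] <- v
    }
  }
  Bp
}

safe_log <- function(x) {
  out <- rep(-Inf, length(x))
  pos <- x > 0
  out[pos] <- log(x[pos])
  out
}

#' Pooled emission components from per-trace mixture fits
#'
#' Fits a Gaussian mixture to every trace individually and pools the
#' component parameters by the median across traces. The result serves as the
#' predetermined, fixed emission model for the global HMM stage.
#'
#' @param traces A `fret_ensemble` or list of FRET vectors.
#' @param n_components Number of emission components.
#' @return List with `means` and `sds` (sorted by mean).
#' @export
emissions_from_traces <- function(traces, n_components = 2) {
  fits <- lapply(traces, function(tr) {
    x <- trace_fret(tr)
    x <- x[is.finite(x)]
    tryCatch(gmm_fit(x, n_components), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("no trace admitted a mixture fit")
  means <- apply(vapply(fits, `[[`, numeric(n_components), "means"), 1,
                 stats::median)
  sds <- apply(vapply(fits, `[[`, numeric(n_components), "sds"), 1,
               stats::median)
  list(means = means, sds = sds)
}

# dwell-based initial transition matrix: two-level discretization gives
# per-frame exit frequencies which are spread over the allowed links
init_transition <- function(fret_list, spec, means, sds, jitter = 0) {
  thr <- mean(range(means))
  q01 <- q10 <- 0.02
  hi_comp <- which.max(means)
  counts <- c(z2h = 0, h2z = 0, z = 0, h = 0)
  for (x in fret_list) {
    x <- x[is.finite(x)]
    if (length(x) < 2) next
    s <- x > thr
    counts["z2h"] <- counts["z2h"] + sum(!s[-length(s)] & s[-1])
    counts["h2z"] <- counts["h2z"] + sum(s[-length(s)] & !s[-1])
    counts["z"] <- counts["z"] + sum(!s[-length(s)])
    counts["h"] <- counts["h"] + sum(s[-length(s)])
  }
  if (counts["z"] > 0) q01 <- max(counts["z2h"] / counts["z"], 1e-4)
  if (counts["h"] > 0) q10 <- max(counts["h2z"] / counts["h"], 1e-4)
  n <- spec$n_states
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbr <- setdiff(which(spec$adjacency[i, ]), i)
    if (length(nbr) == 0) { A[i, i] <- 1; next }
    exit_i <- if (spec$emission_map[i] == hi_comp) q10 else q01
    for (j in nbr) {
      # exchange among same-component states starts at the exit scale too
      A[i, j] <- exit_i / length(nbr)
    }
    A[i, i] <- 1 - sum(A[i, -i])
  }
  if (jitter > 0) {
    off <- A
    diag(off) <- 0
    off <- off * exp(matrix(stats::rnorm(n * n, 0, jitter), n, n))
    off[!spec$adjacency] <- 0
    diag(off) <- 0
    off <- pmin(off, 0.5)
    A <- off
    diag(A) <- 1 - rowSums(off)
  }
  A
}

em_fit <- function(fret_list, spec, means, sds, A, start,
                   fix_emissions = TRUE, tol = 1e-6, max_iter = 500,
                   blur = FALSE) {
  n <- spec$n_states
  comp <- spec$emission_map
  make_dens <- if (blur) make_B_pair else make_B
  fb_fun <- if (blur) hmm_forward_backward_pair else hmm_forward_backward
  ll_fun <- if (blur) hmm_loglik_pair else hmm_loglik
  n_obs <- sum(vapply(fret_list, length, 0L))
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  # with fixed emissions the per-frame densities never change: cache them
  B_list <- if (fix_emissions)
    lapply(fret_list, make_dens, spec = spec, means = means, sds = sds)
  else NULL
  for (iter in seq_len(max_iter)) {
    ll <- 0
    xi_tot <- matrix(0, n, n)
    gamma1 <- rep(0, n)
    if (!fix_emissions) {
      wsum <- wx <- wx2 <- rep(0, spec$n_components)
      B_list <- lapply(fret_list, make_dens, spec = spec, means = means,
                       sds = sds)
    }
    for (k in seq_along(fret_list)) {
      x <- fret_list[[k]]
      fb <- fb_fun(B_list[[k]], A, start)
      ll <- ll + fb$loglik
      xi_tot <- xi_tot + fb$xi_sum
      gamma1 <- gamma1 + fb$gamma[1, ]
      if (!fix_emissions) {
        ok <- is.finite(x)
        g <- fb$gamma[ok, , drop = FALSE]
        xv <- x[ok]
        for (cc in seq_len(spec$n_components)) {
          gs <- rowSums(g[, comp == cc, drop = FALSE])
          wsum[cc] <- wsum[cc] + sum(gs)
          wx[cc] <- wx[cc] + sum(gs * xv)
          wx2[cc] <- wx2[cc] + sum(gs * xv^2)
        }
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (!is.finite(ll))
      stop("non-finite log-likelihood at EM iteration ", iter)
    # M-step
    denom <- rowSums(xi_tot)
    A_new <- A
    for (i in seq_len(n)) {
      if (denom[i] > 0) A_new[i, ] <- xi_tot[i, ] / denom[i]
    }
    A_new[!spec$adjacency] <- 0
    A_new <- A_new / rowSums(A_new)
    start_new <- gamma1 / sum(gamma1)
    if (!fix_emissions) {
      means <- wx / wsum
      sds <- sqrt(pmax(wx2 / wsum - means^2, 1e-6))
    }
    A <- A_new
    start <- start_new
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * n_obs && iter > 2) break
    ll_prev <- ll
  }
  # final likelihood under the last parameter update
  if (!fix_emissions)
    B_list <- lapply(fret_list, make_dens, spec = spec, means = means,
                     sds = sds)
  ll <- sum(vapply(B_list, function(B) ll_fun(B, A, start), numeric(1)))
  n_free <- sum(spec$adjacency) - n + (n - 1) +
    if (fix_emissions) 0 else 2 * spec$n_components
  structure(list(spec = spec, start = start, A = A, means = means, sds = sds,
                 loglik = ll, n_free_parameters = n_free, n_obs = n_obs,
                 n_iter = iter, converged = iter < max_iter,
                 ll_trace = ll_trace, emissions_fixed = fix_emissions,
                 blur = blur),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("HMM fit (%s): logL = %.2f over %d frames, %d free parameters\n",
              x$spec$name, x$loglik, x$n_obs, x$n_free_parameters))
  cat("Transition matrix (per frame):\n")
  print(signif(x$A, 4))
  cat("Emission components: means",
      paste(signif(x$means, 3), collapse = ", "), "| sds",
      paste(signif(x$sds, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Train an HMM on a single trace
#'
#' Baum-Welch expectation maximisation with Gaussian emissions. The
#' log-likelihood is non-decreasing across iterations; the best of
#' `n_restarts` jittered initialisations is returned. Emission parameters
#' are free unless `fixed_emissions` is supplied.
#'
#' @param trace A [fret_trace()] or numeric FRET vector (>= 10 frames).
#' @param spec An [hmm_spec()].
#' @param fixed_emissions Optional list with `means` and `sds` per component;
#'   when supplied the emission model is held fixed.
#' @param init Optional list with `A` and `start` to seed EM.
#' @param tol Convergence tolerance on the log-likelihood gain per frame.
#' @param max_iter Maximum EM iterations.
#' @param n_restarts Number of jittered initialisations.
#' @param seed Integer seed for the restarts.
#' @param blur Use the camera-blur-aware pair-emission likelihood: frames
#'   spanning a jump between FRET levels get the box-convolved density of a
#'   partially integrated level instead of a pure Gaussian. Defaults off for
#'   the exploratory per-trace stage and on for the global stage.
#' @return An object of class `hmm_params`.
#' @export
train_trace_hmm <- function(trace, spec, fixed_emissions = NULL, init = NULL,
                            tol = 1e-6, max_iter = 500, n_restarts = 3,
                            seed = 1L, blur = FALSE) {
  x <- trace_fret(trace)
  if (length(x) < 10) stop("trace must have at least 10 frames")
  train_hmm_list(list(x), spec, fixed_emissions, init, tol, max_iter,
                 n_restarts, seed, blur)
}

#' Train a global HMM on an ensemble of traces
#'
#' A single shared transition matrix and start vector are optimised against
#' the summed log-likelihood over all traces while the emission components
#' (predetermined, e.g. by [emissions_from_traces()]) are held fixed. This is
#' the estimator behind the reported rate constants: individual traces are
#' too short to constrain slow exchange rates, the ensemble is not.
#'
#' @param traces A `fret_ensemble` or list of FRET vectors (>= 2 traces).
#' @param spec An [hmm_spec()].
#' @param fixed_emissions List with `means` and `sds` per emission component
#'   (required: the global stage never refits emissions).
#' @inheritParams train_trace_hmm
#' @return An object of class `hmm_params`.
#' @export
train_global_hmm <- function(traces, spec, fixed_emissions, init = NULL,
                             tol = 1e-6, max_iter = 500, n_restarts = 3,
                             seed = 1L, blur = TRUE) {
  fret_list <- lapply(traces, trace_fret)
  if (length(fret_list) < 2) stop("global HMM needs at least 2 traces")
  if (is.null(fixed_emissions))
    stop("fixed_emissions is required for the global stage")
  train_hmm_list(fret_list, spec, fixed_emissions, init, tol, max_iter,
                 n_restarts, seed, blur)
}

train_hmm_list <- function(fret_list, spec, fixed_emissions, init, tol,
                           max_iter, n_restarts, seed, blur = FALSE) {
  fix <- !is.null(fixed_emissions)
  if (fix) {
    means <- fixed_emissions$means
    sds <- fixed_emissions$sds
    if (length(means) < spec$n_components)
      stop("fixed_emissions must cover every emission component")
  } else {
    pooled <- unlist(fret_list)
    pooled <- pooled[is.finite(pooled)]
    qs <- stats::quantile(pooled, probs = seq(0.1, 0.9,
                                              length.out = spec$n_components))
    means <- as.numeric(qs)
    sds <- rep(max(stats::sd(pooled) / 2, 0.02), spec$n_components)
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    A0 <- if (!is.null(init) && r == 1) init$A else
      init_transition(fret_list, spec, means, sds,
                      jitter = if (r == 1) 0 else 0.5)
    start0 <- if (!is.null(init) && r == 1 && !is.null(init$start))
      init$start else rep(1 / spec$n_states, spec$n_states)
    fit <- tryCatch(
      em_fit(fret_list, spec, means, sds, A0, start0,
             fix_emissions = fix, tol = tol, max_iter = max_iter,
             blur = blur),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("EM failed to converge from every initialisation")
  best
}

#' Most likely hidden state sequence (Viterbi decoding)
#'
#' @param trace A [fret_trace()] or numeric FRET vector.
#' @param params Trained `hmm_params`.
#' @return List with `path` (1-based hidden state index per frame; ties are
#'   broken toward the lower state index) and `logprob` (joint log
#'   probability of the decoded path).
#' @export
viterbi_path <- function(trace, params) {
  x <- trace_fret(trace)
  logB <- make_logB(x, params$spec, params$means, params$sds)
  logA <- safe_log(params$A); dim(logA) <- dim(params$A)
  v <- hmm_viterbi(logB, logA, safe_log(params$start))
  list(path = v$path + 1L, logprob = v$logprob)
}

#' Bayesian information criterion
#'
#' \eqn{BIC = -2 \log L + p \ln(n)} with `p` free parameters and `n` total
#' observed frames. Lower is better.
#'
#' @param logL Maximised log-likelihood.
#' @param n_free_parameters Number of free parameters.
#' @param n_observations Total frames across traces.
#' @return Numeric BIC value.
#' @export
compute_bic <- function(logL, n_free_parameters, n_observations) {
  -2 * logL + n_free_parameters * log(n_observations)
}

#' Rank candidate kinetic networks by BIC
#'
#' Trains every candidate [hmm_spec()] globally on the same ensemble and
#' ranks them by BIC. Candidates that fail to converge are kept in the table
#' with `converged = FALSE` rather than silently dropped.
#'
#' @param traces A `fret_ensemble` or list of FRET vectors.
#' @param specs List of [hmm_spec()] candidates (>= 1).
#' @param fixed_emissions Emission components shared across candidates.
#' @param ... Passed to [train_global_hmm()].
#' @return Data frame sorted by BIC: `name`, `n_states`, `logL`, `n_free`,
#'   `bic`, `delta_bic`, `converged`; fitted models in attribute `fits`.
#' @export
select_model <- function(traces, specs, fixed_emissions, ...) {
  stopifnot(length(specs) >= 1)
  fits <- lapply(specs, function(sp) {
    tryCatch(train_global_hmm(traces, sp, fixed_emissions, ...),
             error = function(e) structure(list(error = conditionMessage(e),
                                                spec = sp),
                                           class = "hmm_failure"))
  })
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "hmm_failure"))
      data.frame(name = f$spec$name, n_states = f$spec$n_states,
                 logL = NA_real_, n_free = NA_integer_, bic = NA_real_,
                 converged = FALSE)
    else
      data.frame(name = f$spec$name, n_states = f$spec$n_states,
                 logL = f$loglik, n_free = f$n_free_parameters,
                 bic = compute_bic(f$loglik, f$n_free_parameters, f$n_obs),
                 converged = f$converged)
  }))
  ord <- order(tab$bic)
  tab <- tab[ord, ]
  tab$delta_bic <- tab$bic - tab$bic[1]
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Convert per-frame transition probabilities to rate coefficients
#'
#' Default (`method = "linear"`): \eqn{k_{ij} = A_{ij}/dt}, the first-order
#' approximation valid when transition probabilities per frame are small; a
#' warning is issued when any off-diagonal \eqn{A_{ij} > 0.1}. The
#' `"logm"` method uses the matrix logarithm \eqn{K = \log(A)/dt} instead and
#' errors when `A` is not embeddable in a continuous-time chain (complex or
#' negative off-diagonal generator entries), suggesting the linear
#' approximation.
#'
#' @param A Stochastic per-frame transition matrix.
#' @param dt Frame interval (s).
#' @param method `"linear"` or `"logm"`.
#' @return Rate matrix (\eqn{s^{-1}}) with diagonal = minus row sums.
#' @export
transition_to_rates <- function(A, dt, method = c("linear", "logm")) {
  method <- match.arg(method)
  A <- as.matrix(A)
  stopifnot(dt > 0, nrow(A) == ncol(A))
  if (max(abs(rowSums(A) - 1)) > 1e-6) stop("A must be row-stochastic")
  off <- A; diag(off) <- 0
  if (method == "linear") {
    if (any(off > 0.1))
      warning("off-diagonal transition probability > 0.1; ",
              "the linear rate approximation k = A/dt is biased ",
              "(consider method = 'logm')")
    K <- off / dt
    diag(K) <- -rowSums(K)
    return(K)
  }
  ev <- eigen(A)
  if (any(abs(Im(ev$values)) > 1e-10) || any(Re(ev$values) <= 0))
    stop("A is not embeddable (complex or non-positive eigenvalues); ",
         "use method = 'linear'")
  L <- ev$vectors %*% diag(log(ev$values), nrow(A)) %*% solve(ev$vectors)
  K <- Re(L) / dt
  offK <- K; diag(offK) <- 0
  # a transition matrix estimated with structural zeros (forbidden links) is
  # not exactly embeddable: its logarithm carries small negative fill-ins on
  # the forbidden entries, which are projected to zero; large violations
  # indicate a genuinely non-embeddable matrix
  if (any(offK < -0.02 * max(offK)))
    stop("matrix logarithm yields substantially negative off-diagonal ",
         "rates; A is not embeddable, use method = 'linear'")
  offK[offK < 0] <- 0
  diag(offK) <- 0
  K <- offK
  diag(K) <- -rowSums(K)
  K
}

stationary_of_A <- function(A) {
  n <- nrow(A)
  M <- rbind(t(A) - diag(n), rep(1, n))
  pi <- as.numeric(qr.solve(M, c(rep(0, n), 1)))
  pi[pi < 0 & pi > -1e-10] <- 0
  pi / sum(pi)
}

#' State populations and population-based dissociation constant
#'
#' Populations come either from the stationary distribution of the fitted
#' transition matrix (default) or from counting Viterbi-decoded frames. The
#' bound population aggregates all states sharing the high-FRET emission
#' component (degenerate states), and
#' \eqn{K_d = S_{unbound} \cdot c / S_{bound}} with ligand concentration `c`.
#'
#' @param params Trained `hmm_params`.
#' @param ligand_conc Ligand concentration (the returned `kd` has the same
#'   unit, typically nM).
#' @param method `"stationary"` or `"viterbi"`.
#' @param traces Required for `method = "viterbi"`.
#' @return List with `populations` (per hidden state), `bound`, `unbound`,
#'   `kd` (`NA` when the bound population is zero).
#' @export
state_population_kd <- function(params, ligand_conc,
                                method = c("stationary", "viterbi"),
                                traces = NULL) {
  method <- match.arg(method)
  n <- params$spec$n_states
  if (method == "stationary") {
    pops <- stationary_of_A(params$A)
  } else {
    if (is.null(traces)) stop("traces required for method = 'viterbi'")
    counts <- rep(0, n)
    for (tr in traces) {
      p <- viterbi_path(tr, params)$path
      counts <- counts + tabulate(p, nbins = n)
    }
    pops <- counts / sum(counts)
  }
  hi <- which.max(params$means)
  bound_states <- which(params$spec$emission_map == hi)
  S_bound <- sum(pops[bound_states])
  S_unbound <- 1 - S_bound
  kd <- if (S_bound > 0) S_unbound * ligand_conc / S_bound else NA_real_
  list(populations = pops, bound = S_bound, unbound = S_unbound, kd = kd)
}

# constrained EM: A[from, to] clamped at `a`, other entries of that row
# renormalised from expected counts; everything else re-optimised
profile_loglik <- function(fret_list, params, from, to, a,
                           tol = 1e-6, max_iter = 200) {
  spec <- params$spec
  n <- spec$n_states
  A <- params$A
  A[from, to] <- a
  rest <- setdiff(which(spec$adjacency[from, ]), to)
  w <- params$A[from, rest]
  if (sum(w) <= 0) w <- rep(1, length(rest))
  A[from, rest] <- (1 - a) * w / sum(w)
  start <- params$start
  means <- params$means; sds <- params$sds
  n_obs <- sum(vapply(fret_list, length, 0L))
  blur <- isTRUE(params$blur)
  make_dens <- if (blur) make_B_pair else make_B
  fb_fun <- if (blur) hmm_forward_backward_pair else hmm_forward_backward
  B_list <- lapply(fret_list, make_dens, spec = spec, means = means,
                   sds = sds)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    ll <- 0
    xi_tot <- matrix(0, n, n)
    gamma1 <- rep(0, n)
    for (B in B_list) {
      fb <- fb_fun(B, A, start)
      ll <- ll + fb$loglik
      xi_tot <- xi_tot + fb$xi_sum
      gamma1 <- gamma1 + fb$gamma[1, ]
    }
    A_new <- A
    for (i in seq_len(n)) {
      if (i == from) next
      if (sum(xi_tot[i, ]) > 0) A_new[i, ] <- xi_tot[i, ] / sum(xi_tot[i, ])
    }
    # constrained row: share the remaining mass by expected counts
    cnt <- xi_tot[from, rest]
    if (sum(cnt) > 0) A_new[from, rest] <- (1 - a) * cnt / sum(cnt)
    A_new[from, to] <- a
    A_new[!spec$adjacency] <- 0
    A_new <- A_new / rowSums(A_new)
    A_new[from, to] <- a  # renormalisation must not move the clamp
    A_new[from, rest] <- A_new[from, rest] *
      (1 - a - sum(A_new[from, setdiff(seq_len(n), c(rest, to))])) /
      max(sum(A_new[from, rest]), 1e-300)
    start <- gamma1 / sum(gamma1)
    A <- A_new
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * n_obs && iter > 2) break
    ll_prev <- ll
  }
  ll
}

#' Likelihood-ratio confidence bounds on a transition parameter
#'
#' Profiles one entry of the transition matrix: the entry is clamped on a
#' grid of values, all remaining parameters are re-optimised, and the bound
#' is placed where twice the log-likelihood drop crosses the \eqn{\chi^2(1)}
#' quantile of the requested confidence level (default 68.27%, i.e. 1 sigma).
#' Bounds are asymmetric by construction. If the profile does not cross
#' within the admissible range the interval is one-sided and flagged.
#'
#' @param traces A `fret_ensemble` or list of FRET vectors.
#' @param params Converged global `hmm_params`.
#' @param from,to 1-based indices of the profiled transition entry.
#' @param confidence Confidence level in (0, 1); default `0.6827`.
#' @param dt Optional frame interval to also report the bounds as rates.
#' @return List with `estimate` (per-frame probability), `lower`, `upper`,
#'   `one_sided` flag, and the same three values converted to rates via
#'   `rate = prob/dt` when `dt` is supplied.
#' @export
likelihood_ratio_errors <- function(traces, params, from, to,
                                    confidence = 0.6827, dt = NULL) {
  fret_list <- lapply(traces, trace_fret)
  a_hat <- params$A[from, to]
  if (a_hat <= 0) stop("profiled entry has zero estimate (forbidden link?)")
  ll_hat <- params$loglik
  crit <- stats::qchisq(confidence, df = 1)
  if (crit == 0)
    return(list(estimate = a_hat, lower = a_hat, upper = a_hat,
                one_sided = FALSE))
  dev <- function(a)
    2 * (ll_hat - profile_loglik(fret_list, params, from, to, a)) - crit
  find_bound <- function(side) {
    lim <- if (side < 0) a_hat * 0.05 else min(a_hat * 20, 0.999)
    f_lim <- tryCatch(dev(lim), error = function(e) NA_real_)
    if (!is.finite(f_lim) || f_lim < 0) return(NA_real_)  # no crossing
    r <- stats::uniroot(dev, sort(c(a_hat * (1 + side * 1e-4), lim)),
                        tol = a_hat * 1e-4)
    r$root
  }
  lower <- find_bound(-1)
  upper <- find_bound(+1)
  out <- list(estimate = a_hat, lower = lower, upper = upper,
              one_sided = is.na(lower) || is.na(upper))
  if (!is.null(dt)) {
    out$rate <- a_hat / dt
    out$rate_lower <- lower / dt
    out$rate_upper <- upper / dt
  }
  out
}
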