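# shared fixtures built in code

# hand-rolled state_path for binning tests
make_path <- function(times, states, duration) {
  structure(list(times = times, states = states, duration = duration),
            class = "state_path")
}

# brute-force HMM log-likelihood by full path enumeration (tiny traces only)
brute_force_loglik <- function(x, A, start, means, sds, emission_map) {
  n <- length(start)
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    pr <- start[p[1]] * stats::dnorm(x[1], means[emission_map[p[1]]],
                                     sds[emission_map[p[1]]])
    if (T_ > 1) for (t in 2:T_) {
      pr <- pr * A[p[t - 1], p[t]] *
        stats::dnorm(x[t], means[emission_map[p[t]]], sds[emission_map[p[t]]])
    }
    total <- total + pr
  }
  log(total)
}

# brute-force best path score by enumeration
brute_force_viterbi <- function(x, A, start, means, sds, emission_map) {
  n <- length(start)
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(start[p[1]]) + stats::dnorm(x[1], means[emission_map[p[1]]],
                                          sds[emission_map[p[1]]], log = TRUE)
    if (T_ > 1) for (t in 2:T_) {
      a <- A[p[t - 1], p[t]]
      if (a == 0) { lp <- -Inf; break }
      lp <- lp + log(a) + stats::dnorm(x[t], means[emission_map[p[t]]],
                                       sds[emission_map[p[t]]], log = TRUE)
    }
    if (lp > best) best <- lp
  }
  best
}

# minimal hmm_params-like object for decoding/population helpers
fake_params <- function(A, means, sds, spec, start = NULL) {
  if (is.null(start)) start <- rep(1 / nrow(A), nrow(A))
  structure(list(spec = spec, start = start, A = A, means = means, sds = sds,
                 loglik = NA_real_, n_free_parameters = NA_integer_,
                 n_obs = NA_integer_),
            class = "hmm_params")
}

# write sugar rings as a (possibly multi-MODEL) PDB file
write_ring_pdb <- function(rings_by_model, path, extra_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(rings_by_model) > 1
  for (m in seq_along(rings_by_model)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0
    for (k in seq_along(rings_by_model[[m]])) {
      ring <- rings_by_model[[m]]
      ring <- ring[[k]]
      resname <- if (isTRUE(ring$deoxy)) "DT" else "U"
      for (a in seq_len(5)) {
        serial <- serial + 1
        nm <- rownames(ring$coords)[a]
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, nm, resname, k,
          ring$coords[a, 1], ring$coords[a, 2], ring$coords[a, 3]), con)
      }
      if (!isTRUE(ring$deoxy)) {  # 2'-OH marks the ribose
        serial <- serial + 1
        o2 <- ring$coords["C2'", ] + c(0.8, 0.8, 0.8)
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, "O2'", resname, k, o2[1], o2[2], o2[3]), con)
      }
    }
    for (ln in extra_lines) { writeLines(ln, con) }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
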