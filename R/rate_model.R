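#' Continuous-time rate model for single-molecule kinetics
#'
#' A `rate_model` bundles the generator matrix \eqn{K} of a continuous-time
#' Markov chain with the FRET emission level of each kinetic state. States
#' sharing one emission level form a *degenerate group*: they are
#' indistinguishable by FRET efficiency and can only be resolved kinetically.
#'
#' Conventions: the off-diagonal entry \eqn{k_{ij} \ge 0} (in \eqn{s^{-1}}) is
#' the first-order rate coefficient for the transition from state \eqn{i} to
#' state \eqn{j}; each diagonal entry is minus the corresponding row sum, so
#' every row of \eqn{K} sums to zero.
#'
#' @param K Square numeric matrix of first-order rate coefficients
#'   (\eqn{s^{-1}}). Off-diagonal entries must be non-negative; the diagonal is
#'   recomputed as minus the off-diagonal row sums (and checked against any
#'   supplied diagonal).
#' @param emission_level Numeric vector, mean FRET efficiency of each state.
#' @param state_labels Character vector of state names. Defaults to
#'   `"0", "1", ...` following the usual numbering of kinetic schemes.
#' @param degenerate_groups Optional list of integer vectors partitioning the
#'   states into groups sharing one emission level. Defaults to grouping
#'   states by equal `emission_level`.
#'
#' @return An object of class `rate_model` with elements `K`,
#'   `emission_level`, `state_labels`, `degenerate_groups`.
#' @examples
#' m <- two_state_model(k_on = 0.0296, k_off = 0.051)
#' stationary_distribution(m)
#' @export
rate_model <- function(K, emission_level, state_labels = NULL,
                       degenerate_groups = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K must be square")
  if (length(emission_level) != n)
    stop("emission_level must have one entry per state")
  off <- K
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal entries of K must be >= 0")
  diag_target <- -rowSums(off)
  supplied <- diag(K)
  if (any(supplied != 0) &&
      max(abs(supplied - diag_target)) > 1e-9 * max(1, max(abs(K))))
    stop("diagonal of K must equal minus the off-diagonal row sum ",
         "(rows of a generator sum to 0)")
  diag(K) <- diag_target
  if (is.null(state_labels)) state_labels <- as.character(seq_len(n) - 1L)
  if (length(state_labels) != n) stop("state_labels length mismatch")
  if (is.null(degenerate_groups)) {
    degenerate_groups <- split(seq_len(n), match(emission_level, unique(emission_level)))
    names(degenerate_groups) <- NULL
  }
  idx <- sort(unlist(degenerate_groups))
  if (!identical(idx, seq_len(n)))
    stop("degenerate_groups must partition the states")
  for (g in degenerate_groups) {
    if (length(unique(emission_level[g])) != 1L)
      stop("states in a degenerate group must share one emission level")
  }
  structure(
    list(K = K, emission_level = as.numeric(emission_level),
         state_labels = state_labels, degenerate_groups = degenerate_groups),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Rate model with", nrow(x$K), "states:",
      paste(x$state_labels, collapse = ", "), "\n")
  K <- x$K
  dimnames(K) <- list(x$state_labels, x$state_labels)
  print(signif(K, 4))
  cat("Emission levels:",
      paste(sprintf("%s=%.2f", x$state_labels, x$emission_level),
            collapse = ", "), "\n")
  invisible(x)
}

#' Two-state binding model
#'
#' Unbound (zero FRET) and bound (high FRET) states connected by a
#' pseudo-first-order association rate and a dissociation rate.
#'
#' @param k_on Pseudo-first-order association rate (\eqn{s^{-1}}).
#' @param k_off Dissociation rate (\eqn{s^{-1}}).
#' @param levels FRET emission levels of the unbound and bound state.
#' @return A [rate_model()].
#' @export
two_state_model <- function(k_on, k_off, levels = c(0, 0.75)) {
  rate_model(matrix(c(-k_on, k_on, k_off, -k_off), 2, byrow = TRUE),
             emission_level = levels, state_labels = c("0", "1"))
}

#' Sequential three-state model with a degenerate bound state
#'
#' The kinetic scheme 0 <-> 1 <-> 2 (no direct 0 <-> 2 link) in which states 1
#' and 2 share the high-FRET emission level: state 0 is the unbound hairpin,
#' state 1 the exon-bound contact, and state 2 the exon-bound contact with a
#' site-specifically coordinated Mg2+ ion. States 1 and 2 are degenerate in
#' FRET and distinguishable only through their exit kinetics.
#'
#' The generator is
#' \deqn{K = \begin{pmatrix} -k_{01} & k_{01} & 0 \\
#'  k_{10} & -(k_{10}+k_{12}) & k_{12} \\ 0 & k_{21} & -k_{21} \end{pmatrix}}
#' Note the (3,2) entry: a conserving generator for this scheme requires the
#' reverse rate \eqn{k_{21}} there (some printed forms of this matrix repeat
#' \eqn{k_{12}} in the third row, which would not conserve probability when
#' \eqn{k_{12} \neq k_{21}}).
#'
#' @param k_on Pseudo-first-order association rate 0 -> 1 (\eqn{s^{-1}}).
#' @param k_off Dissociation rate 1 -> 0 (\eqn{s^{-1}}).
#' @param k12 Forward exchange rate 1 -> 2 (\eqn{s^{-1}}), e.g. Mg2+ coordination.
#' @param k21 Reverse exchange rate 2 -> 1 (\eqn{s^{-1}}).
#' @param levels FRET emission levels: unbound and (shared) bound level.
#' @return A [rate_model()] with degenerate states 1 and 2.
#' @export
three_state_model <- function(k_on, k_off, k12, k21, levels = c(0, 0.75)) {
  K <- matrix(c(
    -k_on,  k_on,            0,
    k_off, -(k_off + k12), k12,
    0,      k21,           -k21), 3, byrow = TRUE)
  rate_model(K, emission_level = c(levels[1], levels[2], levels[2]),
             state_labels = c("0", "1", "2"),
             degenerate_groups = list(1L, c(2L, 3L)))
}

#' Literature rate models for the EBS1*/(d)IBS1* tertiary contact
#'
#' Hidden-Markov-model rate constants reported for the binding of the RNA
#' (IBS1*) or DNA (dIBS1*) exon mimic to the surface-immobilised EBS1* hairpin
#' under high monovalent salt (1 M K+, EDTA) or 20 mM Mg2+. In K+ alone the
#' kinetics are two-state; with Mg2+ a sequential three-state scheme with a
#' twofold degenerate high-FRET state describes the data. Ligand
#' concentrations were 35 nM (IBS1*) and 50 nM (dIBS1*).
#'
#' @return Named list of four entries, each a list with elements `model`
#'   (a [rate_model()]), `ligand_conc_nM`, and `rates` (the generating rate
#'   coefficients in \eqn{s^{-1}}).
#' @export
ebs1_rate_models <- function() {
  list(
    ibs1_K = list(
      model = two_state_model(k_on = 2.96e-2, k_off = 0.051),
      ligand_conc_nM = 35,
      rates = c(k_on = 2.96e-2, k_off = 0.051)),
    ibs1_mg = list(
      model = three_state_model(k_on = 2.14e-2, k_off = 0.146,
                                k12 = 33.1e-2, k21 = 2.56e-2),
      ligand_conc_nM = 35,
      rates = c(k_on = 2.14e-2, k_off = 0.146, k12 = 33.1e-2, k21 = 2.56e-2)),
    dibs1_K = list(
      model = two_state_model(k_on = 0.86e-2, k_off = 3.52),
      ligand_conc_nM = 50,
      rates = c(k_on = 0.86e-2, k_off = 3.52)),
    dibs1_mg = list(
      model = three_state_model(k_on = 7.07e-2, k_off = 0.511,
                                k12 = 2.35e-2, k21 = 6.33e-2),
      ligand_conc_nM = 50,
      rates = c(k_on = 7.07e-2, k_off = 0.511, k12 = 2.35e-2, k21 = 6.33e-2))
  )
}

# closed communicating classes of the jump chain; used for error reporting
closed_classes <- function(K) {
  n <- nrow(K)
  adj <- K > 0
  diag(adj) <- TRUE
  # reachability by repeated squaring (n is tiny)
  reach <- adj
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1L))
    reach <- (reach %*% reach) > 0
  classes <- list()
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    cls <- which(reach[i, ] & reach[, i])
    assigned[cls] <- TRUE
    # closed iff nothing outside the class is reachable from it
    outside <- setdiff(which(reach[i, ]), cls)
    if (length(outside) == 0) classes[[length(classes) + 1L]] <- cls
  }
  classes
}

#' Stationary distribution of a rate model
#'
#' Solves \eqn{\pi K = 0}, \eqn{\sum_i \pi_i = 1} by linear algebra. The chain
#' must have a single closed communicating class, otherwise the stationary
#' distribution is not unique and an error names the closed classes.
#'
#' @param model A [rate_model()].
#' @return Numeric probability vector named by state label.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  K <- model$K
  n <- nrow(K)
  cls <- closed_classes(K)
  if (length(cls) != 1L) {
    desc <- vapply(cls, function(g)
      paste0("{", paste(model$state_labels[g], collapse = ","), "}"), "")
    stop("chain is reducible with multiple closed classes: ",
         paste(desc, collapse = ", "),
         "; the stationary distribution is not unique")
  }
  sub <- cls[[1]]
  Ks <- K[sub, sub, drop = FALSE]
  diag(Ks) <- 0
  diag(Ks) <- -rowSums(Ks)
  m <- length(sub)
  A <- rbind(t(Ks), rep(1, m))
  b <- c(rep(0, m), 1)
  pis <- as.numeric(qr.solve(A, b))
  pi <- rep(0, n)
  pi[sub] <- pis
  pi[pi < 0 & pi > -1e-12] <- 0
  names(pi) <- model$state_labels
  pi
}
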