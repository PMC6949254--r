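PUCKER_MODES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                  "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")
RING_ATOMS <- c("O4'", "C1'", "C2'", "C3'", "C4'")

#' Five-membered sugar ring
#'
#' @param coords 5 x 3 numeric matrix of ring-atom coordinates (Angstrom) in
#'   the order O4', C1', C2', C3', C4'.
#' @param resid Residue identifier.
#' @param chain Chain identifier.
#' @param deoxy `TRUE` for deoxyribose (no 2'-OH).
#' @return Object of class `sugar_ring`.
#' @export
sugar_ring <- function(coords, resid = NA, chain = NA, deoxy = FALSE) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 5, ncol(coords) == 3)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] < 1e-6))
    stop("coincident ring atoms")
  rownames(coords) <- RING_ATOMS
  structure(list(coords = coords, resid = resid, chain = chain,
                 deoxy = deoxy),
            class = "sugar_ring")
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("collinear atom triple; dihedral undefined")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

#' Endocyclic torsion angles of a sugar ring
#'
#' The five ring dihedrals in degrees, standard numbering:
#' \eqn{\nu_0}: C4'-O4'-C1'-C2', \eqn{\nu_1}: O4'-C1'-C2'-C3',
#' \eqn{\nu_2}: C1'-C2'-C3'-C4', \eqn{\nu_3}: C2'-C3'-C4'-O4',
#' \eqn{\nu_4}: C3'-C4'-O4'-C1'.
#'
#' @param ring A [sugar_ring()].
#' @return Named numeric vector `nu0`..`nu4` in (-180, 180].
#' @export
ring_torsions <- function(ring) {
  stopifnot(inherits(ring, "sugar_ring"))
  xyz <- ring$coords
  # atom rows: 1 O4', 2 C1', 3 C2', 4 C3', 5 C4'
  idx <- list(nu0 = c(5, 1, 2, 3), nu1 = c(1, 2, 3, 4),
              nu2 = c(2, 3, 4, 5), nu3 = c(3, 4, 5, 1),
              nu4 = c(4, 5, 1, 2))
  vapply(idx, function(i)
    dihedral_angle(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ], xyz[i[4], ]),
    numeric(1))
}

#' Pseudorotation phase and amplitude of a sugar ring
#'
#' Two definitions are computed and returned together:
#' \itemize{
#'   \item Torsion-based (Altona-Sundaralingam):
#'     \eqn{\tan P = (\nu_4 + \nu_1 - \nu_3 - \nu_0) /
#'       (2\nu_2(\sin 36^\circ + \sin 72^\circ))}, amplitude
#'     \eqn{\nu_{max} = \nu_2 / \cos P} (degrees).
#'   \item Cartesian (Cremer-Pople-style): phase and puckering amplitude `q`
#'     (Angstrom) from the out-of-mean-plane displacements of the five ring
#'     atoms, reported on the same phase scale (C3'-endo near 18 degrees).
#' }
#' The two phases agree within a couple of degrees for physically plausible
#' rings. A ring with amplitude below `tol_deg` is essentially planar and its
#' phase is undefined (`NA`).
#'
#' @param ring A [sugar_ring()], or a numeric vector of five torsions
#'   `nu0`..`nu4` (degrees).
#' @param tol_deg Amplitude below which the phase is reported as undefined.
#' @return Object of class `pucker_state`: list with `phase` (degrees in
#'   `[0, 360)`), `amplitude` (degrees), `phase_cart`, `amplitude_cart_A`
#'   (`NA` when computed from torsions only), `mode` (one of ten labels, or
#'   `NA`), `resid`, `deoxy`.
#' @export
pseudorotation <- function(ring, tol_deg = 1) {
  if (inherits(ring, "sugar_ring")) {
    nu <- ring_torsions(ring)
    cart <- cartesian_pucker(ring$coords)
    resid <- ring$resid; deoxy <- ring$deoxy
  } else {
    nu <- as.numeric(ring)
    stopifnot(length(nu) == 5)
    names(nu) <- paste0("nu", 0:4)
    cart <- list(phase = NA_real_, q = NA_real_)
    resid <- NA; deoxy <- NA
  }
  num <- nu[["nu4"]] + nu[["nu1"]] - nu[["nu3"]] - nu[["nu0"]]
  den <- 2 * nu[["nu2"]] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  P <- atan2(num, den) * 180 / pi
  amp <- nu[["nu2"]] / cos(P * pi / 180)
  if (amp < 0) { # numerical guard; amplitude is non-negative by definition
    amp <- abs(amp)
    P <- P + 180
  }
  P <- P %% 360
  if (amp < tol_deg) {
    P <- NA_real_
    mode <- NA_character_
  } else {
    mode <- classify_pucker(P)
  }
  structure(list(phase = P, amplitude = amp,
                 phase_cart = cart$phase, amplitude_cart_A = cart$q,
                 mode = mode, resid = resid, deoxy = deoxy),
            class = "pucker_state")
}

# Cremer-Pople-style phase from out-of-plane displacements, shifted onto the
# torsion-phase scale (offset fixed by the atom numbering convention)
cartesian_pucker <- function(coords) {
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  j <- 0:4
  Rc <- colSums(X * cos(2 * pi * j / 5))
  Rs <- colSums(X * sin(2 * pi * j / 5))
  nrm <- c(Rc[2] * Rs[3] - Rc[3] * Rs[2],
           Rc[3] * Rs[1] - Rc[1] * Rs[3],
           Rc[1] * Rs[2] - Rc[2] * Rs[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  z <- as.numeric(X %*% nrm)
  qc <- sqrt(2 / 5) * sum(z * cos(4 * pi * j / 5))
  qs <- -sqrt(2 / 5) * sum(z * sin(4 * pi * j / 5))
  q <- sqrt(qc^2 + qs^2)
  phi <- atan2(qs, qc) * 180 / pi
  # relation between the CP phase (this atom order) and the AS torsion phase
  phase <- (phi + 90) %% 360
  list(phase = phase, q = q)
}

#' Classify a pseudorotation phase into one of ten puckering modes
#'
#' 36-degree bins centred at 18 + n*36 degrees so that the canonical
#' C3'-endo (P = 18) and C2'-endo (P = 162) phases are bin centres:
#' C3'-endo `[0,36)`, C4'-exo `[36,72)`, O4'-endo `[72,108)`, C1'-exo
#' `[108,144)`, C2'-endo `[144,180)`, C3'-exo `[180,216)`, C4'-endo
#' `[216,252)`, O4'-exo `[252,288)`, C1'-endo `[288,324)`, C2'-exo
#' `[324,360)`. The bin offset is configurable.
#'
#' @param P Phase(s) in degrees (vectorised); `NA` yields `NA`.
#' @param offset Rotation of the bin edges (degrees, default 0).
#' @return Character vector of mode labels.
#' @export
classify_pucker <- function(P, offset = 0) {
  idx <- floor(((P - offset) %% 360) / 36) + 1
  PUCKER_MODES[idx]
}

#' Circular histogram and median of pucker phases
#'
#' @param P Phases in degrees (NA dropped).
#' @param n_bins Number of uniform circular bins (default 10, matching the
#'   ten puckering modes).
#' @return List with `counts` (named by bin centre), `breaks`, and `median`
#'   (the circular median: the observed phase minimising the summed arc
#'   distance to all others).
#' @export
pucker_histogram <- function(P, n_bins = 10) {
  P <- P[is.finite(P)] %% 360
  if (length(P) == 0) stop("no defined phase")
  breaks <- seq(0, 360, length.out = n_bins + 1)
  counts <- table(cut(P, breaks, include.lowest = TRUE, right = FALSE))
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  names(counts) <- sprintf("%g", centres)
  arc <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  tot <- vapply(P, function(p) sum(arc(p, P)), numeric(1))
  list(counts = as.integer(counts), breaks = breaks,
       centres = centres, median = P[which.min(tot)])
}

#' Repuckering correlation time and north/south exchange rates
#'
#' Reduces a pucker-phase trajectory to a two-state north/south indicator
#' (north: P in `[270, 360) U [0, 90)`; south: `[90, 270)`), reports the mean
#' dwell time on each side with the implied exchange rates, and the
#' correlation time obtained from a single-exponential fit to the
#' autocorrelation of the indicator. For a two-state telegraph process the
#' autocorrelation decays as \eqn{\exp(-(k_{NS}+k_{SN}) t)}, so the fitted
#' decay time equals \eqn{1/(k_{NS}+k_{SN})}.
#'
#' @param P Phase trajectory in degrees (>= 100 frames).
#' @param dt_ps Time step between frames (ps).
#' @param split Two angles delimiting the north sector (default
#'   `c(270, 90)`).
#' @return List with `tau_ps` (correlation time), `mean_dwell_N_ps`,
#'   `mean_dwell_S_ps`, `k_NS_per_ps`, `k_SN_per_ps`, `n_transitions`. With
#'   no transition the rates are reported as upper bounds
#'   (`1/total time`) and `tau_ps` is `NA`.
#' @export
repucker_correlation_time <- function(P, dt_ps = 1, split = c(270, 90)) {
  stopifnot(length(P) >= 100, dt_ps > 0)
  Pm <- P %% 360
  north <- Pm >= split[1] | Pm < split[2]
  s <- ifelse(north, "N", "S")
  r <- rle(s)
  n_trans <- length(r$lengths) - 1L
  total <- length(P) * dt_ps
  if (n_trans == 0) {
    side <- r$values[1]
    out <- list(tau_ps = NA_real_,
                mean_dwell_N_ps = if (side == "N") total else NA_real_,
                mean_dwell_S_ps = if (side == "S") total else NA_real_,
                k_NS_per_ps = if (side == "N") 1 / total else NA_real_,
                k_SN_per_ps = if (side == "S") 1 / total else NA_real_,
                n_transitions = 0L, one_sided = TRUE)
    return(out)
  }
  dwell <- function(side) mean(r$lengths[r$values == side]) * dt_ps
  dN <- dwell("N"); dS <- dwell("S")
  x <- as.numeric(north)
  ac <- stats::acf(x, lag.max = min(length(x) - 1, 5000), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1
  # fit only the initial decay (down to 1/e): at longer lags the empirical
  # autocorrelation of a single trajectory carries a correlated noise floor
  # that flattens the apparent slope
  first_low <- which(ac <= exp(-1))[1]
  upto <- if (is.na(first_low)) length(ac) else max(first_low - 1, 3)
  keep <- seq_len(min(upto, length(ac)))
  keep <- keep[ac[keep] > 0]
  la <- log(ac[keep]); lg <- lags[keep]
  tau <- -1 / stats::coef(stats::lm(la ~ lg))[["lg"]] * dt_ps
  list(tau_ps = tau, mean_dwell_N_ps = dN, mean_dwell_S_ps = dS,
       k_NS_per_ps = 1 / dN, k_SN_per_ps = 1 / dS,
       n_transitions = n_trans, one_sided = FALSE)
}

#' Build an ideal sugar ring with a prescribed pucker
#'
#' Constructs five ring-atom coordinates on a regular pentagon whose
#' out-of-plane displacements are optimised so that the five endocyclic
#' torsions match the ideal pseudorotation wave
#' \eqn{\nu_j = \nu_{max} \cos(P + 144^\circ (j - 2))}. Useful as an
#' independent geometric oracle for the phase/amplitude formulas and to
#' generate synthetic structure fixtures.
#'
#' @param P Target phase (degrees).
#' @param amplitude Target torsional amplitude \eqn{\nu_{max}} (degrees).
#' @param resid,chain,deoxy Passed to [sugar_ring()].
#' @return A [sugar_ring()].
#' @export
build_sugar_ring <- function(P, amplitude = 38, resid = NA, chain = NA,
                             deoxy = FALSE) {
  j <- 0:4
  nu_target <- amplitude * cos((P + 144 * (j - 2)) * pi / 180)
  r <- 1.45 / (2 * sin(pi / 5))  # pentagon radius for ~1.45 A sides
  xy <- cbind(r * cos(2 * pi * j / 5), r * sin(2 * pi * j / 5))
  torsions_of_z <- function(z) {
    ring <- sugar_ring(cbind(xy, z - mean(z)))
    ring_torsions(ring)
  }
  obj <- function(z) sum((torsions_of_z(z) - nu_target)^2)
  # initial guess from the out-of-plane wave matching the phase convention
  z0 <- 0.1 * (amplitude / 38) * cos((4 * pi * j / 5) - (P - 90) * pi / 180)
  opt <- stats::optim(z0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$value > 1e-4 && amplitude > 1)
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000))
  z <- opt$par - mean(opt$par)
  sugar_ring(cbind(xy, z), resid = resid, chain = chain, deoxy = deoxy)
}

#' Read a torsion or phase time series from delimited text
#'
#' Accepts tab- or comma-separated files with a header containing either the
#' five ring torsions (`time_ps`, `residue`, `nu0` .. `nu4`, degrees) or a
#' precomputed phase column (`time_ps`, `residue`, `P`). Torsions are
#' converted to pseudorotation phase and amplitude per frame.
#'
#' @param path File path.
#' @return Data frame with `time_ps`, `residue`, `phase`, `amplitude`
#'   (amplitude `NA` when only `P` was supplied), ordered as in the file.
#' @export
read_torsion_series <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!all(c("time_ps", "residue") %in% names(tab)))
    stop("torsion series needs 'time_ps' and 'residue' columns")
  nus <- paste0("nu", 0:4)
  if (all(nus %in% names(tab))) {
    st <- apply(as.matrix(tab[, nus]), 1, function(v) {
      p <- pseudorotation(v)
      c(p$phase, p$amplitude)
    })
    data.frame(time_ps = tab$time_ps, residue = tab$residue,
               phase = st[1, ], amplitude = st[2, ])
  } else if ("P" %in% names(tab)) {
    data.frame(time_ps = tab$time_ps, residue = tab$residue,
               phase = tab$P %% 360, amplitude = NA_real_)
  } else {
    stop("torsion series needs either nu0..nu4 or a P column")
  }
}

#' Read sugar rings from a PDB structure
#'
#' Extracts the five ring atoms (O4', C1', C2', C3', C4'; `*` spellings are
#' accepted) of every nucleotide in a PDB file. Multi-MODEL files (e.g. NMR
#' ensembles) yield one ring set per model. Residues missing ring atoms —
#' amino acids, ions, solvent — are skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param model Optional integer vector of model numbers to keep (default:
#'   all).
#' @return List (one element per model) of lists of [sugar_ring()] objects.
#' @export
read_structure <- function(path, model = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  atoms$elety_std <- gsub("\\*", "'", atoms$elety)
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  if (is.null(model)) model <- seq_len(n_models)
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert)
  skipped <- character(0)
  out <- lapply(model, function(m) {
    rings <- list()
    for (key in unique(res_key)) {
      sel <- which(res_key == key)
      ring_idx <- vapply(RING_ATOMS, function(a) {
        w <- sel[atoms$elety_std[sel] == a]
        if (length(w) == 0) NA_integer_ else w[1]
      }, integer(1))
      if (anyNA(ring_idx)) {
        skipped <<- union(skipped,
                          paste0(atoms$resid[sel[1]], " ", key))
        next
      }
      coords <- t(vapply(ring_idx, function(i)
        xyz[m, (3 * i - 2):(3 * i)], numeric(3)))
      deoxy <- !any(atoms$elety_std[sel] %in% c("O2'", "O2''"))
      rings[[length(rings) + 1L]] <-
        sugar_ring(coords, resid = paste0(atoms$resid[sel[1]],
                                          atoms$resno[sel[1]]),
                   chain = atoms$chain[sel[1]], deoxy = deoxy)
    }
    rings
  })
  if (length(skipped) > 0)
    warning("skipped residues without a complete sugar ring: ",
            paste(utils::head(skipped, 10), collapse = "; "),
            if (length(skipped) > 10) " ..." else "")
  out
}
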