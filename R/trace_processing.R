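#' Channel correction parameters
#'
#' @param background_donor,background_acceptor Background counts per frame.
#' @param bleedthrough Fraction of the donor signal leaking into the acceptor
#'   channel, in `[0, 1)`.
#' @return Object of class `correction_params`.
#' @export
correction_params <- function(background_donor = 0, background_acceptor = 0,
                              bleedthrough = 0) {
  stopifnot(bleedthrough >= 0, bleedthrough < 1)
  structure(list(background_donor = background_donor,
                 background_acceptor = background_acceptor,
                 bleedthrough = bleedthrough),
            class = "correction_params")
}

#' Correction parameters matching a simulator emission model
#'
#' @param emission An [emission_model()].
#' @return The [correction_params()] that invert its distortions.
#' @export
correction_params_for <- function(emission) {
  stopifnot(inherits(emission, "emission_model"))
  correction_params(background_donor = emission$background_donor,
                    background_acceptor = emission$background_acceptor,
                    bleedthrough = emission$bleedthrough)
}

#' Correct raw intensities for background and donor bleedthrough
#'
#' Background is subtracted from each channel first, then the bleedthrough
#' fraction of the *background-corrected* donor signal is removed from the
#' acceptor channel:
#' \deqn{I_D = I_D^{raw} - bg_D, \quad
#'       I_A = I_A^{raw} - bg_A - \alpha (I_D^{raw} - bg_D).}
#' Negative corrected values are permitted (and flagged via the
#' `n_negative` attribute) so that noise statistics stay unbiased.
#'
#' @param donor_raw,acceptor_raw Raw per-frame counts (equal length).
#' @param params A [correction_params()].
#' @return List with corrected `donor` and `acceptor` vectors.
#' @export
correct_intensities <- function(donor_raw, acceptor_raw, params) {
  stopifnot(length(donor_raw) == length(acceptor_raw),
            inherits(params, "correction_params"))
  donor <- donor_raw - params$background_donor
  acceptor <- acceptor_raw - params$background_acceptor -
    params$bleedthrough * donor
  out <- list(donor = donor, acceptor = acceptor)
  attr(out, "n_negative") <- sum(donor < 0) + sum(acceptor < 0)
  out
}

#' FRET efficiency from corrected intensities
#'
#' The proximity ratio \eqn{E = I_A / (I_A + I_D)}. No gamma or detection
#' efficiency correction is applied. Frames with non-positive total intensity
#' get `NA` (undefined).
#'
#' @param donor,acceptor Corrected per-frame intensities.
#' @return Numeric FRET series with `NA` where \eqn{I_A + I_D \le 0}.
#' @export
compute_fret <- function(donor, acceptor) {
  stopifnot(length(donor) == length(acceptor))
  tot <- donor + acceptor
  fret <- ifelse(tot > 0, acceptor / tot, NA_real_)
  if (all(is.na(fret)))
    stop("FRET undefined on every frame (total intensity never positive)")
  fret
}

#' Classify a molecule by its interconversion frequency
#'
#' Molecules are assigned to one of four classes from their discretized
#' two-level state sequence: `static_zero` (no binding event within the
#' observation time), `static_high` (no unbinding event), `one_transition`,
#' and `dynamic` (at least two transitions). Only dynamic molecules carry
#' full kinetic information.
#'
#' @param states Discretized sequence with levels `"zero"`/`"high"` (or a
#'   logical/binary vector, `TRUE`/1 = high), e.g. from
#'   [discretize_threshold()].
#' @return One of `"static_zero"`, `"static_high"`, `"one_transition"`,
#'   `"dynamic"`.
#' @export
classify_molecule <- function(states) {
  if (length(states) == 0) stop("empty state sequence")
  s <- as_two_level(states)
  changes <- sum(s[-1] != s[-length(s)])
  if (changes == 0) {
    if (s[1] == "high") "static_high" else "static_zero"
  } else if (changes == 1) "one_transition" else "dynamic"
}

as_two_level <- function(states) {
  if (is.character(states) || is.factor(states)) {
    s <- as.character(states)
    if (!all(s %in% c("zero", "high")))
      stop("state labels must be 'zero' or 'high'")
    s
  } else {
    ifelse(as.numeric(states) > 0, "high", "zero")
  }
}

#' Gaussian mixture fit of a pooled FRET histogram
#'
#' Fits an `n_components` Gaussian mixture to FRET values pooled over
#' molecules and reports the fraction of formed contacts as the weight
#' (integral) of the component closest to the high-FRET mean. Uncertainty is
#' estimated by bootstrapping molecules — traces, not frames, are resampled,
#' because frames within a trace are strongly correlated — and reported as
#' the bootstrap mean +/- 2 s.d.
#'
#' @param fret_by_molecule List of numeric FRET vectors, one per (dynamic)
#'   molecule, or a `fret_ensemble`.
#' @param n_components Number of mixture components (default 2: zero and
#'   high FRET state).
#' @param n_boot Number of bootstrap samples (default 100).
#' @param seed Integer seed for the bootstrap.
#' @param high_fret Reference mean used to identify the bound component.
#' @return Object of class `fret_histogram_fit`: list with `means`, `sds`,
#'   `weights`, `fraction_bound`, `fraction_bound_boot` (mean, lower, upper =
#'   mean +/- 2 s.d.), `n_frames`, `n_molecules`.
#' @export
fit_fret_histogram <- function(fret_by_molecule, n_components = 2,
                               n_boot = 100, seed = 1L, high_fret = 0.75) {
  if (inherits(fret_by_molecule, "fret_ensemble"))
    fret_by_molecule <- lapply(fret_by_molecule, function(tr) tr$fret)
  stopifnot(is.list(fret_by_molecule), n_boot >= 1)
  fret_by_molecule <- lapply(fret_by_molecule, function(x) x[is.finite(x)])
  pooled <- unlist(fret_by_molecule, use.names = FALSE)
  if (length(pooled) < 100)
    stop("need at least 100 pooled frames for a mixture fit")
  fit1 <- gmm_fit(pooled, n_components)
  frac <- function(fit) {
    bound <- which.min(abs(fit$means - high_fret))
    sum(fit$weights[bound])
  }
  set.seed(seed)
  nm <- length(fret_by_molecule)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nm, nm, replace = TRUE)
    frac(gmm_fit(unlist(fret_by_molecule[idx], use.names = FALSE),
                 n_components))
  }, numeric(1))
  structure(list(means = fit1$means, sds = fit1$sds, weights = fit1$weights,
                 fraction_bound = frac(fit1),
                 fraction_bound_boot = c(mean = mean(boot),
                                         lower = mean(boot) - 2 * stats::sd(boot),
                                         upper = mean(boot) + 2 * stats::sd(boot)),
                 n_frames = length(pooled), n_molecules = nm),
            class = "fret_histogram_fit")
}

# 1-D Gaussian mixture via mclust (unequal variances); falls back to the
# equal-variance model when the general one degenerates
#' @importFrom mclust Mclust mclustBIC
gmm_fit <- function(x, G) {
  fit <- tryCatch(
    Mclust(x, G = G, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- Mclust(x, G = G, modelNames = "E", verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed to converge")
  ord <- order(fit$parameters$mean)
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, G)
  list(means = as.numeric(fit$parameters$mean)[ord],
       sds = sds[ord],
       weights = fit$parameters$pro[ord])
}

#' Hill fit of a Mg2+ binding isotherm
#'
#' Fits \eqn{f([Mg]) = sat \cdot [Mg]^n / ([Mg]^n + mid^n)} by nonlinear
#' least squares, describing how the fraction of formed tertiary contacts
#' grows with the Mg2+ concentration. The midpoint `mid` is the
#' concentration of half-saturation, `sat` the plateau (the EBS1*/IBS1*
#' isotherm saturates well below 1 at sub-saturating exon concentration),
#' and `n` the Hill coefficient.
#'
#' @param mg Concentrations (mM), at least 4 points.
#' @param fraction_bound Fractions in `[0, 1]` at each concentration.
#' @param n_boot Residual-bootstrap samples for parameter uncertainty.
#' @param seed Integer seed.
#' @return Object of class `isotherm_fit`: list with `midpoint_mM`,
#'   `saturation`, `hill_n`, `boot` (2 s.d. half-widths), `fitted`.
#' @export
fit_binding_isotherm <- function(mg, fraction_bound, n_boot = 100, seed = 1L) {
  stopifnot(length(mg) == length(fraction_bound), length(mg) >= 4,
            all(mg >= 0))
  if (max(fraction_bound) - min(fraction_bound) < 1e-8)
    stop("no curvature in isotherm data; refusing to extrapolate")
  df <- data.frame(c = mg, f = fraction_bound)
  hill_fit <- function(df) {
    start <- list(sat = max(df$f),
                  mid = max(stats::median(df$c[df$c > 0]), 1e-6), n = 1)
    minpack.lm::nlsLM(f ~ sat * c^n / (c^n + mid^n), data = df,
                      start = start,
                      lower = c(sat = 1e-6, mid = 1e-9, n = 0.1),
                      upper = c(sat = 1.5, mid = Inf, n = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- hill_fit(df)
  cf <- stats::coef(fit)
  set.seed(seed)
  res <- stats::resid(fit)
  boot <- t(vapply(seq_len(n_boot), function(b) {
    dfb <- df
    dfb$f <- stats::fitted(fit) + sample(res, length(res), replace = TRUE)
    tryCatch(stats::coef(hill_fit(dfb)), error = function(e) cf * NA)
  }, numeric(3)))
  structure(list(midpoint_mM = unname(cf["mid"]),
                 saturation = unname(cf["sat"]),
                 hill_n = unname(cf["n"]),
                 boot = apply(boot, 2, stats::sd, na.rm = TRUE) * 2,
                 fitted = stats::fitted(fit)),
            class = "isotherm_fit")
}
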