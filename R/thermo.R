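#' Physical constants and conditions for thermodynamic conversions
#'
#' @param T_K Temperature in Kelvin (default 298 K, which reproduces
#'   literature free-energy tables for this system to the printed decimal in
#'   nearly every cell; 298.15 or 300 K move the last digit in a few).
#' @param kappa Transmission coefficient of transition-state theory in
#'   (0, 1]; `kappa = 1` gives a lower bound on the barrier height.
#' @return List with `R` (8.314 J mol^-1 K^-1), `kB`, `h`, `T_K`, `kappa`.
#' @export
thermo_constants <- function(T_K = 298, kappa = 1) {
  stopifnot(T_K > 0, kappa > 0, kappa <= 1)
  list(R = 8.314, kB = 1.380649e-23, h = 6.62607015e-34,
       T_K = T_K, kappa = kappa)
}

#' Second-order association rate from a pseudo-first-order rate
#'
#' \eqn{k_{on} = k'_{on} / c}: the pseudo-first-order rate observed at a
#' fixed ligand concentration `c` divided by that concentration.
#'
#' @param k_on_pseudo Pseudo-first-order rate (\eqn{s^{-1}}).
#' @param ligand_conc Ligand concentration (M).
#' @return Second-order rate coefficient (\eqn{M^{-1} s^{-1}}).
#' @export
kon_from_pseudo_first_order <- function(k_on_pseudo, ligand_conc) {
  stopifnot(ligand_conc > 0)
  k_on_pseudo / ligand_conc
}

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln(K_d)} with \eqn{K_d} in molar units; negative for
#' sub-molar affinities.
#'
#' @param kd_M Dissociation constant (M), > 0.
#' @param constants From [thermo_constants()].
#' @return \eqn{\Delta G} in kJ mol^-1.
#' @export
delta_g_bind <- function(kd_M, constants = thermo_constants()) {
  if (any(kd_M <= 0)) stop("K_d must be positive")
  constants$R * constants$T_K * log(kd_M) / 1000
}

#' Transition-state barrier from an association rate
#'
#' Transition-state theory:
#' \eqn{\Delta G^\ddagger = -RT \ln(k_{on} h / (\kappa k_B T))}.
#' The numerical value of the second-order \eqn{k_{on}} (in
#' \eqn{M^{-1} s^{-1}}) is used inside the logarithm; strictly the Eyring
#' expression applies to first-order rates, so the absolute barrier carries a
#' standard-state ambiguity of \eqn{RT \ln c^0} — differences between
#' conditions are unaffected. With \eqn{\kappa = 1} the barrier is a lower
#' bound.
#'
#' @param k_on Second-order association rate (\eqn{M^{-1} s^{-1}}), > 0.
#' @param constants From [thermo_constants()].
#' @return \eqn{\Delta G^\ddagger} in kJ mol^-1.
#' @export
delta_g_barrier <- function(k_on, constants = thermo_constants()) {
  if (any(k_on <= 0)) stop("k_on must be positive")
  with(constants, -R * T_K * log(k_on * h / (kappa * kB * T_K)) / 1000)
}

#' Two-site Mg2+ binding constants
#'
#' Association constants of the two Mg2+ sites of the EBS1* hairpin (one in
#' the loop, one at the stem-loop transition), as determined from NMR
#' chemical shift perturbations. Constants may be given directly as
#' association constants (M^-1) or as dissociation midpoints in mM
#' (converted by \eqn{K = 1/K_d}).
#'
#' @param K1,K2 Association constants (\eqn{M^{-1}}), both > 0.
#' @return List of class `binding_constants`.
#' @export
binding_constants <- function(K1, K2) {
  stopifnot(K1 > 0, K2 > 0)
  structure(list(K1 = K1, K2 = K2), class = "binding_constants")
}

#' @rdname binding_constants
#' @param kd1_mM,kd2_mM Dissociation midpoints in mM; defaults are the NMR
#'   values for the loop site (1.78 mM) and the stem-loop site (0.87 mM).
#' @export
binding_constants_from_kd_mM <- function(kd1_mM = 1.78, kd2_mM = 0.87) {
  binding_constants(1 / (kd1_mM * 1e-3), 1 / (kd2_mM * 1e-3))
}

#' Fractional Mg2+ occupancy of a two-site RNA
#'
#' The fraction of Mg2+-bound RNA for two independent sites with association
#' constants \eqn{K_1}, \eqn{K_2}:
#' \deqn{\Theta = \frac{K_1 c + K_2 c + K_1 K_2 c^2}
#'                     {1 + K_1 c + K_2 c + K_1 K_2 c^2}}
#' with \eqn{c = [Mg^{2+}]}. This is the ratio of the singly- and
#' doubly-bound terms of the two-site partition function to the full sum.
#'
#' @param mg_M Mg2+ concentration(s) in M (vectorised), >= 0.
#' @param binding A [binding_constants()].
#' @return Fraction(s) \eqn{\Theta} in `[0, 1)`.
#' @export
mg_occupancy <- function(mg_M, binding) {
  stopifnot(inherits(binding, "binding_constants"), all(mg_M >= 0))
  x <- binding$K1 * mg_M + binding$K2 * mg_M + binding$K1 * binding$K2 * mg_M^2
  x / (1 + x)
}

#' Dissociation constant from on- and off-rates
#'
#' \eqn{K_d = k_{off} / k_{on}}; a consistency check against the
#' population-based estimate of [state_population_kd()].
#'
#' @param k_on Second-order association rate (\eqn{M^{-1} s^{-1}}).
#' @param k_off Dissociation rate (\eqn{s^{-1}}).
#' @return \eqn{K_d} in M.
#' @export
kd_from_rates <- function(k_on, k_off) {
  stopifnot(all(k_on > 0), all(k_off > 0))
  k_off / k_on
}

#' Derived kinetic-thermodynamic table for one condition
#'
#' Bundles the standard conversions applied to each measured condition:
#' second-order on-rate from the pseudo-first-order rate and ligand
#' concentration, binding free energy from the population-based dissociation
#' constant, barrier height from the on-rate, and the rate-based
#' \eqn{K_d = k_{off}/k_{on}} cross-check.
#'
#' @param k_on_pseudo Pseudo-first-order association rate (\eqn{s^{-1}}).
#' @param k_off Dissociation rate (\eqn{s^{-1}}).
#' @param kd_nM Population-based dissociation constant (nM); optional.
#' @param ligand_conc_M Ligand concentration (M).
#' @param constants From [thermo_constants()].
#' @return One-row data frame: `k_on_pseudo_s`, `k_on_M_s`, `k_off_s`,
#'   `kd_rates_nM`, `kd_pop_nM`, `dG_bind_kJ`, `dG_barrier_kJ`.
#' @export
thermo_table <- function(k_on_pseudo, k_off, kd_nM = NA_real_,
                         ligand_conc_M, constants = thermo_constants()) {
  k_on <- kon_from_pseudo_first_order(k_on_pseudo, ligand_conc_M)
  kd_rates <- kd_from_rates(k_on, k_off)
  kd_used <- if (is.na(kd_nM)) kd_rates * 1e9 else kd_nM
  data.frame(k_on_pseudo_s = k_on_pseudo,
             k_on_M_s = k_on,
             k_off_s = k_off,
             kd_rates_nM = kd_rates * 1e9,
             kd_pop_nM = kd_nM,
             dG_bind_kJ = delta_g_bind(kd_used * 1e-9, constants),
             dG_barrier_kJ = delta_g_barrier(k_on, constants))
}
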