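---
title: "Kinetic analysis of single-molecule FRET trajectories with degenerate states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of single-molecule FRET trajectories with degenerate states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkin)
```

## The system and the model

`fretkin` analyses camera-based single-molecule FRET trajectories of a
reversible bimolecular contact. Its motivating system is the EBS1*/IBS1*
exon-intron tertiary contact of group II introns: a surface-immobilised
RNA hairpin (EBS1*, donor-labelled) that transiently base-pairs with a
seven-nucleotide RNA (IBS1*) or DNA (dIBS1*) strand carrying the acceptor.
Each binding event moves the dyes close together and switches the proximity
ratio

$$E = \frac{I_A}{I_A + I_D}$$

from a zero-FRET level to a high-FRET level near 0.75. The kinetics are
modelled as a continuous-time Markov chain. Under high monovalent salt a
two-state scheme (unbound 0, bound 1) suffices. In the presence of Mg²⁺ a
*sequential three-state* scheme describes the data:

$$0 \;\underset{k_{10}}{\overset{k_{01}}{\rightleftharpoons}}\; 1
\;\underset{k_{21}}{\overset{k_{12}}{\rightleftharpoons}}\; 2,$$

where state 1 is the exon-bound contact and state 2 the exon-bound contact
with a site-specifically coordinated Mg²⁺ ion. States 1 and 2 share the
same FRET level — a *degenerate* FRET state — and are distinguishable only
through their exit kinetics: dissociation from the bound level is
multiexponential even though only two FRET levels are visible. The
generator of the three-state scheme is

$$K = \begin{pmatrix} -k_{01} & k_{01} & 0 \\
k_{10} & -(k_{10}+k_{12}) & k_{12} \\ 0 & k_{21} & -k_{21}\end{pmatrix}.$$

Note the $(3,2)$ entry: probability conservation for the sequential scheme
requires the reverse rate $k_{21}$ there. Some printed forms of this matrix
repeat $k_{12}$ in the third row; with $k_{12} \neq k_{21}$ that matrix
would not conserve probability, so the package uses $k_{21}$.

## The synthetic-data generator

No raw microscope traces are publicly deposited for this system, so the
package ships a simulator that replaces the microscope and defines the
study conditions for all stochastic tests:

1. **Exact-event state paths.** Gillespie-style sampling from the generator
   $K$: dwell in state $i$ is Exponential$(-K_{ii})$, the successor is
   chosen proportionally to $k_{ij}$. Dwells are sampled in continuous
   time, *then* binned — not as per-frame Bernoulli transitions — because
   the model is a continuous-time generator.
2. **Camera binning.** The camera integrates photons, so each frame value
   is the occupancy-weighted average of the emission levels visited during
   the frame (5 Hz frames by default, i.e. `dt = 0.2` s; observation window
   400 s). The dominant state of each frame is kept as ground truth for
   benchmarking discretizers.
3. **Noisy two-channel emission.** The ideal split is $I_A = E\,I_{tot}$,
   $I_D = (1-E)\,I_{tot}$ with Gaussian noise applied on the FRET axis so
   that the recomputed apparent FRET has standard deviation
   `fret_noise_sd`, then channel backgrounds and a donor-bleedthrough
   fraction are added; an optional exponential photobleaching time
   truncates the signal to background. Negative raw counts are clipped at
   zero.

Defaults: high-FRET mean 0.75, zero-FRET mean 0.0, `fret_noise_sd = 0.10`
(a package default in the realistic range for camera-based smFRET, not a
literature value), total intensity 500 counts/frame, backgrounds 150
counts/frame per channel. The backgrounds are deliberately large relative
to the channel noise so that clipping raw counts at zero is rare and the
corrected FRET noise stays effectively Gaussian; the per-trace `fret`
column is always the efficiency recomputed after the matching background
and bleedthrough correction, which is exactly the ideal level plus the
Gaussian FRET noise.

Seeds: one master seed per ensemble; trace $i$ uses `seed + 2i` for the
path and `seed + 2i + 1` for the emission noise, so ensembles are
reproducible as a whole and per trace.

What the generator does *not* emulate: photon-level (Poisson) statistics,
dye photophysics (blinking), spot-detection artefacts, drift. Passing
recovery tests on these synthetic ensembles therefore demonstrates the
correctness of the estimators under the stated noise model, not robustness
to every camera artefact of real data.

## Dwell-time statistics

Trajectories are discretized by a threshold (default 0.375, the midpoint of
the two emission levels; in general the midpoint of the fitted mixture
means). Molecules are classified by their number of transitions into
static zero, static high, one-transition and dynamic; only dynamic
molecules (≥ 2 transitions) enter kinetic analysis. Run lengths become
dwell times; the first and last dwell of every trace are censored by the
observation window and are excluded from fits by default (a toggle allows
sensitivity analysis — the corresponding published analysis does not state
its convention).

Per-molecule statistics follow: mean dwells $\langle t_{zero}\rangle$,
$\langle t_{high}\rangle$, within-trace ranges $\Delta t$, the
per-molecule dissociation constant
$K_{d,n} = c\,\langle t_{zero}\rangle / \langle t_{high}\rangle$, and the
logistic fit of the cumulative $K_{d,n}$ distribution

$$P(K_{d,n}) = \frac{1}{1 + (K_d/K_{d,n})^p},$$

whose inflection point $K_d$ is the ensemble stability constant.
Ensemble survival curves of the pooled dwells are fitted with a
biexponential ($S(t) = w e^{-k_1 t} + (1-w) e^{-k_2 t}$, $k_1 \ge k_2$) or
a stretched exponential ($S(t) = e^{-(t/\tau)^\beta}$, $\beta \in (0,1]$).

**Fit objective.** The survival fits default to direct maximum likelihood
on the pooled dwell times (exponential-mixture or Weibull likelihood,
left-truncated at `t_min`). Least squares on the empirical survival with
uniform weights is also provided, but it is not the default for a concrete
reason: with a strongly dominant fast component (e.g. $w = 0.96$) the
least-squares objective can find solutions with *lower* residual sum than
the generating parameters by trading tail fidelity for tiny early-time
gains, misestimating $w$ by ten percentage points or more, while the
likelihood objective recovers the generating parameters. Dwells shorter
than `t_min` (recommended: two frames) are excluded because sub-frame
events are unobservable and one-frame dwells are heavily biased by
discretization.

Bootstrap uncertainties resample molecules, not frames, because frames
within a trace are strongly correlated; 100 bootstrap samples by default,
reported as mean ± 2 s.d.

## The global degenerate-state HMM

The headline estimator is a hidden Markov model trained in two stages:

1. **Per-trace stage.** A Gaussian-emission HMM is fitted to each dynamic
   trace by Baum–Welch EM (emissions free). The emission components are
   then pooled across traces by the median — a robust choice, since
   individual traces can lack one state entirely.
2. **Global stage.** With emissions frozen, a single shared transition
   matrix and start vector are optimised against the summed log-likelihood
   of all dynamic traces. Individual traces are far too short to constrain
   slow exchange rates; the ensemble is not.

Degeneracy enters through the emission map of the model specification:
hidden states 1 and 2 share one emission component in the sequential
three-state network, and the 0↔2 link is structurally forbidden. The two
bound states are therefore identified by their topology (state 1 has the
direct path to the unbound state), not by their emissions.

**Camera-blur-aware likelihood.** A frame during which the chain jumps
between different FRET levels integrates part of each level, so its
observed value lies between the two means. The global stage therefore uses
a pair-emission likelihood by default: the density of frame $t$ given the
state pair $(s_{t-1}, s_t)$ is the box distribution on
$[\min(E_i,E_j), \max(E_i,E_j)]$ convolved with the Gaussian noise —
exactly the distribution of an occupancy-averaged level when a single jump
time falls uniformly inside the frame. With the plain per-state Gaussian
likelihood these blurred frames are outliers under both states and the
maximum-likelihood rates are substantially biased low.

**Numerics.** The forward/backward and Viterbi recursions are implemented
in C++ (Rabiner scaling in linear space; Viterbi in log space with ties
broken toward the lower state index). Convergence is declared when the
log-likelihood gain per frame drops below `tol` (default $10^{-6}$) or
after `max_iter` iterations. Initial transition matrices come from
threshold-based dwell estimates; restarts jitter them multiplicatively.
Model ranking uses $BIC = -2\log L + p\ln n$ with $p$ counted as the
allowed off-diagonal transition entries plus $n_{states}-1$ start
probabilities (emissions are fixed at the global stage; when free, two
parameters per emission component are added). This counting is stated
explicitly so BIC values are comparable across network specifications.

**From transition probabilities to rates.** The default conversion is the
first-order approximation $k_{ij} = A_{ij}/dt$, with a warning once any
$A_{ij} > 0.1$. The matrix-logarithm alternative $K = \log(A)/dt$ is
exact for an embeddable chain and is used by the acceptance analyses; a
transition matrix estimated with structural zeros is never exactly
embeddable, so small negative fill-ins on forbidden entries are projected
to zero (large violations still raise an error).

**Residual discretization bias and its correction.** Even with the
blur-aware likelihood, events shorter than one camera frame are
unobservable: sub-frame excursions leave at most a partial bump and the
fitted rates of fast-exiting states shrink by 10–20% at
$k\,dt \approx 0.1$. Where the acceptance analyses report recovered rates,
they therefore apply one step of indirect inference: the full estimator
(simulate → emission pooling → global HMM → matrix-log rates) is re-run on
an ensemble simulated from its own first-pass estimate, the per-rate
shrinkage factor is measured, and the first-pass estimate is divided by
it. This is a standard simulation-based bias correction; it uses only the
package's own forward model and no external information. Two details
matter. The correction ensemble matches the data size, because the
estimator's bias depends on ensemble size — larger ensembles constrain
the degenerate-state likelihood better — so a replicate of a different
size measures the wrong shrinkage. And the replicate is fitted *exactly*
like the data (same initialisation protocol, same restarts): part of the
bias is which likelihood basin the estimator's initialisation selects, so
a replicate fit seeded at its own generating parameters would measure no
bias at all. The shrinkage is averaged over two independent replicates by
default, because a single replicate fit carries sampling noise of the same
order as the bias being corrected, and the averaged factors are clamped to
at most 1 (discretization can only shrink rates) and at least 0.5.
Residual error after correction is dominated by the realization noise of
the degenerate-pair exit rates, roughly ±10% at 250 traces of 400 s.

Errors on transition parameters come from likelihood-ratio profiling: one
entry of the transition matrix is clamped on a grid, all remaining
parameters are re-optimised by constrained EM, and the (asymmetric) bounds
sit where twice the log-likelihood drop crosses the $\chi^2(1)$ quantile
(1σ by default).

## Thermodynamic conversions

With the gas constant $R$ and $T = 298$ K (the published energy tables are
reproduced to the printed decimal at 298 K; the exact temperature used
there is not stated, and 298.15 vs 300 K moves the last digit in a few
cells — $T$ is configurable):

* $k_{on} = k'_{on}/c$ converts the pseudo-first-order association rate at
  ligand concentration $c$ (35 nM for IBS1*, 50 nM for dIBS1*) into the
  second-order rate coefficient;
* $\Delta G = RT \ln K_d$ (with $K_d$ in molar units) is the stability of
  the bound state;
* $\Delta G^\ddagger = -RT\ln\!\big(k_{on} h/(\kappa k_B T)\big)$ is the
  association barrier from transition-state theory. The numerical value of
  the *second-order* $k_{on}$ is used inside the logarithm, as in the
  published analysis; strictly the Eyring expression applies to
  first-order rates, so absolute barriers carry a standard-state offset
  while differences between conditions are unaffected. With the
  transmission coefficient $\kappa = 1$ (its maximum), the formula yields
  the upper estimate of the barrier: the same observed rate with fewer
  successful crossings ($\kappa < 1$) would imply a barrier lower by
  $RT\ln(1/\kappa)$.
* The fraction of Mg²⁺-bound RNA for two independent sites with
  association constants $K_1, K_2$ is
  $\Theta = (K_1 c + K_2 c + K_1 K_2 c^2)/(1 + K_1 c + K_2 c + K_1 K_2 c^2)$,
  the occupied fraction of the two-site partition function. The NMR-derived
  dissociation midpoints 1.78 mM (loop) and 0.87 mM (stem-loop transition)
  are provided as a convenience constructor.

## Sugar pseudorotation

The conformation of a five-membered sugar ring is parameterised by the
pseudorotation phase $P$ and amplitude $\nu_{max}$. From the five
endocyclic torsions $\nu_0 \ldots \nu_4$:

$$\tan P = \frac{\nu_4 + \nu_1 - \nu_3 - \nu_0}
{2\nu_2(\sin 36^\circ + \sin 72^\circ)}, \qquad
\nu_{max} = \frac{\nu_2}{\cos P}.$$

A Cartesian definition (Cremer–Pople-style, from the out-of-mean-plane
displacements of the five ring atoms) is computed alongside and reported
on the same phase scale; the two agree within a couple of degrees for
plausible rings, and the Cartesian amplitude is reported separately in
Ångström because the two amplitude conventions are not interchangeable.
Phases are classified into ten 36°-wide modes with C3'-endo covering
[0°, 36°), so that the canonical C3'-endo (P ≈ 18°, A-form/RNA) and
C2'-endo (P ≈ 162°, B-form/DNA) phases are bin centres; the bin offset is
configurable since only the 36° increment is fixed by convention. Rings
with amplitude below 1° are treated as planar, with an undefined phase.

Pucker dynamics are summarised by reducing the phase trajectory to a
north/south indicator (north: $P \in [270°, 360°) \cup [0°, 90°)$ — the
package's own split, chosen symmetric about the canonical N/S centres) and
reporting mean dwell times per side plus the decay time of the indicator
autocorrelation fitted over its initial decay (down to $1/e$): at longer
lags the empirical autocorrelation of a single trajectory carries a
correlated noise floor that flattens the apparent slope. For a two-state
telegraph process the decay time equals $1/(k_{NS}+k_{SN})$, which the
tests verify.

`build_sugar_ring()` constructs ring coordinates whose torsions match the
ideal wave $\nu_j = \nu_{max}\cos(P + 144°(j-2))$ by optimising the
out-of-plane displacements of a regular pentagon; it serves as the
geometric oracle for round-trip tests (build at known $(P, \nu_{max})$,
re-measure, compare) and generated the synthetic PDB fixture shipped under
`inst/extdata/` (labelled synthetic in the file header; it is not an
experimental structure).

## Problem sizes and reproducibility

The stochastic validation analyses use ensembles of 150–250 traces of
400 s at 5 Hz with FRET noise 0.1 — matching the stated experimental
conditions of the motivating study — for global-HMM rate recovery, and
smaller ensembles (tens of traces) for classification, dwell statistics
and model selection, where the statistics converge faster. Every random
operation consumes an explicit seed; `scripts/acceptance.R` derives all of
its seeds from the single `--seed` argument.

## Known limitations

* Rates approaching the frame rate ($k\,dt \gtrsim 0.3$) are not reliably
  recoverable; the simulator can generate them but the HMM stage will
  underestimate them even with the blur-aware likelihood and bias
  correction.
* The Gaussian emission model ignores photon-counting statistics and dye
  blinking; the zero-FRET state of real corrected data can be mildly
  non-Gaussian.
* Missed-event correction for dwell-time fits is limited to the
  `t_min` cut; no analytical dead-time correction is applied.
* The HMM start distribution is shared across traces; ensembles whose
  molecules start in systematically different states (e.g. flow
  experiments) violate this.
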