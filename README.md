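# fretkin

Kinetic analysis of camera-based single-molecule FRET trajectories with
degenerate-state hidden Markov models, built around the EBS1*/IBS1*
exon–intron tertiary contact of group II introns.

## The problem

A surface-immobilised RNA hairpin (EBS1*) transiently base-pairs with a
short RNA (IBS1*) or DNA (dIBS1*) exon mimic. Each binding event switches
the FRET proximity ratio `E = I_A / (I_A + I_D)` between a zero-FRET and a
high-FRET (~0.75) level. In the presence of Mg²⁺, exon dissociation is
*kinetically heterogeneous*: the bound FRET level hides two interconverting
kinetic states — with and without a site-specifically coordinated Mg²⁺ ion —
that share the same FRET efficiency. Such a *degenerate FRET state* is
invisible to the FRET histogram and can only be resolved kinetically.

`fretkin` implements the full analysis chain for this class of experiment:

- **`synthetic_traces`** — an exact-event (Gillespie) continuous-time
  Markov chain simulator with occupancy-weighted camera binning, Gaussian
  FRET noise, channel backgrounds, donor bleedthrough and optional
  photobleaching (`rate_model()`, `simulate_ensemble()`); it replaces the
  microscope, since no raw traces are publicly deposited for this system.
- **`trace_processing`** — background/bleedthrough corrections, FRET
  efficiency, molecule classification (static zero / static high / one
  transition / dynamic), Gaussian-mixture FRET histograms with
  molecule-level bootstrap, Hill binding isotherms.
- **`dwell_analysis`** — threshold discretization, dwell extraction with
  censoring flags, per-molecule mean dwells and ranges, k-means cluster
  centres, per-molecule dissociation constants
  `K_d,n = c · ⟨t_zero⟩/⟨t_high⟩`, the logistic fit
  `P(K_d,n) = 1/(1 + (K_d/K_d,n)^p)` of the cumulative `K_d,n`
  distribution, and biexponential / stretched-exponential survival fits.
- **`hmm_kinetics`** — per-trace and global Baum–Welch HMMs with shared
  transition matrix, fixed pooled emissions, degenerate emission maps,
  sequential network topologies, a camera-blur-aware pair-emission
  likelihood, BIC model ranking, Viterbi decoding, likelihood-ratio error
  bounds, and rate recovery with indirect-inference bias correction
  (`recover_rate_model()`).
- **`thermo`** — `k_on = k'_on/c`, `ΔG = RT ln K_d`,
  `ΔG‡ = −RT ln(k_on h/(κ k_B T))`, the two-site Mg²⁺ occupancy
  `Θ`, and `K_d = k_off/k_on` cross-checks.
- **`pucker_analysis`** — sugar pseudorotation phase/amplitude from PDB
  structures or torsions (Altona–Sundaralingam and a Cartesian definition),
  the ten 36°-wide pucker modes, circular histograms and medians, and
  north/south repuckering correlation times.
- **`io_cli`** — a delimited trace format with JSON sidecars,
  `run_pipeline()` for the end-to-end analysis, and a thin CLI wrapper in
  `inst/cli/fretkin.R`.

## Worked example

Simulate an ensemble from the published three-state model of the RNA–RNA
contact at 20 mM Mg²⁺ (rates in s⁻¹: k01 = 0.0214, k10 = 0.146,
k12 = 0.331, k21 = 0.0256; 35 nM ligand), then recover the rates with the
global HMM:

```r
library(fretkin)

mods <- ebs1_rate_models()
ens <- simulate_ensemble(mods$ibs1_mg$model, emission_model(),
                         n_traces = 250, duration = 400, dt = 0.2,
                         seed = 421)
rec <- recover_rate_model(ens, type = "three_state", seed = 422)
round(rec$rates, 4)
#>    k01    k10    k12    k21
#> 0.0230 0.1354 0.3446 0.0264

pops <- state_population_kd(rec$fit, ligand_conc = 35)
round(pops$kd, 1)   # population-based Kd in nM
#> 16.5

tab <- thermo_table(k_on_pseudo = rec$rates[["k01"]],
                    k_off = rec$rates[["k10"]],
                    kd_nM = pops$kd, ligand_conc_M = 35e-9)
round(tab$dG_bind_kJ, 1); round(tab$dG_barrier_kJ, 1)
#> -44.4
#> 39.8
```

All four generating rates come back within 8% (the simulation-based bias
correction removes most of the shrinkage that camera binning inflicts on
exit rates near a tenth of the frame rate; the residual is realization
noise of the degenerate-pair split), the population-based dissociation
constant lands in the low-tens-of-nM range characteristic of the
Mg²⁺-stabilised contact, and the derived free energies follow from
`ΔG = RT ln K_d` and transition-state theory at 298 K.

Sugar puckers from the bundled synthetic structure fixture (first model):

```r
pdb <- system.file("extdata", "synthetic_sugars.pdb", package = "fretkin")
rings <- read_structure(pdb)[[1]]
vapply(rings, function(r) pseudorotation(r)$mode, "")
#> "C3'-endo" "C3'-endo" "C3'-endo" "C3'-endo" "C3'-endo" "C2'-endo" "C3'-endo"
```

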