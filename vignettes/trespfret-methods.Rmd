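---
title: "Simulating FRET observables with transition charges in a polarizable environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating FRET observables with transition charges in a polarizable environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trespfret)
```

## The problem

Fluorescence quenching of a single tryptophan by a bound ligand is one of
the cheapest ways to probe where a small molecule sits in a protein.  The
textbook analysis converts a measured Förster resonance energy transfer
(FRET) efficiency into a donor--acceptor distance through the Förster
relation

$$E = \frac{1}{1 + (R/R_0)^6},$$

which silently assumes (i) that each chromophore can be replaced by a point
transition dipole, (ii) that the mutual orientation of the dipoles is
isotropic ($\kappa^2 = 2/3$), and (iii) that the environment screens the
interaction by a constant factor $s = 1/n^2$.  None of the three holds in a
protein--ligand complex: the ligand is orientationally locked by the
pocket, chromophore dimensions are comparable to their separation, and the
local dielectric response depends on which residues and how much solvent
surround the pair.

`trespfret` implements the atomistic alternative.  Chromophores are
represented by **transition charges** -- atom-centered charges fitted
(externally, from quantum-mechanical transition densities) to reproduce the
electrostatic potential of the excitation -- and the environment by a
classical **polarizable model** in which every nearby atom carries an
isotropic polarizability and responds to the chromophore fields with an
induced point dipole.  Applied frame by frame to a molecular-dynamics
ensemble of a candidate binding mode, this yields coupling trajectories,
screening factors, orientation-factor statistics, and disorder-resolved
efficiency distributions that can be ranked against titration experiments.

## The coupling model

For one structural frame the electronic coupling is

$$V = V_\mathrm{Coul} + V_\mathrm{env},$$

with the Coulomb term a plain double sum over donor and acceptor transition
charges,

$$V_\mathrm{Coul} = \sum_{i,j} \frac{q^T_{D,i}\, q^T_{A,j}}{|r_i - r_j|},$$

and the environment term the interaction of the donor's transition-charge
field with the dipoles induced in the environment by the acceptor's
transition charges,

$$V_\mathrm{env} = -\sum_l \mu_l \cdot E_D(r_l), \qquad
  \mu_l = \alpha_l \Big( E_A(r_l) + \sum_{m \neq l} T_{lm}\, \mu_m \Big).$$

The sign follows the usual charge--dipole interaction energy
$U = -\mu\cdot E$; with a single site and no mutual coupling the term
reduces to the closed form $-\alpha\, E_D \cdot E_A$, which the test suite
asserts exactly.  Because the dipole--dipole tensor $T$ is symmetric, the
roles of donor and acceptor can be exchanged (induce with the donor field,
contract with the acceptor field) without changing the value; this
linear-response reciprocity is asserted to $10^{-8}$ relative on random
fixtures.

The per-frame **screening factor**

$$s = \frac{V_\mathrm{Coul} + V_\mathrm{env}}{V_\mathrm{Coul}}$$

is the atomistic counterpart of the Förster factor $1/n^2$.  Near a node of
$V_\mathrm{Coul}$ the ratio is ill-conditioned; frames with
$|V_\mathrm{Coul}| < 10^{-9}$ Hartree are flagged `near-zero-coulomb`,
retained in the raw output, and excluded from screening and ratio
statistics.  The threshold is a package choice: the quantity is genuinely
undefined at a node and some convention is required.

Point-dipole (PDA) quantities are computed per frame from the instantaneous
transition dipoles $\mu = \sum_i q_i r_i$ and the center-to-center axis:
the signed orientation factor
$\kappa = \hat\mu_D\cdot\hat\mu_A - 3(\hat\mu_D\cdot\hat r)(\hat\mu_A\cdot\hat r)$
and the unscreened coupling $V_\mathrm{PDA} = \kappa\,\mu_D \mu_A / R^3$.
The ratio $V_\mathrm{PDA}/V_\mathrm{Coul}$, binned in 1 Å distance shells,
quantifies where the dipole approximation fails; on the analytic
dipole-pair fixture the deviation falls below 1% once $R$ exceeds roughly
50 times the intramolecular charge separation, and grows steeply toward
contact.

### Conventions chosen where the field has none

* **Chromophore center.** "Center-to-center distance" is not standardized;
  we use the unweighted centroid of the charge-bearing atoms and record it
  in every output so alternative conventions can be compared.
* **Units.** Coordinates are stored in Å and converted to bohr only where
  energies or fields are evaluated; charges in $e$, dipoles in
  $e\cdot$bohr, couplings in Hartree internally with wavenumber copies in
  the exported records.  Atomic units keep the coupling and rate formulas
  constant-free.
* **Transition-charge sign.** The global sign of a transition density is
  arbitrary.  All distribution statistics are built from $V^2$, $s$ (a
  ratio), or $\kappa^2$; signed values are retained in the raw records.
* **Net-charge tolerance.** ESP-fitted transition charges never sum to
  exactly zero; sets are accepted when $|\sum q| \le 10^{-3}\,e$
  (configurable) and rejected otherwise -- never silently neutralized.
* **Dipole rescaling.** `rescale_to_dipole()` scales a charge set to match
  a reference transition-dipole magnitude.  It is provided but optional:
  whether to impose the reference dipole is a modelling decision for the
  user, so nothing in the pipeline applies it implicitly.

## The polarizable environment

The environment of a frame is every non-chromophore atom whose distance to
*any* donor or acceptor atom is at most the cutoff (default 15 Å, closed
interval).  Atom-based truncation is the default because it is the simplest
reproducible rule; whole-residue inclusion is available via
`whole_residue = TRUE` when residue labels are supplied.  Polarizabilities
are attached from a table keyed by atom type; the shipped
`default_polarizabilities()` is a small element-based synthetic table of
magnitudes typical for additive polarizable force fields, intended for
fixtures and examples -- production work should load the force-field table
actually parameterized for the system.

The induced-dipole equations are solved two ways, and the two must agree:

* `direct` assembles the dense $3N \times 3N$ system
  $(\alpha^{-1} - T)\,\mu = E$ and solves it; this is the reference for the
  site counts ($N \lesssim$ a few hundred) typical of a 15 Å cutoff
  selection.
* `iterative` runs a Jacobi fixed-point iteration with linear mixing 0.5,
  tolerance $10^{-10}$ $e\cdot$bohr on the maximum component change, and a
  500-iteration cap, failing loudly on non-convergence.

Agreement to $10^{-10}$ relative on random 60--100-site fixtures is part of
the test suite.  **Thole damping** of the dipole--dipole tensor (linear
scheme, per-pair smearing length $a(\alpha_l\alpha_m)^{1/6}$) is available
via `thole_a` but off by default: damping parameters are force-field
specific, and the undamped model is the reproducible baseline.  Damping is
applied only to the dipole--dipole tensor; the transition-charge source
fields are left bare.

## From couplings to observables

The instantaneous transfer rate folds the spectroscopic factors into the
Förster radius:

$$k(t) = V(t)^2\, \frac{3 n^4 R_0^6}{2\, \tau_D\, \mu_D^2\, \mu_A^2},$$

a combination that is dimensionless in atomic units apart from $1/\tau_D$,
so rates come out in ns$^{-1}$.  Feeding the *screened* point-dipole
coupling with $\kappa^2 = 2/3$ and $s = 1/n^2$ through this expression
reproduces $(R_0/R)^6/\tau_D$ to machine precision over a distance sweep --
the internal consistency check between the atomistic and spectroscopic
forms of the rate.  $R_0$ itself can be computed from
$R_0^6 = 8.79\times10^{-5}\, \kappa^2 n^{-4} \Phi_D J$ (Å$^6$, $J$ in
M$^{-1}$cm$^{-1}$nm$^4$) with `forster_radius()`, and $J$ from two-column
spectra with `spectral_overlap()` (trapezoidal quadrature on the union
grid, donor emission renormalized to unit area on the common support).

**Disorder averaging.**  Coupling fluctuations faster than the donor
fluorescence lifetime average *inside* the rate; slower fluctuations
produce a distribution of efficiencies.  `efficiency_distribution()`
implements the intermediate regime: the rate series is cut into
non-overlapping windows of duration `fast_window_ns` (default $\tau_D$ --
the natural separation scale, exposed because the choice is a convention,
with partial trailing windows dropped), the arithmetic mean rate in each
window gives a window efficiency
$E_w = \tau_D\langle k\rangle / (1 + \tau_D\langle k\rangle)$, and the
distribution collects all windows of all replicas with equal weight
(replica-length weighting is not applied; windows are the exchangeable
unit).  The limits behave as they must: a window spanning the whole series
gives the fully dynamic average, a one-frame window the fully static one.

The synthetic two-timescale generator makes this machinery testable: a
piecewise-constant slow coupling with additive zero-mean Gaussian fast
noise has an exactly computable intermediate-regime efficiency, because
Gaussian noise on the *coupling* shifts the expected window-mean of $V^2$
by exactly $\sigma^2$ (noise on the rate would not admit such a closed
form, which is why the generator perturbs the coupling).

**Distance bias.**  `distance_bias_analysis()` inverts window efficiencies
through the Förster relation, $R = R_0(1/E - 1)^{1/6}$, and compares the
resulting apparent distances with distances measured directly on the
ensemble.  Efficiencies of exactly 0 or 1 cannot be inverted and are
excluded with a reported count.  Samples of equal length are compared
pairwise (mean signed error, mean unsigned error, maximum deviation);
otherwise the summary compares distribution means and deciles.  The
fixed-distance, fluctuating-orientation fixture in the test suite shows
the qualitative signature that motivates the whole exercise: orientation
spread masquerades as distance spread under the Förster reading.

## Titration analysis

The experimental side processes quenching titrations of the donor
fluorescence at fixed emission wavelength:

1. **Inner-filter correction**
   $I_\mathrm{cor} = I \cdot 10^{(A_\mathrm{ex}+A_\mathrm{em})/2}$.
2. **Binding fit**: ordinary least squares of
   $\log_{10}\!\big[(I_D - I_{DA})/I_{DA}\big]$ against $\log_{10}[L]$;
   intercept $= \log_{10} K_b$, slope $=$ Hill coefficient $n$,
   $K_d = 1/K_b$.
3. **Fraction-bound correction**: each raw efficiency
   $E = 1 - I_{DA}/I_D$ is divided by the Hill fraction bound
   $f = [L]^n/(K_d^n + [L]^n)$, clipped to $[0,1]$ with a logged count,
   and averaged over concentrations.
4. **Site ranking**: $|E_\mathrm{exp} - E_\mathrm{site}|$ per candidate
   binding site, with sites beyond a configurable threshold (default 0.25)
   flagged as ruled out.

Two conventions deserve comment.  *Concentration units*: for $n \neq 1$
the numerical value of $1/K_b$ depends on the unit in which $[L]$ enters
the fit.  The package fits in micromolar, which keeps $K_d$ on the scale
of the titrated concentrations and keeps the downstream fraction-bound
correction numerically stable; the convention is stated in the fit report.
*Free-ligand approximation*: $[L]_\mathrm{free} \approx [L]_\mathrm{total}$
throughout, appropriate when the ligand is in excess of the protein (the
5 µM protein / 10--100 µM ligand design the generator mirrors).

The two titration generators are deliberately different models.
`loglinear` makes the quenching ratio an exact power law, so the log-log
fit inverts it to machine precision -- but that model implies complete
quenching of the bound complex.  `hill_quench` quenches the bound protein
fraction by a partial efficiency $E_\mathrm{true} < 1$; its quenching
ratio $e f/(1-ef)$ is *not* a power law, so the chained
fit-plus-correction estimate carries a small model bias (about $+0.03$ at
$E_\mathrm{true}=0.7$, $K_d=10$ µM, $n=1$ on the 10/50/100 µM design),
while correction with the generating isotherm recovers
$E_\mathrm{true}$ exactly.  The tests assert both facts separately rather
than pretending the chained estimator is unbiased.

## What the synthetic data do and do not establish

The generators emulate the *structure* of real inputs -- charge tables,
multi-frame ensembles, polarizability assignments, spectra, titrations --
with analytic ground truth, so every pipeline stage is validated against a
closed form or an independent brute-force computation.  They do not emulate
force-field geometries, realistic protein environments, correlated
orientation/distance dynamics, or photophysical artifacts (static
quenching, spectral drift).  Passing tests therefore establish that the
implementation computes its model correctly, not that the model describes
any particular protein; the latter is the job of the comparison with
measured efficiencies that the ranking module mediates.

Problem sizes used by the test and acceptance runs -- $10^6$ orientation
samples, 60--100 polarizable sites, 200-window trajectories of 100 frames,
200 noisy titration replicates -- were chosen as the smallest sets for
which the Monte-Carlo standard errors are far below the assertion
tolerances.

## Known limitations

* Only the environment-mediated *coupling* term is modelled; permanent
  environment charges, site-energy shifts, and exchange or charge-transfer
  contributions to the coupling are out of scope.
* No periodic-boundary treatment of the environment: the cutoff selection
  assumes an unwrapped frame.
* The two-state donor-quenching kinetics behind the efficiency formula
  ignore competing decay channels beyond FRET.
* Secondary binding mixes site populations in the measured efficiency; the
  ranking metric assumes a dominant single site and degrades gracefully
  (larger deviations) when that fails.
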