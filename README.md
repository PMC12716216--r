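# trespfret

Atomistic simulation of FRET observables for protein–ligand complexes, with
the titration analysis needed to compare them to fluorescence experiments.

## The problem

When a bound ligand quenches the fluorescence of a protein tryptophan by
Förster resonance energy transfer (FRET), the measured efficiency is
routinely converted into a donor–acceptor distance through

    E = 1 / (1 + (R/R0)^6)

This conversion assumes point transition dipoles, an isotropic orientation
factor (κ² = 2/3), and a constant dielectric screening s = 1/n². In a
binding pocket all three fail: the ligand's orientation is restricted, the
chromophores are not small compared to their separation, and screening
depends on the local environment. The result is systematically biased
distances and efficiency spreads that get misread as distance fluctuations.

`trespfret` computes the observables atomistically instead. Each
chromophore excitation is represented by **transition charges** (TrESP:
atom-centered charges fitted externally to the electrostatic potential of a
quantum-mechanical transition density); the environment is a **polarizable
model** in which every atom within a cutoff (default 15 Å) carries an
isotropic polarizability and acquires an induced dipole. Per frame of a
structural ensemble the package evaluates

    V       = V_Coul + V_env
    V_Coul  = Σ_ij  q_Di q_Aj / |r_i − r_j|
    V_env   = −Σ_l  μ_l · E_D(r_l),   μ_l = α_l (E_A(r_l) + Σ_m T_lm μ_m)
    s       = (V_Coul + V_env) / V_Coul
    k(t)    = V(t)² · 3 n⁴ R0⁶ / (2 τ_D μ_D² μ_A²)

together with the instantaneous κ², center distance R, and the unscreened
point-dipole coupling for ratio analyses. Rate trajectories become
disorder-resolved efficiency distributions by intermediate averaging
(fast fluctuations averaged within windows of the donor lifetime, slow ones
kept as a distribution), and efficiency distributions can be pushed back
through the Förster relation to quantify the distance bias. A titration
module (inner-filter correction, log–log Hill binding fit,
fraction-bound-corrected efficiencies, site ranking) produces the
experimental numbers the simulations are compared against.

Who it is for: anyone validating candidate binding sites/poses from MD
ensembles against tryptophan-quenching FRET data, or quantifying how far
Förster assumptions bend their distance estimates.

## Worked example

Two model chromophores (±q charge pairs, parallel transition dipoles,
centers 20 Å apart) with a handful of polarizable sites near the
inter-chromophore axis:

```r
library(trespfret)

fx    <- make_dipole_pair(mu_mag = 1, sep_ang = 1, r_ang = 20,
                          orientation = "parallel")
sites <- polarizable_sites(rbind(c(0.5, 0, 10), c(-0.5, 0.3, 11),
                                 c(0, -0.4, 9), c(0.8, 0.8, 12),
                                 c(-0.6, -0.7, 8)), alpha = 6)
rec <- coupling_record(fx$donor, fx$acceptor, sites = sites)
rec[, c("v_coul_cm", "v_env_cm", "v_total_cm", "s", "R_ang", "kappa2")]
#>   v_coul_cm v_env_cm v_total_cm     s R_ang kappa2
#> 1    4.0577   -0.138     3.9198 0.966    20      1
```

The Coulomb coupling is 4.06 cm⁻¹; the polarizable sites contribute an
opposing −0.14 cm⁻¹, i.e. the environment screens the interaction by
s = 0.966 — much weaker screening than the Förster factor 1/n² = 0.5.
Feeding the dressed coupling into the rate expression:

```r
p <- photophysics(tau_d_ns = 5, r0_ang = 25, n_refr = sqrt(2),
                  mu_d_mag = 1, mu_a_mag = 1)
k <- instantaneous_rate(rec$v_total, p)   # 4.256 ns^-1
e <- k * p$tau_d_ns / (1 + k * p$tau_d_ns)
invert_distance(e, r0 = 25)
#> [1] 15.02
```

The transfer efficiency is 0.955, and the Förster inversion reads it as an
apparent distance of 15.0 Å — 5 Å short of the true 20 Å separation,
because this geometry has κ² = 1 and s = 0.97 while the inversion assumes
2/3 and 0.5. That gap is exactly the bias the package is built to expose.

On the experimental side, a synthetic titration generated from the log–log
binding model is inverted exactly by the fitting pipeline:

```r
s   <- make_titration(kd_uM = 10, n_hill = 1, e_true = 1, model = "loglinear")
fit <- corrected_efficiency(s, hill_fit(s))
fit
#> Binding fit (synthetic-loglinear): Kd = 10 uM, n = 1.000, R^2 = 1.0000, E_final = 1.0000

compare_to_simulation(0.73, c(IIA = 1.00, IB = 0.25, IIIA = 0.41))
#>   site e_sim deviation ruled_out
#> 1  IIA  1.00      0.27      TRUE
#> 2 IIIA  0.41      0.32      TRUE
#> 3   IB  0.25      0.48      TRUE
```

The ranking table orders candidate binding sites by the deviation of their
simulated mean efficiency from the measured value (here 0.73), flagging
sites beyond the rule-out threshold (default 0.25).

A thin command-line wrapper over the same functions lives in
`inst/cli/trespfret` (subcommands `couple`, `efficiency`, `titrate`,
`rank-sites`, each driven by a YAML config).

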