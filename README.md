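# chainrelax

Analysis toolkit for the molecular mechanism of the **Debye relaxation** in
hydrogen-bonding liquids, built around methanol's transient hydrogen-bond
chains. Alcohols form short-lived chains of hydroxyl hydrogen bonds that
form, grow, shrink and die; the package dissects how that life cycle
carries the low-frequency dielectric response by post-processing molecular
dynamics trajectories driven by a small oscillating electric field — and by
generating synthetic ensembles with exactly known ground truth so every
analysis stage is testable without an MD engine.

It is aimed at simulators of polar liquids who want, from a trajectory:

- **Hydrogen-bond chains per frame** — geometric detection
  (H⋯O ≤ 2.6 Å, O–O ≤ 3.5 Å, O–H⋯O ≥ 140° by default, configurable) with a
  cell list verified exactly against brute force; connected components are
  chains, isolated molecules are "lone".
- **Chain life cycles** — identity tracking by maximal member overlap,
  classification of birth / addition / removal / death (plus merge, split
  and dissolution), and censored-exponential lifetime statistics with
  bootstrap intervals.
- **Field response** — any metric folded onto the field period
  ("cycle averaging") and fit to
  `⟨θ⟩ = A·sin(ωt) + B·cos(ωt) + C`: `A` is the in-phase (real) response,
  `B` the quadrature (imaginary) one; `|B|(ω)` peaks at `ωτ = 1` for a
  single relaxation process, and a joint Debye-form fit recovers `τ`.
- **Dielectric spectra** — the equilibrium route via the
  fluctuation–dissipation theorem,
  `χ(ω) = ⟨δP²⟩/(3ε₀VkBT) · [1 − iω∫₀^∞ Ĉ(t)e^{−iωt}dt]`,
  with multi-mode Debye fitting `Σk Δεk/(1+iωτk) + ε∞`; and the
  direct-field route `χ′ = A/(ε₀E₀V)`, `χ″ = −B/(ε₀E₀V)`, which must agree
  in the linear regime.
- **Synthetic generators** — a rotational-Brownian dipole ensemble with
  exact single-Debye truth `τ = 1/(2D_r)`, a kinetic Monte Carlo chain
  model whose chain and lone lifetimes are exponential *by construction*
  (means 2.2 ps and 0.3 ps by default, ≈20% lone molecules), and exact
  geometric fixtures.

Trajectory input: extended-XYZ (with declared per-atom charge/dipole
columns) and Tinker ARC. Units: Å, ps, e, e·Å, V/Å; frequencies in GHz.

## Worked example

Chain dynamics with known lifetime laws, run through the full tracker:

```r
library(chainrelax)

run <- generate_chain_kmc(n_molecules = 100, t_total = 40, seed = 1)
trk <- track_chains(run)
trk
#> <cr_tracking> 421 tracks, 4225 events over 4227 frames
#> addition    birth    death  removal
#>     1698      405      396     1726

cl <- chain_lifetimes(trk)
fit_lifetime_distribution(cl$duration, cl$censored)
#> <cr_lifetime_fit> mean 2.211 ps  95% CI [2.006, 2.443]  (n = 421, 25 censored)
#>   KS vs exponential: D = 0.04339 (p = 0.445)
```

The tracker recovered 396 deaths among 4225 events and the censored MLE
puts the mean chain lifetime at 2.21 ps with the generator's true value
(2.2 ps) inside the 95% CI; the KS statistic is consistent with the
exponential law the generator guarantees. The lone-molecule episodes behave
the same way (mean 0.303 ps vs truth 0.3 ps), and about 20% of molecules
are lone at any instant.

A driven dipole ensemble and its hydroxyl-angle response at 3.2 GHz (the
Debye peak of a 50-ps process sits at `1/(2πτ) = 3.18` GHz):

```r
fld <- cr_field(amplitude = 0.005, frequency_GHz = 3.2, frames_per_cycle = 50)
rot <- generate_rotor_ensemble(500, tau = 50, field = fld, n_cycles = 100,
                               seed = 42)
fit_sinusoid(cycle_average(rot$mean_theta, fld))
#> <cr_sinusoid_fit> at 3.2 GHz (n = 50, iid SEs)
#>   A = -0.7607  [-0.80653, -0.71488]
#>   B = +0.7774  [0.73157, 0.82323]
#>   offset = 89.912, residual RMS = 0.11
```

The mean hydroxyl angle oscillates about ~90° with in-phase and quadrature
amplitudes of equal magnitude — exactly what a single-Debye process does at
its loss peak (`|B|/|A| = ωτ ≈ 1`). Repeating across frequencies and
passing the fits to `response_spectrum()` recovers `τ` to within a few
percent.

A YAML-config pipeline (`validate_config()` / `run_pipeline()`) orchestrates
read → detect → chains → lifecycle → response/spectrum and writes TSV tables
plus a JSON report, each stamped with the config hash;
`inst/scripts/chainrelax.R` is a thin command-line wrapper with
`generate` / `detect` / `lifecycle` / `respond` / `spectrum` / `all`
subcommands.

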