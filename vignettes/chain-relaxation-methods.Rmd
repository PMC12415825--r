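---
title: "Methods: hydrogen-bond chain dynamics and the Debye relaxation"
author: "chainrelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond chain dynamics and the Debye relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainrelax)
```

## The problem this package addresses

Primary alcohols such as methanol owe their large static dielectric constant
to the Debye peak, the lowest-frequency feature of their dielectric loss
spectrum. The prevailing molecular picture — the *transient chain model* —
holds that alcohol molecules form short-lived, possibly branched chains of
hydrogen bonds through their hydroxyl groups: chains continually form when
two lone molecules bond, grow by molecular addition, shrink by removal, and
die when the final pair dissociates. Which part of this life cycle carries
the Debye-scale polarization response is a mechanistic question that can be
answered in simulation by applying a small oscillating electric field and
watching, frequency by frequency, how hydroxyl orientations, chain
populations, and life-cycle events ride the field cycle.

`chainrelax` implements the analysis side of that program as reusable,
testable components:

1. **Trajectory layer** (`read_trajectory`, `box_polarization`,
   `bond_angle_to_axis`): extended-XYZ / Tinker ARC input, the box dipole
   $P_\alpha(t) = \sum_i [\,q_i \alpha_i(t) + \mu^{sta}_{i\alpha} +
   \mu^{ind}_{i\alpha}(t)\,]$ of a polarizable force field, and bond angles
   to the field axis under the minimum-image convention.
2. **Hydrogen-bond chains** (`detect_hbonds`, `find_chains`,
   `chain_census`): geometric bond detection and partition of each frame
   into chains and lone molecules.
3. **Life cycle** (`track_chains`, `fit_lifetime_distribution`,
   `lone_intervals`): chain identity through time, event classification,
   and censored exponential lifetime statistics.
4. **Field response** (`cycle_average`, `fit_sinusoid`,
   `response_spectrum`, `split_counts_by_angle`,
   `proportion_vs_population_test`, `event_orientation_change`): folding any
   metric onto the field cycle and fitting
   $\langle\theta\rangle_{cyc} = A\sin\omega t + B\cos\omega t + C$.
5. **Dielectric spectrum** (`polarization_autocorrelation`, `fdt_spectrum`,
   `fit_relaxation_modes`, `susceptibility_from_direct_field`): the
   equilibrium (fluctuation–dissipation) route to $\chi(\omega)$ and the
   direct-field route, which must agree in the linear regime.
6. **Synthetic generators** (`generate_rotor_ensemble`,
   `generate_chain_kmc`, `generate_fixture`): seed-deterministic stand-ins
   for molecular dynamics with exactly known ground truth, so that every
   stage above is testable without an MD engine.

Units throughout: Angstrom, ps, elementary charge e, dipoles in e·Å, fields
in V/Å, energies in eV, user-facing frequencies in GHz (converted once to
rad/ps; 1 ps⁻¹ = 1000 GHz).

## Hydrogen-bond definition

A donor molecule *d* is bonded to an acceptor *a* when

* dist(H\_d, O\_a) ≤ `r_HO_max` (default **2.6 Å**),
* dist(O\_d, O\_a) ≤ `r_OO_max` (default **3.5 Å**),
* the O\_d–H\_d⋯O\_a angle at the hydrogen ≥ `angle_min` (default **140°**).

The defaults follow common geometric criteria for alcohol hydrogen bonds;
they are configurable, and all pipeline outputs echo the criteria used. A
hydroxyl can donate one bond and an oxygen's two lone pairs can accept two,
so the graph has degree ≤ 3; when a donor satisfies the criteria with
several acceptors the geometrically best one (smallest H⋯O distance, then
lowest molecule id) is kept, and an oxygen claimed by more than two donors
keeps its two best donors by the same ordering. Dropped donors are not
reassigned to their next-best acceptor; with physical geometries this case
is already rare, and the deterministic rule keeps detection reproducible.
Distances use the minimum image in an orthorhombic box (triclinic cells are
rejected), and `r_OO_max` must not exceed half the smallest box edge. The
cell-list and all-pairs detectors are required by the test suite to agree
*exactly*.

Connected components of size ≥ 2 are chains; branched components count as
single chains; isolated molecules are lone. The partition property
(chain members + lone set = all molecules) is asserted, not assumed.

## Chain identity and life-cycle events

A chain at frame *t+1* continues the track of the frame-*t* component with
which it shares the largest member overlap (ties resolved to the lowest
track id). Against that identity rule the tracker classifies:

* **birth** — a new two-molecule component whose members were both lone;
* **death** — a track whose final pair dissociates into two lone molecules;
* **addition / removal** — molecules entering from or leaving to the lone
  pool (and chain→chain hops, recorded as a removal plus an addition);
* **merge / split** — coalescence or fission of multi-molecule components.
  These are deliberately distinct event types, excluded from birth/death
  statistics, because forcing them into births and deaths would distort
  lifetime laws;
* **dissolution / emergence** — a component of more than two molecules
  vanishing into (or appearing from) the lone pool in a single frame step,
  flagged rather than silently coerced.

A track may end sharing no molecule with its initial pair. There is no
transient-gap tolerance: a bond absent for one frame breaks continuity.
Lifetimes are differences of frame timestamps; with event-synchronous
synthetic frames they are exact, and with uniform sampling they carry the
usual ±half-frame discretization.

**Lifetime estimation.** The exponential MLE under right-censoring is
`mean = total observed time / number of uncensored endings`; the CI is a
percentile bootstrap over episodes, and a Kolmogorov–Smirnov statistic
against the fitted exponential is reported as a diagnostic (with the rate
estimated from the same data it is conservative). Episodes already in
progress at the start of the observation window are kept as ordinary
episodes: for an exponential law the residual life has the same
distribution, so this introduces no bias. Episodes still open at the end
are censored.

## Cycle averaging and the (A, B) response

With the field $E(t) = E_0 \sin(\omega t)\,\hat z$ and the phase origin at a
zero-crossing going positive (fixed by simulation bookkeeping, never by
fitting), a metric sampled `frames_per_cycle` times per period is folded by
averaging the *i*-th frame of every cycle. The average cycle is fit by
ordinary least squares on the $\{\sin\omega t, \cos\omega t, 1\}$ basis. The
constant term is deliberate: bond-angle series oscillate about a ~90°
baseline, which would otherwise leak into $A$ and $B$. Because the signs of
$A$ and $B$ flip with the bond-vector convention (OH vs HO), magnitudes
$|A|$ and $|B|$ are reported alongside the signed values. The fit is exact
on noiseless sinusoids (machine precision), and for a single relaxation
process $|A|(\omega)$ is sigmoidal while $|B|(\omega)$ peaks at
$\omega\tau = 1$; `response_spectrum` fits both jointly to recover
$\tau$ and the amplitude.

**Uncertainty of (A, B).** Three standard-error methods are provided:

* `"iid"` — classical OLS errors, correct when phase-point noise is
  independent (e.g. white measurement noise);
* `"hac"` — Newey–West errors for mildly correlated residuals;
* `"cycles"` — each block of consecutive cycles is fit separately and a
  t-interval is taken over the block estimates (the point estimate is
  unchanged). This is the method of choice when folding *equilibrium*
  fluctuations, whose correlation time $\tau$ spans several phase points:
  blocks longer than the correlation time restore calibrated intervals.

A note on power that recurs below: the per-cycle scatter of the box dipole
is set by $\langle\delta M_z^2\rangle = N\mu^2/3$ regardless of frequency,
while the response amplitude falls off as $|\chi| \propto
1/\sqrt{1+\omega^2\tau^2}$. The relative error of a susceptibility point at
fixed cycle count therefore grows past the Debye peak, and checks that need
a few-percent point error must scale cycles as $1+\omega^2\tau^2$.

## Dielectric spectrum: two routes

**FDT route** (field-free): with mean-removed autocorrelation
$C(t) = \langle \delta P(0)\,\delta P(t)\rangle$ and $\hat C = C/C(0)$,

$$\chi(\omega) = \frac{\langle \delta P^2\rangle}{3\,\epsilon_0 V k_B T}
\left[ 1 - i\omega \int_0^\infty \hat C(t)\, e^{-i\omega t} dt \right],$$

with the factor 3 for the isotropic (vector) correlation and omitted for a
single Cartesian component. This is the classical linear-response form with
no polarizable-force-field quantum corrections; absolute calibration of the
static constant is explicitly out of scope. Numerical choices: the
autocorrelation is FFT-based and unbiased per lag; the one-sided transform
integrates the piecewise-linear interpolant of $\hat C$ exactly per segment
(Filon-type), so its accuracy is set by how well the sampling resolves
$C(t)$, not by $\omega\,\Delta t$; the frequency grid (default log-spaced
0.05–500 GHz) is capped at the Nyquist limit $\pi/\Delta t$ of the
correlation sampling; the default maximum lag is 10% of the series, but for
spectra a window of ~5–6 correlation times is better — beyond that the
integrand is pure noise, and the point error grows with the square root of
the window length. A non-decayed correlation at the window end triggers a
truncation-bias warning.

**Direct route** (in-field): from the $(A, B)$ fit of $P_z$,
$\chi' = A/(\epsilon_0 E_0 V)$ and $\chi'' = -B/(\epsilon_0 E_0 V)$ (the
sign convention makes loss positive). In the linear regime the two routes
must agree; the package's acceptance suite verifies this on the rotor
ensemble within 10% at three frequencies around the peak, with run lengths
sized by the power argument above (500/800/2000 cycles at 1.6/3.2/6.4 GHz
for ~3% point errors, and a 400-ns field-free run for a ≤4% FDT error).

`fit_relaxation_modes` fits $\sum_k \Delta\epsilon_k/(1+i\omega\tau_k) +
\epsilon_\infty$ to the complex spectrum by Levenberg–Marquardt on
log-amplitude/log-time parameters, with multi-start initialization from the
loss peaks and from a log-spaced ladder; the slowest mode is reported as
$\tau_D$. Fitted modes are Kramers–Kronig consistent by construction, which
the tests exploit by reconstructing the real part from the fitted modes.

## The synthetic generators, and what they do not emulate

**Rotor ensemble** — $N$ independent rigid dipoles undergoing overdamped
rotational diffusion on the sphere (Euler–Maruyama with tangent-projected
noise and renormalization; substep chosen so $D_r\,\Delta t \le 0.01$ by
default, and an explicit unstable substep is refused) with torque drift
$({\mu D_r}/{k_B T})\,(\vec E - (\vec u\cdot\vec E)\,\vec u)$. Ground truth:
isotropic equilibrium at $E_0=0$, Boltzmann orientation statistics in a
static field, and a single-Debye susceptibility with $\tau = 1/(2D_r)$ and
$\chi_0 = N\mu^2/(3\epsilon_0 V k_B T)$. Defaults are methanol-scaled
(μ = 0.35 e·Å ≈ 1.7 D, number density 0.0149 Å⁻³, 300 K) and the default
field amplitude used in the acceptance runs (0.005 V/Å) keeps
$\mu E_0/k_B T \approx 0.07$, inside the linear-response design bound of
0.1. What it does not emulate: any interaction between molecules — there is
no collective dynamics, no hydrogen bonding, no α process. It validates the
response and spectrum machinery, not chain physics.

**Chain KMC** — a continuous-time Markov model of the chain life cycle with
two episode laws that hold *exactly*, so lifetime estimators can be tested
against known truth:

* every lone molecule exits the lone pool with total hazard $1/\tau_{lone}$
  (a self-exit hazard $\lambda = (1/\tau_{lone})/(1+p_{birth})$ plus a
  partner-grab hazard $\lambda\,p_{birth}$ that is state-independent because
  birth partners are drawn uniformly from the other lone molecules), making
  lone episodes Exp($\tau_{lone}$) by memorylessness;
* every chain carries a constant death hazard $1/\tau_{chain}$ from birth at
  any size, making chain lifetimes Exp($\tau_{chain}$). When death strikes a
  chain of size $s>2$, the generator emits $s-2$ removal events at
  ε-spaced timestamps (ε = 10⁻⁶ ps) immediately before the pair death, so
  every logged event stays canonical (birth/addition/removal/death).

Defaults: $\tau_{chain} = 2.2$ ps, $\tau_{lone} = 0.3$ ps, and
$p_{birth} = 0.2$, churn rate 2 ps⁻¹, chosen once so the stationary lone
fraction is ≈ 20% of molecules with mean chain size ≈ 3.5 — the population
structure the transient-chain picture describes. Frames are
event-synchronous by default (one frame per event, stamped at the event
time), which makes tracker-vs-log comparisons and episode durations exact;
a uniform-grid sampling mode exists for discretization studies. Geometry is
realized on demand: chains lie on straight lines with 2.8 Å O–O spacing and
donors pointing at the next oxygen, components separated by 6 Å, so the
default criteria recover the KMC bond graph with ≥ 0.4 Å / 40° margins.
What it does not emulate: spatial diffusion (components are re-laid per
frame), branched chains (linear only — branching is exercised by the
fixture generator), merges and splits (never generated, though the tracker
classifies them), and any energetics. Passing tests on KMC data show the
bookkeeping is exact; they say nothing about whether real methanol's events
are captured by a geometric bond criterion.

**Fixtures** — explicit placements realizing prescribed topologies (linear
chains, a branched 4-molecule star, lone molecules) with no knife-edge
distances, used for exactness tests of the detector and partitioner.

## Statistical design of the study-condition checks

The test suite's acceptance file runs the whole pipeline at a documented
desk scale: rotor ensembles of 500 dipoles with $\tau = 50$ ps (so the peak
sits at $1/(2\pi\tau) = 3.18$ GHz) sampled at 50 frames/cycle over 100
cycles at six frequencies (0.8–25.6 GHz, log-2 spaced around the peak); a
400-ns field-free run for the FDT spectrum; KMC runs of 200 molecules out
to 240 ps (≈ 5×10³ chain lifetimes, ≈ 3×10⁴ lone episodes). Two
multiplicity decisions are worth recording. First, the null-honesty check
(field-free $A$ and $B$ statistically zero at three folding frequencies)
tests a *family* of six intervals; each interval is Bonferroni-corrected so
the family-wise level stays at 95% — uncorrected per-interval tests would
fail a quarter of well-calibrated runs by construction. Second, the same
correction is applied across phase bins when checking that uniformly drawn
events show zero excess over the population. Folding equilibrium
fluctuations yields serially correlated phase noise, so these checks use
the blocked-cycle intervals with blocks of at least $3\tau$ of simulated
time.

## Known limitations

* Orthorhombic boxes only; no triclinic support.
* The geometric bond definition has no energetic or orbital component.
* The tracker's overlap rule is the standard choice but not the only one; a
  shared-edge identity would differ when a chain's membership changes
  wholesale in one frame. With event-synchronous or fast-sampled input the
  two coincide.
* Lifetime statistics assume the frame rate resolves the kinetics; there is
  no transient-gap tolerance in this version.
* The FDT prefactor uses the classical fluctuation formula; comparisons to
  experimental static dielectric constants are out of scope.
* Hydrogen-bond autocorrelation (intermittent/continuous) kinetics are
  deliberately not implemented; lifetimes here are episode-based.

## A small worked example

```{r example, eval = FALSE}
library(chainrelax)

# chain dynamics with known lifetime laws, tracked through the full pipeline
run <- generate_chain_kmc(n_molecules = 100, t_total = 40, seed = 1)
trk <- track_chains(run)
cl  <- chain_lifetimes(trk)
fit_lifetime_distribution(cl$duration, cl$censored)

# a driven rotor ensemble and its in-phase/quadrature hydroxyl response
fld <- cr_field(amplitude = 0.005, frequency_GHz = 3.2, frames_per_cycle = 50)
rot <- generate_rotor_ensemble(500, tau = 50, field = fld, n_cycles = 100,
                               seed = 42)
fit_sinusoid(cycle_average(rot$mean_theta, fld))
```
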