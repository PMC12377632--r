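---
title: "Model and methods: tethered DNA in shear flow with a crowding attraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: tethered DNA in shear flow with a crowding attraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tetherflow)
```

## The physical problem

In a single-molecule flow-stretching assay, a lambda-DNA molecule
(contour length $L = 16.49\,\mu\mathrm{m}$) is tethered by one end to the
lower wall of a shallow microfluidic channel and stretched by laminar
shear flow; the free end carries a quantum dot whose position is tracked.
Supplementing the buffer with polyethylene glycol (PEG) has two opposing
effects: it raises the buffer viscosity (more drag, more stretching) and
it induces a depletion attraction between DNA segments (compaction, less
stretching and smaller fluctuations).  `tetherflow` implements a
Brownian-dynamics model that separates the two effects and a calibration
pipeline that connects the dimensionless simulation to the measured
viscosities and extensions.

## The model

The DNA is a bead--spring chain of $N+1$ beads joined by $N$ stiff
harmonic springs of equilibrium length $a$ ($a = L/N = 330\,$nm for
$N = 50$).  Bead 0 is clamped at $(0, 0, a)$; this is the simplest
reading of a chain "attached" near the wall, and the clamp force is
reported but never applied.  All quantities are reduced: lengths by $a$,
energies by $k_BT$, forces by $k_BT/a$, and times by
$\tau_0 = \zeta a^2 / k_BT$, the diffusion time of one free bead over one
bond length.  The drag coefficient $\zeta$ and temperature never appear
individually.

Forces on bead $n$:

* **Springs** $-k_s(\ell - 1)\hat r$ along each adjacent bond, with
  $k_s = 1000\,k_BT/a^2$.  The springs are stiff enough that the chain is
  effectively inextensible (bond-length SD $\approx k_s^{-1/2} \approx
  0.03$), yet compatible with an explicit integrator at
  $\Delta t = 10^{-4}\tau_0$ (the constructor rejects
  $k_s\,\Delta t > 0.5$).
* **Soft wall** at $z = 0$:
  $F_z = \tfrac{6\varepsilon}{a}\big[(a/z)^7 - (a/z)^4\big]$ for
  $0 < z \le a$ and zero above, with $\varepsilon = k_BT$; purely
  repulsive and continuous at $z = a$.  Only this wall is modelled: the
  chain never reaches the far wall of the channel.  The wall *energy*
  used by the gradient tests is the antiderivative with $U(a) = 0$,
  $U(z) = \varepsilon[(a/z)^6 - 2(a/z)^3 + 1]$.
* **Crowding (PEG) attraction**: pair energy
  $\Delta G(r) = -\alpha\,[\mathrm{PEG}]\,e^{-r/D}$ between beads with
  contour separation $1 \le |n - n'| \le 5$, giving a pair force of
  magnitude $(\alpha [\mathrm{PEG}]/D)\, e^{-r/D}$ pulling the beads
  together.  $[\mathrm{PEG}]$ enters as the bare percent number (3, 5).
  The exponential form mirrors the phenomenology of hydrophobic
  attraction; $D$ is of order the bond length, and the cutoff at five
  contour neighbours is adequate because stretched conformations keep
  distant segments far apart.  Electrostatics, excluded volume, bending
  stiffness and hydrodynamic interactions are deliberately absent (high
  salt, free-draining chain).

The overdamped Langevin equation is integrated by the explicit
Euler--Maruyama scheme

$$ r_n(i{+}1) = r_n(i) + (F^{el}_n + F^{s}_n + F^{PEG}_n
   + \mathrm{Pe}\, z_n\, \hat x)\,\Delta t + f^B_n, $$

with Gaussian impulses of zero mean and variance $2\Delta t$ per bead per
axis and the shear drift $\mathrm{Pe}\,z$ along the flow.  The shear rate
is constant in $z$: the free end stays within $\sim 0.2\%$ of the channel
height, so the parabolic correction $2z/h$ of the full Poiseuille profile
(available in `flow_profile()`/`shear_rate()`) is negligible and the
integrator never uses it.  No higher-order scheme is offered; matching
the plain Euler--Maruyama numerics is part of the model definition.

## Dimensionless numbers and the calibration chain

The per-bead flow strength is the Péclet number
$\mathrm{Pe} = \dot\gamma\,\tau_0$; the chain-level strength is the
Weissenberg number $\mathrm{Wi} = \dot\gamma\,\tau_R =
\mathrm{Pe}\,\tilde\tau_R$ with $\tilde\tau_R$ the reduced longest
relaxation time.  `estimate_relaxation_time()` measures $\tilde\tau_R$
two ways at $\mathrm{Pe} = 0$, $\alpha = 0$: the decay of the
equilibrium autocorrelation $C(t') = \langle \rho(t)\cdot\rho(t+t')
\rangle$ of the planar end vector $\rho = (x, y)$, and the decay of
$\langle \rho(t)\rangle$ from a fully $x$-extended start.  Both are
fitted by unweighted linear-scale least squares to $A e^{-t/\tau}$ on the
lag window $[200, 2000]\,\tau_0$ and averaged.  For the default chain the
package obtains $\tilde\tau_R \approx 333$, consistent with the tethered
Rouse estimate $4N^2/(3\pi^2) \approx 338$.  Downstream code treats
$\tilde\tau_R$ as an input (default 333) so the expensive estimate runs
once.

At high salt $\tau_R \propto \eta$, so $\mathrm{Wi} = c'\eta$ with a
single constant $c'$.  The pipeline of `calibrate_pipeline()`:

1. **`calibrate_cprime()`** simulates the fractional extension
   $\xi = \langle x\rangle / L$ at $\alpha = 0$ on a log-spaced Wi grid,
   interpolates monotonically (Hyman-filtered spline in $\log
   \mathrm{Wi}$), solves $\xi(\mathrm{Wi}_0) = \xi_{exp}(0\%)$ and returns
   $c' = \mathrm{Wi}_0 / \eta_0$.
2. **`calibrate_alpha()`** fixes $\mathrm{Wi}_1 = c'\eta_1$ (3% PEG) and
   solves $\xi(\mathrm{Wi}_1; \alpha, D) = \xi_{exp}(3\%)$ for $\alpha$
   at each decay length ($D = a$ and $D = a/2$ are both run, to show the
   fitted attraction is robust against the choice of $D$).
3. **`predict_condition()`** simulates the 5% condition at
   $\mathrm{Wi}_2 = c'\eta_2$ with the already-fitted $\alpha$ — no
   adjustable parameters — and converts to micrometres via
   $\langle x\rangle = \xi L$ and $\Delta x = \phi R_e$, where $\phi$ is
   the reduced end fluctuation normalised by the equilibrium end-to-end
   distance $R_e$ ($\sqrt{N}\,a$ for the model chain;
   $\sqrt{L b_K} = 1.284\,\mu\mathrm{m}$ for the experimental DNA, from
   Kuhn length $b_K = 2\ell_P = 0.1\,\mu\mathrm{m}$).

## Numerical choices

* **RNG.** The integrator consumes $3N$ Gaussian draws per $10^{-4}\tau_0$
  step, so the noise generator dominates the run time.  The engine uses a
  dedicated xoshiro256++ stream (seeded per run) with a 128-level
  ziggurat normal sampler; the draw stream is a pure function of the seed
  and is validated by moment tests and the free-diffusion $2t$ law.
* **Equilibrium initial states.** Starting equilibrium runs from a
  stretched conformation would require several relaxation times of
  burn-in ($\langle x \rangle = N e^{-t/\tilde\tau_R}$ decays slowly and
  biases $C(t')$ upward).  `sample_coil_state()` instead draws a
  freely-jointed coil (exact equilibrium for the in-plane coordinates,
  heights reflected at the wall), after which $\sim 150\,\tau_0$ of
  burn-in relaxes bond lengths and the near-wall height profile.
  Sheared steady-state runs start from the fully extended conformation,
  which is close to the stretched steady state at the Weissenberg numbers
  of interest; low-Wi grid points get a longer burn-in
  (`grid_burn_in_low`) because there the steady state is coil-like and
  the decay from the stretched start is slow.
* **Variance reduction for the relaxation time.** A single-exponential
  fit to the empirical $C(t')$ is statistically fragile: the sampling
  error of an autocorrelation is quadratic in the signal, coherent
  across lags, and dominated by the slowest mode, so the fitted
  $\tau$ from a few $10^4\,\tau_0$ of equilibrium data scatters by tens
  of percent.  `estimate_relaxation_time()` therefore applies two
  classical variance-reduction devices, both optional and both leaving
  the estimators' definitions untouched.  (i) *Control variate for
  $C(t')$*: alongside each equilibrium replica, a rest-length-0
  harmonic ("Gaussian") chain with spring constant $3\,k_BT/a^2$ —
  matching the real chain's unit mean-square bond length and, nearly,
  its slowest relaxation — is integrated with the *same* impulse
  stream.  Its autocorrelation is known exactly (linear OU modes), so
  its empirical-minus-exact difference is an unbiased estimate of the
  sampling error, which is subtracted from the real chain's estimate.
  Because the two error processes are driven by the same noise they are
  strongly correlated, and the subtraction cuts the fitted-$\tau$
  standard error several-fold at equal cost.  (ii) *Antithetic pairs
  for $\langle \rho(t)\rangle$*: relaxation replicas come in pairs with
  mirrored impulse streams.  The fluctuation of the decaying mean is
  almost linear in the noise, so the pair average cancels it nearly
  completely (observed: about two orders of magnitude in variance),
  leaving a smooth decay curve from a handful of pairs.
* **Exponential fits.** The amplitude is linear in the model, so it is
  profiled out exactly and $\tau$ found by 1-D minimisation — ordinary
  least squares on the linear scale with no convergence failures, exactly
  reproducing noiseless inputs.
* **The shallow $\alpha$ objective.** At the 3%-PEG condition
  $d\xi/d\alpha \approx -0.02\ldots{-0.03}$ per $k_BT$, so a naive
  Monte-Carlo estimate of $\xi(\alpha)$ would need very long runs before
  its error, divided by that slope, resolves $\alpha$ at all.
  `calibrate_alpha()` therefore bisects on a control-variate objective
  with common random numbers: a single long $\alpha = 0$ baseline fixes
  the level, and paired runs with *identical* noise streams measure the
  attraction-induced shift $\xi(\alpha) - \xi(0)$, whose sampling error
  is several-fold smaller than that of either run alone because the
  paired trajectories are strongly coupled.  Given the seeds the
  objective is deterministic and decreasing in $\alpha$ (asserted during
  bisection); the bisection stops at a bracket of $0.02\,k_BT$, well
  below the statistical uncertainty of the fit.
* **Degenerate inputs.** Coincident beads (undefined unit vectors) and
  beads reaching `z_floor` $= 10^{-3}$ (diverging wall force, a
  stability failure) abort with the offending bond/bead named; with
  $k_s = 1000$ neither occurs in practice.
* **Monotone grid.** $\xi(\mathrm{Wi})$ grid means can wiggle by
  Monte-Carlo noise; inversions below `mono_tol` (0.015) are projected
  onto the nearest monotone curve by isotonic regression before the
  spline, larger ones abort with a request for more replicas.

## Run sizes

The defaults in `relaxation_protocol()` and `calibration_protocol()` are
the package's standard compromise between Monte-Carlo error and runtime
on a single core: 6 equilibrium replicas of $4000\,\tau_0$ production
(with paired surrogates) plus 4 antithetic relaxation pairs of
$2050\,\tau_0$ for $\tilde\tau_R$ — roughly $\pm 10\%$ statistical
error on the autocorrelation estimate, well under $1\%$ on the
relaxation-decay estimate, hence about $\pm 5\%$ on their average; a
7-point Wi grid in $[2, 120]$ with 2 replicas and $1600\,\tau_0$
production each for the $c'$ inversion (grid-point $\xi$ errors
$\approx 0.006$, hence $c'$ errors of a few percent after monotone
interpolation); a $9000\,\tau_0$ baseline and common-random-number
paired runs of $700\,\tau_0$ production per bisection step for
$\alpha$.  Every protocol is a plain list argument, so larger studies
simply pass bigger numbers; seeds for every replica are derived
deterministically from the user seed and recorded.

## What the synthetic traces do and do not emulate

`generate_synthetic_traces()` produces quantum-dot-like position traces:
a flow-off segment fluctuating around the tether, a flow-on segment
following a stationary Gaussian mean-reverting (Ornstein--Uhlenbeck)
process around a molecule-specific mean, molecule-level heterogeneity as
a Gaussian offset of that mean, frame interval 0.1 s (the camera
exposure), and iid localization noise.  This is the *simplest* process
matching the statistics the analysis consumes (mean, SD, a correlation
time) — it contains no cyclic-dynamics intermittency, no drift, no
blinking, no tracking outliers.  Tests passing on these fixtures
validate the estimators' arithmetic and convergence rates, not the
photophysics of real traces.

## Known limitations

* Free-draining dynamics: no hydrodynamic coupling between beads, as in
  the model the package implements; absolute time scales inherit that
  approximation.
* The crowding attraction is phenomenological (exponential pair law,
  amplitude linear in concentration); $\alpha$ is meaningful only
  jointly with $D$.
* Steady-state summaries assume the production span covers many
  correlation times of the end position; at very low Wi the
  fluctuations are slow and the replica-scatter SE reported alongside
  every summary should be checked before trusting $\xi$ there.
* The quantitative characterisation of cyclic dynamics (recirculation at
  moderate Wi) is out of scope; trajectories can be exported and
  inspected, nothing more.
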