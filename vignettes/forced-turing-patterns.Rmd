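---
title: "Turing patterns under a periodically forced feed: models and numerics"
author: "turingforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turing patterns under a periodically forced feed: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package studies the two-variable Lengyel–Epstein description of the
chlorite–iodide–malonic acid (CIMA) reaction, the classic chemical
realization of Turing's diffusion-driven instability, when the feed of the
malonic acid is modulated sinusoidally in time.  In dimensionless form the
fields are the activator (iodide) concentration $u(x, y, t)$ and the
inhibitor (chlorite) concentration $v(x, y, t)$ on a periodic square
domain:

$$
\partial_t u = a + A\sin\!\frac{2\pi t}{T} - u - \frac{4uv}{1+u^2}
  + \nabla^2 u,
\qquad
\partial_t v = \sigma\!\left(b\Big(u - \frac{uv}{1+u^2}\Big)
  + c\,\nabla^2 v\right).
$$

* `a` — feed parameter tied to the malonic-acid supply; the experimental
  control knob.  The sinusoidal term (amplitude `A`, period `T`) models a
  periodically modulated feed; `A = 0` recovers the autonomous model.
* `b` — feed parameter tied to the iodine supply.
* `sigma` ($\sigma = 1 + K$) — rescaling from the reversible
  iodide–iodine–starch complexation, which slows the effective diffusion
  and kinetics of the activator.  $\sigma \ge 1$.
* `c` ($= D_Y / D_X$) — inhibitor-to-activator diffusivity ratio.  Note
  that the whole second equation carries $\sigma$, so the inhibitor's
  effective diffusion coefficient is $\sigma c$.

Throughout, the reference parameter set is $\sigma = 8$, $b = 1.9$,
$c = 1.5$, with `a` varied.  The unforced homogeneous steady state is
$u^* = a/5$, $v^* = 1 + a^2/25$, an exact zero of the kinetics for every
$a > 0$.

The kinetics are evaluated exactly as written also for (transiently)
negative concentrations; the solver monitors finiteness but does not clamp.
Clamping would silently alter the dynamics, and under all protocols
exercised in the tests the fields remain positive after the initial noisy
transient.

## From tank chemistry to dimensionless parameters

`cima_rate_constants()` carries the rate laws of the skeleton CIMA
mechanism ($k_{1a} = 7.5\times10^{-3}\,\mathrm{s^{-1}}$,
$k_{1b} = 5\times10^{-5}\,\mathrm{M}$,
$k_2 = 6\times10^{3}\,\mathrm{M^{-1}s^{-1}}$,
$k_3 = 2.65\times10^{-3}\,\mathrm{s^{-1}}$,
$\alpha = 10^{-14}\,\mathrm{M^2}$).  Two intermediates must be estimated
from the feeds because they are not supplied directly:

* chlorite radical: with iodine present, the fast chlorite–iodine
  equilibrium gives $[\mathrm{ClO_2^\cdot}] = 0.2\,[\mathrm{ClO_2^-}]$;
* iodine: formed from iodide with iodate in excess at $3/5$ stoichiometry
  and consumed by the chlorite–iodine reaction at
  $\tfrac16[\mathrm{ClO_2^\cdot}]$.

With the standard feed composition (10 mM chlorite, 2 mM iodide) this
yields $[\mathrm{ClO_2^\cdot}] = 2\times10^{-3}$ M,
$[\mathrm{I_2}] \approx 8.7\times10^{-4}$ M, an effective
$k_1 = k_{1a}[\mathrm{I_2}]/(k_{1b} + [\mathrm{I_2}])$, and finally

$$
a = \frac{k_1 [\mathrm{MA}]_0}{k_2 [\mathrm{ClO_2^\cdot}]_0 \sqrt\alpha}
  \approx 5.9\times10^{3}\,[\mathrm{MA}]_0,
\qquad
b = \frac{k_3 [\mathrm{I_2}]_0}{k_2 [\mathrm{ClO_2^\cdot}]_0 \sqrt\alpha}
  \approx 1.9 .
$$

All operations return full precision; the published value $b = 1.9$ rests
on intermediate concentrations rounded to two digits, so comparisons use a
$\pm 0.05$ band that covers both the rounded and unrounded chains.  The
excess-iodate assumption is taken as valid for all user inputs — the
package deliberately implements the fixed stoichiometric fractions, not an
equilibrium speciation solver.

## The stirred-tank forcing model

The modulated pump feeds malonic acid stock (concentration
$[\mathrm{MA}]_s$) at rate $q_1(t) = q_0 + A_q \sin(2\pi t/T)$ into a tank
of volume $V$ that is also fed by a constant co-flow $q_2$, giving the
linear mixing equation

$$
\frac{d[\mathrm{MA}]_0}{dt} = [\mathrm{MA}]_s \frac{q_1(t)}{V}
  - [\mathrm{MA}]_0\,\frac{q_1(t) + q_2}{V}.
$$

Units: minutes and mL/min internally, mL/h at the interface (matching how
pump rates are usually quoted, e.g. $q_2 = 499$ mL/h, $V = 26$ mL, giving
residence times of 2–3 min).  The ODE is linear and non-stiff, so a
fixed-step classical fourth-order Runge–Kutta scheme at 0.01 min suffices;
a step-halving check in the test suite bounds the error below
$10^{-8}$ M, and `deSolve::lsoda` serves as an independent cross-check.

`symmetric_modulation_design()` finds $(q_0, A_q)$ so that the long-run
extremes of $[\mathrm{MA}]_0(t)$ straddle a requested basis value
symmetrically.  Because the tank damps and distorts the sinusoid (gain
roughly $1/\sqrt{1 + (2\pi\tau/T)^2}$ with $\tau = V/(q_0+q_2)$), the
design runs a damped Newton iteration on the *simulated* trajectory rather
than inverting the quasi-static map; requests that would need a negative
inflow fail with the achievable range.  A genuine consequence of the
multiplicative $q_1(t)$ term is rectification: the long-run mean sits
slightly above the centre of the modulation (ranging from $\sim$0.1% at
moderate settings to above 1% at deep modulation in our simulations).
The tests assert the sign of this effect, not a particular magnitude,
since the design tolerance (0.5% of the basis) is of the same order at
moderate settings.

## Linear stability of the unforced model

Linearizing about $(u^*, v^*)$ and diagonalizing in Fourier modes gives
the $2\times2$ matrix $M(k) = J - \mathrm{diag}(k^2, \sigma c k^2)$; the
dispersion relation records the leading real eigenvalue part per $k$
(computed from trace and determinant, with an `eigen()` cross-check in the
tests).

* **Hopf point**: root in `a` of $\mathrm{tr}\,J = 0$ with
  $\det J > 0$, solved by bisection to $|\Delta a| < 10^{-4}$; at the
  reference parameters $a \approx 26.88$.
* **Turing point**: smallest `a` at which $\max_{k>0}$ of the growth rate
  crosses zero while $k = 0$ stays stable; located by bisection in `a`
  over a scan-plus-golden-refinement maximization in $k \in (0, 5]$; at
  the reference parameters $a \approx 22.07$ with marginal wavenumber
  $k_c \approx 1.08$.  A closed form exists for this model but a numeric
  root with independent oracle tests is less error-prone; the nested
  search is the deliberate design choice.

Stability comparisons use a $10^{-10}$ guard band on growth rates.  Note
the ordering: the Turing point lies *below* the Hopf point, so for
$a \in (22.07, 26.88)$ patterns grow from a temporally stable uniform
state, and just below 22.07 (e.g. the reference forced case $a = 22$) the
uniform state is linearly stable but close to marginal.

## Floquet analysis of the forced uniform state

With forcing on, the spatially uniform reference state is periodic, not
stationary, so per-wavenumber stability comes from the linearized
Poincaré map over one forcing period:

1. **Orbit**: the space-free forced kinetics are integrated with explicit
   Euler at $N$ steps per period ($N = 10{,}000$ by default), period after
   period from the steady-state initial condition, until two consecutive
   period samples agree to $10^{-6}$ in max norm (cap: 500 periods —
   convergence genuinely depends on the parameters, and non-convergent
   cells of a phase diagram are reported as indeterminate, never stable).
2. **Map**: a wavenumber-$k$ perturbation obeys
   $\dot w = L(t;k)\,w$ with $L$ the kinetics Jacobian along the orbit
   minus $\mathrm{diag}(k^2, \sigma c k^2)$.  The map is accumulated as
   the ordered Euler product
   $P(k) = \prod_{s} \big(I + \Delta t\, L(s;k)\big)$ using the
   left-endpoint orbit samples, $\Delta t = T/N$.  First-order Euler is
   retained for both orbit and product deliberately — the two
   discretizations then agree exactly with direct integration of the
   perturbation (an identity the tests check to machine precision) — and a
   doubled-$N$ convergence check guards accuracy (moduli move by
   $<0.5\%$ from $N = 10^4$ to $2\times10^4$ at the reference point).
3. **Spectrum**: eigenvalue moduli of the real $2\times2$ map come from
   its trace and determinant; a complex pair has modulus $\sqrt{\det P}$.
   "Unstable" means $\max_k |\lambda| > 1 + 10^{-9}$, the guard keeping
   the neutral mode at marginality from flagging.

Two independent identities anchor the implementation: at $A = 0$ the
moduli must equal $e^{T\,\mathrm{Re}\,\mu(k)}$ from the autonomous
dispersion relation (agreement within 1% at $N = 10^4$), and
$\det P(k)$ must follow Liouville's formula
$\exp\int_0^T \mathrm{tr}\,L\,dt$ (agreement within 0.1%; this check runs
at $N = 10^6$ because the determinant of the Euler product carries an
$O(\Delta t)$ bias of a few times $10^{-3}$ at $N = 10^4$, which is a
property of the discretization, not an implementation error).

At the reference forced point ($a = 22$, $A = 6$, $T = 1$) the spectrum
exceeds one over a band of wavenumbers with its maximum at
$k \approx 1.10$ on a $k$-grid of step 0.01 (converged in both $N$ and
grid refinement), close to the marginal wavenumber of the unforced Turing
point; the instability persists down to forcing amplitudes near $A = 2$.
The `phase_diagram()` routine repeats this per $(T, A)$ cell.

## The reaction–diffusion solver

Space is discretized on a uniform periodic square grid with the five-point
Laplacian; the reference numerics use $\Delta x = 0.125$ on a
$50\times50$ domain with $\Delta t = 3.124\times10^{-4}$.  Each time step
applies, in order:

1. a half-step of diffusion, implicit along one axis and explicit along
   the other (Peaceman–Rachford ADI);
2. a full Heun (two-stage, second-order) step of the reaction terms, with
   the forcing evaluated at $t_n$ for the predictor and $t_n + \Delta t$
   for the corrector, preserving second order for the non-autonomous
   term;
3. the mirror diffusion half-step (implicit along the other axis).

The leading axis alternates between steps to symmetrize the splitting
error.  The periodic tridiagonal systems are reduced by a Sherman–
Morrison rank-one correction to two ordinary Thomas solves whose
factorization is cached for a whole stage (the coefficients are time
independent).  Diffusion of the inhibitor uses the coefficient
$\sigma c$.  Initial conditions are $u = v = 0$ plus independent Gaussian
noise of standard deviation 0.01, drawn once from the configuration seed;
everything afterwards is deterministic.

Correctness anchors in the tests: a uniform steady state is a fixed point
of the full stepper to $10^{-10}$ over a thousand steps; a single Fourier
mode with kinetics disabled decays per step by exactly the scheme's
analytic symbol; diffusion substeps conserve the spatial sum of each field
to round-off (both operators are zero-row-sum on the periodic domain);
and halving $\Delta t$ changes a settled pattern by well under 1% in
relative $L_2$ norm.

### Scaled-down preset and problem sizes

`fast_config()` runs a $25\times25$ domain at $\Delta x = 0.25$ and
$\Delta t = 10^{-3}$, with unforced runs of length $t = 300$.  The sizes
are set by the physics: the slowest case inside the pattern window
($a = 23$) grows at $\gamma \approx 0.074$, so growth from the noise
floor to saturation needs $\ln(10^3)/\gamma \approx 95$ time units plus
nonlinear settling — $t = 300$ leaves a comfortable margin, and just
below onset ($a = 22$) the slowly decaying marginal band
($\gamma \approx -0.02$) has decayed far below the homogeneity threshold
by then.  The domain holds roughly four pattern wavelengths
($k_c \approx 1.05$–1.1, $\lambda \approx 6$), enough to distinguish
spots from stripes while quantizing wavenumbers to bins of
$2\pi/25 \approx 0.25$.  The tests verify that $\Delta x = 0.25$ and the
reference $\Delta x = 0.125$ agree on the state label and the dominant
wavenumber to within one bin.

With these sizes the full simulated window $a = 21\ldots29$ reproduces:
homogeneous steady states up to $a = 22$, stationary spots from
$a = 23$ turning to stripes near $a = 27$, and homogeneous oscillations
from $a = 28$.

### Forcing protocols

A protocol is a list of stages (duration, $A$, $T$) integrated with a
continuous field state; the forcing phase restarts at zero at each stage
onset, matching how a pump program is switched on.  Stage durations for
the two canonical scenarios are chosen from the measured linear rates,
not tuned by eye:

* **Suppression** ($a = 24$ spots, then $A = 15$, $T = 1$): under
  forcing, pattern-scale modes decay by a factor $\approx 0.045$ per
  period, so six periods suppress the pattern by eight orders of
  magnitude — well below the homogeneity threshold — while leaving a
  seed above the round-off floor from which the pattern regrows at
  $\gamma \approx 0.147$ once the forcing stops ($\approx 120$ time
  units; the post stage uses 170).  A much longer forcing stage would
  drive the field to the round-off floor and the deterministic,
  noise-free solver could then not regrow the pattern within any
  reasonable stage — a scale artifact worth knowing about, since a real
  system is continuously re-seeded by fluctuations.
* **Induction** ($a = 22$ homogeneous, then $A = 6$, $T = 1$): the
  Floquet multiplier at the critical band is $\approx 1.114$ per period,
  so growth from the decayed noise level ($\sim 3\times10^{-4}$) to
  saturation needs $\approx 75$ periods; the forcing stage uses 110.
  After switch-off the induced pattern persists (the subcritical
  coexistence region below the Turing point) with its wavelength
  unchanged — the locking signature checked by `wavelength_locked()`.

### Pattern classification

`classify_pattern()` works from a time-ordered snapshot window (each
stage's closing stretch is sampled densely for this purpose):

* homogeneous iff the spatial standard deviation of the final frame is
  below $10^{-3}$ times the field's amplitude scale
  ($\max(1, |\bar u|)$); steady vs oscillatory by the temporal standard
  deviation at a fixed $4\times4$ probe grid with the same threshold;
* patterned states are labelled from the final frame's spectrum: the
  radially binned power spectrum (bin width $2\pi/L$, the domain's
  wavenumber quantum) gives the dominant wavenumber; a field whose
  distribution is strongly asymmetric ($|\text{skewness}| > 0.3$) is
  `spots` — an ideal hexagonal three-mode planform has skewness
  $\approx 0.8$, a stripe field 0; otherwise a single dominant spectral
  orientation (angular concentration $> 0.6$ on the dominant ring;
  stripes score $\approx 1$, hexagons $\approx 1/3$) gives `stripes`;
  a broad ring with neither signature is `mixed`, and a spectrum without
  a sharp ring at all is `irregular`.

The thresholds were calibrated once on the synthetic fixtures
(`make_fixture()`), which generate ideal planforms with known labels:
three cosines at 120° with wavevectors summing to zero (hexagonal spots),
a single cosine (stripes), constants and spatially uniform oscillations.
Wavevectors snap to the periodic domain's reciprocal lattice.  The
fixtures emulate planform geometry, not real pattern imperfections —
defects, amplitude modulation, domain walls — so passing fixture tests
shows the discriminators separate ideal planforms robustly (including
under 1% additive noise and under translation/rotation), not that the
labels are infallible on strongly disordered fields; such fields land in
`mixed`/`irregular`, which every downstream consumer treats as
patterned.  Spatiotemporal-wave states, which the model can produce
outside the regimes studied here, are likewise absorbed by `irregular`
rather than claiming a wave detector.

## Known limitations

* The two-variable model is a reduced description; it reproduces the
  suppression and induction/locking scenarios but is not expected to
  capture every experimental transition (e.g. a no-pattern → pattern →
  no-pattern sequence).
* The solver is strictly 2-D with periodic boundaries and spatially
  uniform forcing; feed gradients across a real gel (3-D effects) are out
  of scope.
* No stability analysis of the *patterned* state is attempted — the
  Floquet machinery addresses the uniform oscillatory state only.
* Spot-vs-stripe *selection* is not modelled; the classifier reports
  planforms, it does not predict them.
* After the single initial noise draw the dynamics are deterministic;
  consequences for very long suppression stages are noted above.

## Reproducing the headline numbers

```{r, eval = FALSE}
library(turingforce)

hopf_point(sigma = 8, b = 1.9, c = 1.5)      # 26.88
turing_point(sigma = 8, b = 1.9, c = 1.5)    # a = 22.07, k_c = 1.08

orb <- compute_periodic_orbit(le_params(a = 22), le_forcing(A = 6, T = 1))
stability_spectrum(orb)                      # unstable, argmax near k = 1.1

rc <- cima_rate_constants()
estimate_dimensionless_params(rc, clo2_anion = 10e-3, iodide = 2e-3)

res <- run_protocol(fast_config(a = 24, seed = 1))
res$stages[[1]]$report                       # spots, k about 1.0
```

`scripts/acceptance.R` packages these recomputations (bifurcation points,
destabilizing wavenumber, estimated `b`, and the simulated pattern-window
boundaries) into a single seeded run writing a JSON summary.
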