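---
title: "Helical chemotaxis under shot noise: model, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical chemotaxis under shot noise: model, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helitax)
```

## The model

Sperm cells of marine invertebrates find the egg by helical klinotaxis:
they swim along a helix and read the periodic modulation of a
chemoattractant signal sampled along the turns. The package implements
the closed control loop of that process:

1. **Field.** A radially symmetric chemoattractant field around a
   spherical egg of radius $R_{egg}$.
2. **Binding.** Ligand molecules bind at rate $b(t) = \lambda\,
   c(\mathbf r(t))$; the sensory input is the train of individual
   binding events, an inhomogeneous Poisson process — the molecular shot
   noise that limits gradient sensing at low concentration.
3. **Signalling.** A minimal adaptive module with output $a$ and dynamic
   sensitivity $p$,
   $$\mu\dot a = p\,[\lambda c_b + s(t)] - a, \qquad
     \mu\dot p = p\,(1-a),$$
   which adapts perfectly (steady state $a = 1$,
   $p = 1/(\lambda c_b + s_0)$) and responds to the helix-frequency
   modulation of the input. A slower trigger variable
   $\eta\dot q = a - q$ low-passes the output: its baseline shifts
   record whether the cell swims up- or down-gradient.
4. **Steering.** The output modulates path curvature and torsion,
   $\kappa = \kappa_0[1-\rho(a-1)]$, $\tau = \tau_0[1+\rho(a-1)]$; the
   Frenet–Serret equations turn that into a swimming path. The
   sensori-motor gain $\rho$ sets both the steering speed and the
   amplification of sensing noise. Two values idealize the
   experimentally observed steering modes: $\rho_{low} = 1$ and
   $\rho_{high} = 10$.

Coarse-grained, the helix centreline bends towards the gradient at rate
$\gamma = (\rho\varepsilon/T)\,|\nabla c|\sin\Psi\, r_0/(c_b+c)$ while
shot noise adds rotational diffusion
$D = (\rho\varepsilon/T)^2 c/[\lambda(c_b+c)^2]$, with
$\varepsilon = 2\pi\kappa_0\tau_0/(\kappa_0^2+\tau_0^2)$. The
placement of the period $T$ in these two expressions is fixed by
requiring exact consistency with the identity
$$\frac{\gamma^2}{D} = \frac{2\sin^2\Psi}{T}\,\mathrm{SNR}(R),$$
which the test suite verifies to $10^{-12}$ relative (dimensional
analysis concurs). The identity is the scientific core: the gain
cancels, so fast steering cannot be bought without proportionally
stronger directional noise.

On top of the simulator sit (i) a finite Markov decision process over
the coarse state $(R, \Psi)$ — distance to the egg and angle between
centreline tangent and gradient — whose maximum-reachability solution
is the optimal memoryless switching strategy between the two gains, and
(ii) a cell-implementable translation of that strategy into a rule on
the internal pair $(p, q)$: switch to high gain when $q < \Theta(p)$,
with $\Theta$ fitted to the 50% contour of the strategy projected into
$(p, q)$.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| $v$ | 200 | µm/s | swimming speed |
| $r_0$ | 7.5 | µm | helix radius |
| $2\pi h_0$ | 48.3 | µm | helix pitch (period $T = 0.34$ s) |
| $\lambda$ | 7 | s⁻¹pM⁻¹ | binding constant |
| $R_{egg}$ | 100 | µm | egg radius = capture distance |
| $\rho_{low}, \rho_{high}$ | 1, 10 | — | steering gains |
| $\mu$ | $1/\Omega_0 \approx 54$ ms | s | adaptation time |
| $\eta$ | $4T \approx 1.35$ s | s | trigger relaxation time |
| $c_b$ | 12 | pM | adaptation threshold |
| $R_{th}$ | 10 | mm | failure threshold |
| $t_{max}$ | 300 | s | search time of full simulations |
| $dt$ | $T/200$ | s | integration step |

Kinematic constants are the measured sea-urchin values. $\mu$, $\eta$,
$c_b$ and the field constants are not printed in the source text; they
are package calibration choices, fixed once as follows.

**Adaptation time $\mu = 1/\Omega_0$.** The adaptive module acts as a
band-pass; at $\mu = 1/\Omega_0$ it is centred on the helix frequency
with unit normalized gain and zero phase lag. This is the
matched-filter choice for a sensor that must read a signal modulated at
$\Omega_0$, and it makes the weak-gradient expressions for $\gamma$ and
$D$ quantitatively exact (the empirical bending-rate recovery in the
test suite agrees to well under a percent).

**Field.** The profile is $c(R) = c_s\,(R_{egg}/R)\,
\exp[-((R-R_{egg})/\ell)^\beta]$: spherical diffusion with a
stretched-exponential cut-off. $\beta = 1$ is steady-state diffusion
with first-order clearance of the chemoattractant; $\beta = 2$ mimics
the Gaussian front of a finite-duration release; the shipped default
interpolates. A pure $1/R$ profile cannot serve: its decay is too
shallow to put either the noise-zone boundaries or the attraction radii
at millimetre distances (in a scale-free $1/R$ field the coarse-grained
balance between bending, $\gamma R \le \varepsilon r_0/T \approx 70$
µm/s per unit gain, and the geometric defocusing at the axial drift
speed $v_\parallel \approx 143$ µm/s makes low-gain attraction
impossible at any distance). The cut-off supplies the local gradient
steepening that real egg plumes have.

**Calibration.** The defaults $\beta = 1.6$, $\ell = 1.305$ mm,
$c_s = 24000$ pM, $c_b = 12$ pM, $\eta = 4T$ were fixed once, in this
order: $(\beta, \ell)$ so that the noise-free target-zone radius and the
two attraction radii fall at 1.0, 3.8 and 4.8 mm (the coarse-grained
balance gives the initial guess; bisection over simulations verifies);
the ratio $c_s/c_b$ is pinned by the same radii (noise-free dynamics
depends only on $c/c_b$); the remaining overall concentration scale and
$\eta$ so that discriminating up- from down-gradient swimming from
$(p,q)$ is ~66% accurate at $R = 3$ mm, the distance at which state
estimation stops being reliable. All of these are plain arguments of
`model_params()` and `default_field()`. With the shipped values the
noise zone (SNR $< 1$ but $\ge 1$ binding event per turn) spans 0.65 mm
to 4.55 mm.

## What the generator emulates, and what it does not

Ensembles produced by `simulate_path()` and
`simulate_coarse_ensemble()` are the study conditions: physiological
binding rates, shot-noise-limited sensing, the two-gain steering law,
isotropic or stratified initial conditions, success when the raw
position reaches $R_{egg}$, failure at $R_{th}$, timeout at 300 s. They
do **not** emulate hydrodynamic wall interactions, flagellar-beat
mechanics, receptor saturation beyond the linear binding regime,
time-dependent plumes, or biochemical detail of the real cascade
(cGMP/Ca²⁺). Passing tests therefore show that the *model* behaves as
the theory predicts under its own assumptions — not that real sperm
achieve these numbers.

## Numerics

* **Path integration.** The Frenet triad is advanced by the exact
  rotation for piecewise-constant $(\kappa, \tau)$ (Rodrigues rotation
  about the Darboux vector) and the position by the exact integral of
  the rotating tangent, so a perfect helix closes to machine precision.
* **Signalling integration.** Exponential integrator for $a$ with the
  sensitivity predicted at midstep, exponential-trapezoidal update for
  $p$ (its dynamics is exactly $p \propto e^{\int(1-a)/\mu}$), exact
  relaxation of $q$ under linearly interpolated $a$, and a midpoint
  concentration along the tangent: the deterministic scheme is second
  order, and halving $dt$ moves a 300 s noise-free endpoint by well
  under one helix radius. Binding events enter as exact jumps
  $a \mathrel{+}= p/\mu$; in the compiled closed-loop core they are
  drawn as per-step Poisson counts (equivalent to event thinning at
  $O(dt)$, and necessary near the egg where rates reach $10^5$/s).
* **Centreline.** Moving average of the recorded positions over exactly
  one helix period (the circular component of an ideal helix cancels
  identically); tangent by central difference spanning one period;
  coarse samples taken once per period.
* **Curvature clipping.** $\kappa$ is clipped at zero from below
  (relevant only for large high-gain excursions); occurrences are
  counted on the trajectory object.
* **Attraction radii.** Bisection (50 µm resolution) on the predicate
  "mean over 4 initial helix phases of the minimum egg distance is
  below $R_0 - 2r_0$", with the helix axis initially perpendicular to
  the gradient. The $2r_0$ margin keeps the trivial excursion of the
  helix turn itself (which reaches exactly $R_0 - r_0$) off the
  decision boundary.
* **Value iteration.** From $V = 0$, monotone, to sup-norm $10^{-10}$;
  ties in the argmax go to low gain (less noise amplification).
  Unvisited bins become flagged unit self-loops and evaluate to 0.
  Strategy evaluation is a direct linear solve of the absorption
  system.
* **Zone boundaries.** Bracketed root finding (`uniroot`) to relative
  tolerance $10^{-10}$; a bracket without sign change is reported as
  "outside domain" rather than extrapolated.
* **Decision boundary.** Per-$p$-column 50% crossing of the high-gain
  frequency map, then continuous piecewise-linear least squares with 3
  segments, valid up to $p = 5$ ms (beyond it — far from the egg —
  the rule returns low gain). The $(p,q)$ samples are taken once per
  period at centreline-aligned times to suppress residual within-turn
  oscillations of $q$.
* **Accuracy estimator.** Bayes classifier with equal priors on
  held-out 2-D histogram densities of $(p, q)$, balanced classes — the
  natural reading of an accuracy scale running from 50% (no
  information) to 100% (perfect discriminability) given the two
  conditional densities.

## Problem sizes used by the shipped tests

The test suite and examples run at desk scale, chosen as the smallest
ensembles at which the qualitative results are stable: transition
models from $10^3$ stratified paths per action (an order of magnitude
below what a full-scale study would use), bootstrap cohorts of 10
replicates, 500 paths per point for
the gain-optimum curve, $10^4$ samples per class for the 3 mm accuracy
point, 150–200 paths per estimate elsewhere. Quantities quoted from the
reduced pipeline (for example the chemotactic ranges of the optimal,
all-high and all-low strategies) carry correspondingly wider sampling
error than the full-scale study; the acceptance tolerances account for
this.

## Known limitations

* The coarse $(R,\Psi)$ chain is only approximately Markovian: the
  hidden signalling state and within-bin position leave a residual
  history dependence of about 0.1 total variation in the conditional
  next-bin distributions. A formal goodness-of-fit test detects this at
  large counts; functionally, chain-predicted success probabilities
  agree with full closed-loop simulation at the tested distances.
* Far outside the sensation limit the Markov model slightly inflates
  success probabilities (bin-aggregation mixes favourable sub-states),
  so chemotactic ranges estimated from reduced ensembles run a few
  percent high.
* The $(p,q)$ decision rule is memoryless and hysteresis-free by
  construction; refractory dynamics of real off-responses are out of
  scope.
* The field calibration reproduces the millimetre-scale zone geometry
  characteristic of sea-urchin egg chemoattraction
  but is not unique: the radii constrain $c/c_b$ and the decay shape,
  not the absolute concentration scale, which is pinned only through
  the noise level (the 66% accuracy point).
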