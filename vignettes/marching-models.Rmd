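---
title: "Modelling marching locusts in one dimension: models, coarse-graining, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling marching locusts in one dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustmarch)
```

## The scientific setting

Gregarious locust nymphs marching in a ring-shaped arena synchronise into
collective clockwise or counter-clockwise motion, with rare spontaneous
reversals of the common direction. A family of one-dimensional
self-propelled-particle (SPP) models captures this: $N$ particles with
positions $x_i \in [0, L)$ on a periodic ring and dimensionless velocities
$u_i$ move as $\dot x_i = v\,u_i$, while each $u_i$ relaxes towards a
response to the local average direction of its neighbours, against noise.
The population order parameter

$$\phi(t) = \frac{1}{N} \sum_i u_i(t)$$

is near $\pm 1$ during coherent marching and near $0$ in disorder. This
package implements the model family, and the coarse-graining machinery that
reduces the many-particle dynamics to an effective one-dimensional diffusion
for $\phi$.

## The alignment family

All alignment models share the response function
$G(u) = \tfrac12\,(u + \mathrm{sign}(u))$ with $G(0) = 0$: an odd,
piecewise-linear map that pushes any non-zero average direction towards full
speed ($G(\pm 1) = \pm 1$) while leaving an undecided average alone. Noise
$\xi_i$ has variance $\sigma^2$ and is uniform on $[-\eta/2, \eta/2]$
(so $\sigma^2 = \eta^2/12$) or Gaussian.

**Continuous/discrete alignment model (`czirok`).** The Euler–Maruyama
update with step $\Delta t$ is

$$u_i \leftarrow u_i + \big[G(\langle u \rangle_i) - u_i\big]\Delta t +
\sqrt{\Delta t}\,\xi_i,$$

where $\langle u \rangle_i$ averages $u_j$ over all $j$ (including $i$)
within interaction range $\Delta$. With $\Delta t = 1$ this is the classic
discrete model $u_i \leftarrow G(\langle u \rangle_i) + \xi_i$. The
constructor rejects $\Delta t > 2$: the velocity relaxation has unit rate,
so the explicit Euler step is unstable beyond that. An isolated particle
obeys an Ornstein–Uhlenbeck process with mean $\pm 1$ (the sign it started
with) and stationary variance $\sigma^2$ — particles are genuinely
*self-propelled*.

**Individual-choice model (`individual_choice`).** Each step, each particle
independently *retains* its velocity with probability $\alpha$; otherwise
it performs the alignment update above. We implement the retain branch as
exact persistence (no noise added). The alternative reading — noise in both
branches — is rejected on quantitative grounds: with retain-noise the
high-density switching rate at $\alpha = 0.66$ comes out roughly forty-fold
above the discrete alignment model's *and* above the Buhl model's, whereas
exact persistence keeps the expected ordering (Buhl fastest, then
individual-choice, then the plain alignment model) and a severalfold
rate separation. Under this reading the measured individual-choice /
alignment rate ratio at the reference high-density setting is about 3–4
(the acceptance script computes it), below the order-of-magnitude
separation reported in the comparative literature; the dependence of the
switching rate on $\alpha$ is non-monotonic (strong persistence freezes
the swarm — a property the test suite checks), so no choice of the —
nowhere printed — retain probability stretches the separation to ten
under this reading. At $\alpha = 0$ every particle aligns every step and
the model reproduces the discrete alignment model draw-for-draw.

**Buhl model (`buhl`).** A deterministic weighting of self against others,
$u_i \leftarrow \alpha u_i + (1-\alpha) G(\langle u \rangle_i^-) + \xi_i$,
where $\langle u \rangle_i^-$ *excludes* the focal particle (zero for a
lone particle, hence an isolated particle fluctuates around zero — it is
not self-propelled). The conventional $\alpha$ is $0.66$. The update is a
discrete-time rule; the package enforces $\Delta t = 1$.

**Three-zone model (`bode`).** Asynchronous: per time step, $N$ random
particles are updated sequentially. A chosen particle with neighbours
within $\Delta$ picks one uniformly; it copies $G(u_k)$ if the neighbour is
within the alignment radius $r_2$, and otherwise takes the bounded
attraction response $G(\mathrm{sgn}(\delta x)\,(d - r_2)/(\Delta - r_2))$
toward it. No avoidance zone exists: repulsion has no sensible counterpart
on a 1D ring. $r_2$ defaults to $0.5$ (with $\Delta = 1$), a mid-zone
value.

**Internal-noise variants.** `update_mode = "asynchronous"` (N random
sequential sub-updates per step) and
`neighbor_mode = "single_random_neighbor"` (align with one uniformly chosen
neighbour) are available for the synchronous family; neither changes the
phenomenology much.

### Common random numbers

All synchronous alignment models consume identical per-step blocks of
random variates (N choice uniforms, then N noise variates, in particle
order), even where a model ignores a block. Two models run from the same
seed therefore see the same noise stream, which makes paired comparisons
(and the exact $\alpha = 0$ equivalence above) possible.

## The pause-and-go model

Marching locusts move intermittently: walk bouts alternate with pauses, and
only about the moving fraction participates in alignment. The two-state
model (`pause_and_go`) makes this explicit:

* a walker stops at rate $k_\mathrm{walk}$;
* a stander starts at rate $k_\mathrm{stand,0}$, jumping to
  $k_\mathrm{stand,1} > k_\mathrm{stand,0}$ once the number of *moving*
  neighbours within $\Delta$ reaches the quorum $n_{c,\mathrm{moving}}$
  (inclusive threshold);
* a particle that starts walking aligns with probability
  $\alpha(x) = \mathrm{clip}(a_0 + a_1 |x|,\,0,\,1)$, where $x$ is the local
  order among moving neighbours (magnitude, so both rotation senses are
  treated alike), using the continuous alignment update; otherwise it
  retains its heading plus the same noise term;
* walkers keep a fixed heading while walking; standers neither move nor
  enter anyone's averages.

Rates are converted to per-step probabilities with the exact mapping
$1 - e^{-k\Delta t}$, so results are robust to the choice of $\Delta t$.
The order parameter of interest is $\phi_\mathrm{moving}$, the mean $u$
over movers; a sample with no movers is recorded as $0$ with an explicit
*undefined* flag that all downstream estimators skip.

The rates are not constrained by printed values; the defaults
($k_\mathrm{walk} = 0.2$, $k_\mathrm{stand,0} = 0.05$,
$k_\mathrm{stand,1} = 1$, $n_{c,\mathrm{moving}} = 2$, $a_0 = 0.3$,
$a_1 = 0.7$, $\Delta t = 0.1$, all per unit time) were fixed once so that
both the onset of order with density and the coexistence of ordered and
disordered metastable states are observable at the reference geometry
($N = 100$, $v = 0.1$, $\Delta = 1$, $\eta = 2$).

A diagnostic flag `realign_walkers` lets walking particles re-evaluate the
alignment rule every step. With stops disabled and $a_0 = 1$ this embeds an
always-moving alignment model as a limiting case (used in tests); it is off
by default because the model's premise is that headings change only at
stand-to-walk transitions.

## Escape and pursuit

The cannibalism-motivated social-force model (`escape_pursuit`) evolves 2D
velocities by Langevin dynamics
$\dot u_i = -\gamma u_i + F^S_i + \sqrt{2D}\,\dot W$. The social force sums
two averaged projections of relative velocity: *pursuit* towards neighbours
in front that recede, and *escape* away from neighbours behind that
approach; front/back and approach/recede are the signs of
$u_i \cdot \hat r_{ji}$ and $u_{ji} \cdot \hat r_{ji}$, with strict
inequalities (a zero projection contributes nothing, so measure-zero
configurations inject no force), each class normalised by its own count.
Front-approaching and back-receding neighbours are ignored. The geometry is
a periodic square; boundary conditions are a package choice, as the model
itself does not fix them.

The 1D variant (`escape_pursuit_1d`) projects the same gates onto the ring
and exists to exhibit a structural defect: a pair with opposite-signed
velocities can never satisfy either gate pair, so clockwise and
counter-clockwise groups exert exactly zero mutual force and evolve as
independent subsystems — 1D escape–pursuit cannot reproduce the turning
that synchronises real marching bands. The test suite verifies this both
as an exact subsystem-equality over long noise-free runs and directly on
the force level.

## Coarse-graining

The order parameter is treated as an effective diffusion,
$\dot\phi = F(\phi) + \sqrt{2 D(\phi)}\,\dot W$. The estimators condition
coarse increments on the starting value (hard binning, 51 bins on
$[-1.2, 1.2]$ by default):

$$\hat F(\phi) = \frac{\langle \phi_{t+\Delta t} - \phi_t \rangle_\phi}{\Delta t},
\qquad
\hat D(\phi) = \frac{\mathrm{Var}_\phi[\phi_{t+\Delta t} - \phi_t]}{2\Delta t},$$

with a `second_moment` variant replacing the variance by the raw second
moment. The two differ per bin by $F^2 \Delta t / 2$, so they agree as
$\Delta t \to 0$ and diverge monotonically at larger coarse steps (a
property the tests assert on a synthetic double well). Bins with fewer than
`min_count` increments (default 100) are masked invalid, never
extrapolated. Stable zeros of $\hat F$ (sign change $+ \to -$, located by
linear interpolation between adjacent valid bins) are the metastable
states; unstable zeros separate their basins.

**Choosing the coarse increment.** $\Delta t$ must sit between the
individual correlation time and the metastable dwell time. The lap time
$L/v$ is the natural upper scale and the package default. Two practical
notes from working with these models:

* The Buhl model at high density loses the memory of a prepared initial
  order within far less than a lap (its noise per step is large), so
  ensemble drift profiles for it use $\Delta t \approx 30$–$60$ time units;
  at $L/v$ every increment relaxes to a stationary endpoint and the drift
  profile degenerates.
* The pause-and-go model's walk bouts last $1/k_\mathrm{walk} = 5$ time
  units; its profiles use $\Delta t = 25$, a few bouts long yet far below
  the disordered dwell time.

**Sampling protocols.** `estimate_FD()` accepts a single series or a list
(increments never span series boundaries), supporting both a single long
trajectory and many short ones. `fd_ensemble()` materialises the many-short
protocol: fresh runs of exactly one coarse increment from initial orders
laid out on a grid, which populates the rarely visited transition region of
strongly bistable models evenly. For the pause-and-go model the ensemble
initialisation (everyone moving) would pin the system to the high-activity
branch, so its drift profile is instead estimated from long trajectories
started at rest (everyone standing, random headings): these dwell in the
low-activity disordered state for thousands of time units before ordering,
so the pooled increments sample both branches. At density $\rho = 1.2$ this
yields five alternating zeros of $\hat F$ — stable disorder near $0$
flanked by unstable crossings and the two stable ordered states — the
tristability that distinguishes pause-and-go from the always-moving models,
whose disordered state is unstable at high density.

**Metastable states and switching.** States are labelled
$A_\pm = \{\phi \gtrless \pm p\}$ with cutoff $p = 0.7$. A switch is
counted only when the series enters one ordered set after most recently
residing in the other (hysteresis: same-side re-entries through the
undecided band do not count). Waiting times between opposite entries are
fitted by maximum likelihood to an exponential (rate $= 1/\bar w$) with a
Kolmogorov–Smirnov goodness-of-fit check — for an ordered swarm behaving as
a two-state Markov chain the fit should not reject. The plug-in of the
estimated rate makes the p-value conservative, which is adequate for this
qualitative check; waits inherit the sampling discretisation, so ties are
tolerated.

## The synthetic SDE generator

`synth_sde()` integrates $\dot\phi = F(\phi) + \sqrt{2D}\,\dot W$ by
Euler–Maruyama for named drift families (zero, constant, mean-reverting,
double-well) at fixed diffusion, in compiled code, reproducibly by seed.
It is the estimator oracle: on its output the generating functions are
known exactly, so recovery (within 10% on well-populated bins at small
coarse steps) and the fixed-point classifier (exactly
stable/unstable/stable on a double well) can be asserted. What passing
those tests shows is that the estimators are correct *given* the effective
model; it does not show that any particular particle model is well
approximated by a one-dimensional diffusion — for the particle models the
drift profiles remain protocol-dependent summaries (see the coarse-increment
discussion above).

## Numerical and design choices

* **Ring geometry.** Minimal-image distances; positions wrapped to
  $[0, L)$ with `x - L * floor(x / L)` in both R and compiled code so the
  two paths agree bit-for-bit. Positions advance with the pre-update
  velocity (the asynchronous models advance the chosen particle with its
  freshly updated velocity, following their algorithmic statement).
* **sign(0) = 0** exactly, hence $G(0) = 0$.
* **Initial conditions.** $x \sim U[0, L)$, $u \sim U[-1, 1]$, all moving,
  drawn from the same seeded stream as the dynamics; overridable via
  `init`.
* **Empty neighbour sets** average to zero (self-excluded) or to the own
  velocity (self-inclusive); the single-neighbour mode falls back to the
  own velocity so the lone-particle limit is preserved.
* **Burn-in.** Statistics discard the first 10% of a run by default.
* **Horizons.** Switching-rate estimates use $2 \times 10^5$ steps per
  replicate, 8 replicates. Order scans use $2 \times 10^4$ steps: at low
  density the 1D models exhibit slow cluster coarsening, so the mean order
  there is horizon-dependent; the shorter horizon measures order after
  local equilibration without conflating it with coarsening, and is the
  package's fixed convention for density scans.
* **Compiled cores.** The per-step loops live in C++ (with a cell list for
  neighbour searches, capped at $4N$ cells); the exported R step functions
  define the per-step semantics and are cross-checked against the compiled
  loop in the tests at tolerance $10^{-10}$ (summation order differs, so
  bit-identity is not asserted between the two implementations — it *is*
  asserted between models coupled on a common stream).

## Known limitations

* All 1D models inherit the artificial features of a ring: no band
  structure, no density profile, no front dynamics.
* The pause-and-go rates are package defaults, not fitted to arena data;
  conclusions about locusts should rest on the model structure, not these
  numbers.
* The drift/diffusion estimates use hard binning, not kernel estimators;
  bins straddling a sign change bias the interpolated zero by up to half a
  bin width.
* The 2D escape–pursuit implementation is a structural test bed, not a
  reproduction of published phase diagrams.
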