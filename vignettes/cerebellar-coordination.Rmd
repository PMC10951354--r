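---
title: "Cerebellar state estimation and behavioural synchronisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebellar state estimation and behavioural synchronisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cerebsync` simulates a hypothesis about cerebellar function: that the
cerebellum's contribution to behaviour is to *estimate how behavioural
variables interact* and to feed those estimates back so that the circuits
producing the behaviours stay coordinated. The package couples two kinds of
dynamical object in a closed loop:

**The generative process** stands in for the extra-cerebellar circuits that
actually produce rhythmic behaviour. It is a set of stochastic phase
oscillators. For orofacial behaviour, two oscillators produce whisker
position $w = \alpha\sin\phi_w$ and rib-cage expansion $r = \sin\phi_r$,
with phase dynamics

$$\dot\phi_w = \omega_w + k\sin(x_w - \phi_w) + Q_w, \qquad
  \dot\phi_r = (\omega_w + \omega_0) + k\sin(x_r - \phi_r) + Q_r,$$

where $Q$ are independent Gaussian phase noises and $\omega_0$ is an
intrinsic angular-velocity offset between the two rhythms. Crucially there
is **no direct coupling** between the oscillators: the only terms that can
coordinate them involve $x_w$ and $x_r$, the cerebellar estimates of the
somatic states. For locomotion, four limb oscillators
($l = \sin\phi$ for fr, fl, hr, hl) carry an intrinsic coupling
$k_{\mathrm{intr}}\sin(\phi_{fr} + \delta - \phi)$ that imposes walk-like
offsets $\delta = \pi, \tfrac32\pi, \tfrac12\pi$ on fl, hr, hl relative to
fr, plus a cerebellar term $k_{cb}\sin(x - \phi)$; the tail is a passive
sum $t = \sin\phi_{fr} + \sin\phi_{fl}$.

**The generative model** is the cerebellum: a linear stochastic state-space
model with observations $y = \theta_g x + Z$, state motion
$\dot x = -x + \theta_f v + W$ and unconstrained hidden causes $v = V$,
with Gaussian noises of precision $\Pi_z, \Pi_w, \Pi_v$. Inverting this
model is Bayesian filtering; under the Laplace assumption the filter's
state is the triple of expectations $(\mu_x, \mu_{x'}, \mu_v)$ and its
dynamics are a gradient flow on the variational free energy

$$F = \tfrac12\varepsilon_y^T\Pi_z\varepsilon_y
    + \tfrac12\varepsilon_x^T\Pi_w\varepsilon_x
    + \tfrac12\varepsilon_v^T\Pi_v\varepsilon_v
    - \tfrac12\log|\Pi_z\,||\Pi_w||\Pi_v|,$$

with prediction errors $\varepsilon_y = y - \theta_g\mu_x$,
$\varepsilon_x = \mu_{x'} + \mu_x - \theta_f\mu_v$ and
$\varepsilon_v = \mu_v$:

$$\dot\mu_x = \mu_{x'} + \kappa_x(\theta_g^T\Pi_z\varepsilon_y
  - \Pi_w\varepsilon_x), \qquad
  \dot\mu_{x'} = -\kappa_{x'}\Pi_w\varepsilon_x, \qquad
  \dot\mu_v = \kappa_v(\theta_f^T\Pi_w\varepsilon_x - \Pi_v\varepsilon_v).$$

The whole hypothesis lives in $\theta_f$, the parallel-fibre connectivity.
With $\theta_f = I$ the filter expects the channels to evolve
independently and simply tracks each output. With the all-ones $\theta_f$
(whisking) or the $\pm1$ diagonal-pair pattern (locomotion) the motion
prior ties the channels together: the hidden causes can only explain
*coordinated* motion, so the state estimates are biased toward the
coordinated pattern, and — because those estimates re-enter the process
coupling terms — the bias becomes a real synchronising force. This is what
the package calls *contextualisation*.

Only first-order generalised motion is carried ($\mu_x, \mu_{x'}$); there
are no higher derivatives, no action variable, and no learning of
$\theta_f$ — the connectivity is set per scenario, emulating the state
after (or before) cerebellar learning.

## Why the rate constants are asymmetric

A single design decision makes the loop work, and it is worth spelling
out. Suppose all three rate constants were equal and fast. Then
$\mu_{x'}$ relaxes $\varepsilon_x \to 0$ within a fraction of an
oscillation cycle — the motion prior is satisfied by *adjusting the motion
expectation* rather than by biasing the state estimate. The filter then
tracks each channel perfectly, $x \approx y$, each oscillator's coupling
term becomes a self-interaction, and no coordination ever emerges; we
verified this over a wide parameter grid. The same happens for any
$\kappa_{x'}$ above roughly one cycle$^{-1}$.

The defaults therefore separate timescales, in units where oscillator
periods are order 1:

* $\kappa_x = \kappa_v = 100$ — sensory assimilation and cause inference
  are fast (quasi-static with respect to the rhythms);
* $\kappa_{x'} = 0.3$ — motion expectations integrate over a few cycles.

With the motion channel slow, the stationary balance of the $\mu_x$
equation is $\theta_g^T\Pi_z\varepsilon_y = \Pi_w\varepsilon_x$: the
state estimate settles part-way between the sensory evidence and the
coordinated pattern, with the fraction set by the precision ratio
$\Pi_w/\Pi_z$. The scenario presets use $\Pi_z = 0.5I$, $\Pi_w = I$, so
roughly two thirds of any coordination error shows up as a bias on the
descending estimates. $\Pi_v = 10^{-2}I$ keeps the prior over causes
noninformative (its covariance has large variance terms).

## Process parameters and the locking region

The cerebellar coupling $k\sin(x-\phi)$ compares an amplitude-valued
estimate ($|x|\lesssim1$) with a phase, exactly as the model specifies.
This makes the coupling much weaker than a textbook Kuramoto term: writing
$\sin(x-\phi) \approx x\cos\phi - \sin\phi$, the informative part is the
$x\cos\phi$ forcing, an effective gain of roughly $k/4$ once the estimate
bias is accounted for. Entrainment against an angular-velocity offset
$\omega_0$ therefore needs $k$ several times larger than $\omega_0$, and
$k$ must stay below $\omega$ or the coupling stalls the rotation
($\dot\phi$ must remain positive). We probed the closed loop's locking
region directly; the defaults sit comfortably inside it:

* whisking: $\omega_w = 2\pi$ (low regime) and $4\pi$ (high regime),
  offset $\omega_0 = 0.1\pi \approx 0.314$ rad/time (5% of the low rate,
  applied in all regimes), gain $k = 4$, phase noise $\sigma = 0.1$;
* locomotion: $\omega = 2\pi$, $k_{cb} = 4$, $k_{\mathrm{intr}} = 0.5$,
  $\sigma = 0.1$. The cerebellar gain must dominate the intrinsic walk
  coupling for the diagonal pairs to lock (the intrinsic pattern is a
  quarter-cycle away), while $k_{\mathrm{intr}}$ alone must still
  establish its offsets within a run — $0.5$ satisfies both.

The behavioural episode of the whisking scenarios runs low-rate locomotor
whisking for the first third of the run, a short no-whisk gap
($\alpha = 0$, one fifteenth of the run), then high-rate object
exploration. During the gap $|w - r| = |r|$ touches 1 at the respiratory
peaks; the coordination claim ("difference below 1") is carried by the
whisking regimes, where the default loop holds $|w-r|$ near 0.6.

Perturbation events add $\Delta\phi = \pi/2$ to the whisking phase at 15%
and 60% of the run; recovery is assessed against the pre-event band of
the synchronisation-manifold distance $|w-r|/\sqrt2$.

## Integration and numerical choices

Both the process (Euler–Maruyama) and the filter (explicit Euler) advance
synchronously with the same step, $dt = 10^{-3}$, i.e. 500–1000 filter
steps per oscillator cycle; stability requires
$\kappa_{\max}\lambda_{\max}(\Pi)\,dt \ll 2$ and the defaults give 0.1.
One standard normal deviate per oscillator is drawn every step regardless
of the noise scale, so noise streams are reproducible and independent
across oscillators under a fixed seed. Phases are stored wrapped to
$[0, 2\pi)$; sine outputs make wrapping unobservable. All expectations
start at zero (the sparsity attractor of the recognition dynamics). A
divergence guard aborts a run, naming the offending expectation, if any
$|\mu|$ exceeds $10^6$. Observations are the noiseless process outputs:
stochasticity enters through the phases only, and $\Pi_z$ is the filter's
*expected* sensory precision, not an added measurement noise.

While cerebellar-nuclear output is suspended (the `cn_active` schedule)
the process-side coupling gain is zeroed but the filter keeps
assimilating; this reproduces the dissociation in which estimates shrink
in amplitude as behaviour desynchronises.

## Metrics

* `abs_difference_trace` / `sync_manifold_distance`: $|w-r|$ and its
  perpendicular distance to the diagonal of the joint output space.
* `phase_locking_stats`: circular mean and mean resultant length of a
  wrapped phase difference over the post-transient window.
* `stride_average`: stride-triggered averaging anchored on upward
  crossings of $\phi_{fr}$ through 0 (mod $2\pi$), resampled to a common
  stride-phase grid; the default request is 14 strides.
* `tail_symmetry_index`: 1 minus the mean per-phase standard deviation of
  the tail across strides, relative to the range of the stride-averaged
  tail curve. This is a construct of this package. We first implemented
  an index comparing the mean tail curve with its half-cycle reflection,
  but it cannot separate the conditions here: the front limbs sit near
  antiphase in *both* coordination patterns, so the mean curve has the
  same half-cycle structure in both. What does distinguish them is
  stride-to-stride reproducibility — with cerebellar coordination the
  tail repeats the same excursion every stride; without it the excursion
  wanders — and the index quantifies exactly that.

Transients: whisking metrics discard the first 20% of the run; the
locomotion preset discards the first third (the limbs start stacked at
the unstable in-phase configuration and take several cycles to relax) and
runs for 28 time units so that at least 14 full strides remain.

## What the generator emulates, and what it does not

The oscillators emulate the *statistics* of whisking, respiration and
stride cycles — rhythms with intrinsic rate offsets, phase noise and
abrupt perturbations — not their biomechanics. Extra-cerebellar inference
is deliberately collapsed into a stochastic process; proprioceptive
reflex arcs, transport delays, multi-rate message passing and plasticity
are all absent. Passing tests therefore show that the *coordination
mechanism* behaves as described under these idealised conditions; they do
not validate the model against recorded behaviour, and parameter values
(rates in rad per arbitrary time unit, unit-amplitude outputs) are not
calibrated to any animal.

Two known limitations are worth flagging. First, the amplitude-vs-phase
comparison inside $\sin(x-\phi)$ is taken literally from the model
definition; an alternative reading converts $(\mu_x, \mu_{x'})$ to a
phase with the two-argument arctangent before comparison, which would
give a much stronger (classical Kuramoto) coupling. We implement the
literal form; the conversion is easy to apply externally to a trace but
is not part of the simulator. Second, under the literal form the
contextualised diagonal limb pairs lock at a compromise angle
(about 0.3–0.6 rad from exact in-phase, against the quarter-cycle
intrinsic offsets) rather than at zero; concentrations are nevertheless
above 0.95 and the pairwise stride curves overlap far more closely than
any non-paired combination.

## Problem sizes

The test suite and the acceptance analyses use runs of 28–30 time units
(about 30 oscillation cycles, 28,000–30,000 steps) for the full
scenarios, and runs of 0.2–8 time units for structural checks; the
finite-difference gradient audit uses 100 random model instances of
dimension 1–4.
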