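---
title: "Modelling subretinal electric stimulation of cone bipolar cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling subretinal electric stimulation of cone bipolar cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbcstim)
```

## The model

Subretinal prostheses stimulate the retina from beneath: a photodiode array
sits where the photoreceptors used to be, so the bipolar cells — whose
dendrites face the implant and whose axon terminals reach into the inner
plexiform layer — are the primary targets of the voltage-controlled
electrodes. `cbcstim` simulates how a rat ON (type 9) and OFF (type 3) cone
bipolar cell respond to such stimulation, in two one-way coupled stages.

**Stage 1 — the extracellular field.** The tissue is a quasi-static volume
conductor: the potential obeys $\nabla\cdot(\sigma\nabla V_e)=0$ in a
2000 × 2000 µm sandwich of electrode-carrier chip (100 µm, $10^6\,\Omega$ cm),
retina (300 µm, 57 $\Omega$ cm) and silicone tamponade (300 µm,
$10^6\,\Omega$ cm). A 50 µm disk electrode at the chip/retina interface is a
Dirichlet surface at the drive voltage; the distant return electrode is
modelled by grounding the retina layer's outer lateral boundaries; all other
outer faces are insulating. `solve_potential()` discretises this with a
7-point finite-volume stencil on a regular grid (series/parallel conductivity
averaging at layer interfaces and boundary half-faces) and solves it with
Jacobi-preconditioned conjugate gradients, matrix-free in compiled code.
Because the problem is linear, one unit-drive solution is reused for every
stimulus waveform.

**Stage 2 — the cell.** Each cell is a tree of 94 (ON) or 78 (OFF)
compartments — cylinders plus a spherical soma — each represented electrically
by its centre point. Charge conservation per compartment gives the cable
system for the reduced potential $V_n = V_{i,n}-V_{e,n}-V_{rest}$:
capacitive current balances the ionic currents and one axial term
$\big[(V_{j}-V_n) + (V_{e,j}-V_{e,n})\big]/(R_j/2+R_n/2)$ per neighbour $j$.
Only *differences* of the extracellular potential between neighbouring
compartments drive the membrane, which the uniform-field invariance test
checks directly.

The membrane is deliberately minimal: a leak
($E_{leak}=-53.08$ mV $=V_{rest}$, $g_{leak}=0.0417$ mS/cm²,
$c_m=1.1$ µF/cm², $\rho_a=130\,\Omega$ cm) everywhere, plus one voltage-gated
calcium channel type on the synaptic terminal compartments: L-type on the ON
cell ($\bar g=1.088$ mS/cm², $m^2h$ gating with rate-form activation and a
292 ms inactivation) and T-type on the OFF cell ($\bar g=0.954$ mS/cm², $mh$
gating). Terminal calcium follows a single-pool balance: influx proportional
to the calcium current scaled by the compartment's surface-to-volume ratio,
and relaxation to a residual 0.15 µM with $\tau=1.5$ ms; the extracellular
concentration is fixed at 1800 µM and the calcium Nernst potential is
re-evaluated every step at 25 °C. No other channels are modelled, and no
temperature (Q10) correction is applied — the kinetics are used at the
experimental temperature they were fitted at.

### The effective reversal potential

At sub-micromolar internal calcium, outward current through an open calcium
channel is carried almost entirely by K⁺, so the channel's effective reversal
lies far below the calcium Nernst potential. This is implemented as a
configurable blend $E_{eff} = w\,E_{Ca} + (1-w)E_K$ with $E_K=-75$ mV.
The mixing weights are not published; the defaults $w_T=0.65$ and
$w_L=0.67$ place the effective reversals near +52 mV (T) and +56 mV (L) at
resting calcium, chosen once so that simulated clamp families stay inward up
to +45 mV for the T-type channel and reverse right at the top (+55 mV) step
for the L-type channel. Two consequences worth knowing:

* the K⁺-carried outward current does not deplete the calcium pool, so the
  residual concentration acts as a hard floor on $[\mathrm{Ca}]_i$ (the
  pool clamps at 0.15 µM from below rather than dipping under it);
* because $E_{Ca}$ is dynamic, strong influx lowers the driving force — a
  self-limiting mechanism that produces the observed saturation of peak
  calcium between 1 V and 2 V pulses.

### Sign convention for pulse polarity

Polarity labels name the phase of the *distant return electrode*, so a
"cathodic" pulse drives the working electrode positive. In this perpendicular
geometry that is the polarity that hyperpolarises the dendrites facing the
implant and depolarises the axon terminals — the depolarising pulse of every
experiment here. The activating-function end effect makes the physical sign
unambiguous: with the working electrode negative, the compartment chain's
near end (dendritic tip) would depolarise and the terminals hyperpolarise,
which is the mirror image of every polarisation pattern this model is built
to produce. Users comparing against conventions that name the working
electrode should flip the labels.

## Numerical scheme

* **Gates**: exact exponential relaxation per step toward
  $m_\infty(V)$ with $\tau_m(V)$, evaluated at the start-of-step voltage —
  unconditionally stable across the stiff $\tau$ range (microseconds for
  L-type deactivation to 292 ms for L-type inactivation). The removable
  singularity of the L-type activation rate at $V_m=63$ mV is evaluated
  analytically within $|V_m-63|<10^{-6}$ mV.
* **Voltages**: backward Euler with the channel conductance linearised at
  the freshly updated gates; the resulting tree-structured system is solved
  exactly in $O(n)$ per step by Hines elimination. Default
  $\Delta t = 0.01$ ms; halving it changes terminal traces by a bounded,
  shrinking amount (first-order convergence, tested).
* **Calcium**: exact exponential update toward the fixed point implied by
  the step's current, floored at the residual level.
* **Field**: default grid spacing 10 µm (the 50 µm electrode is resolved by
  ~5 nodes across its radius); relative-residual tolerance $10^{-8}$. The
  solver is validated against the closed-form oblate-spheroidal solution for
  an equipotential disk on a homogeneous half-space (on-axis
  $V=(2V_0/\pi)\arctan(a/z)$): with analytic Dirichlet values on the far
  faces the discrete solution agrees within 1% on axis for
  $z\in[10,200]$ µm at 5 µm spacing, comfortably inside the 3% criterion.
  A 5 µm spacing on the full sandwich is supported but costs ~8× more; the
  10 µm default changes sampled compartment potentials by well under the
  grid-convergence bound measured in the tests.
* **Blow-up guard**: the integrator aborts with a diagnostic if any
  $|V|$ exceeds 10 V (configurable).

## The morphology generator

No public 3D reconstructions exist for these cells, so the two fixtures are
generated, seeded, synthetic stand-ins. Each spec fixes a region layout —
dendritic branches fanning down toward the electrode plane, a spherical soma
(11 µm ON / 9 µm OFF), a straight axon (60 µm ON / 22 µm OFF) and a terminal
fan — with exact compartment counts (94 / 78). Lateral branch geometry is
deterministic; the depth (y) extent uses a confined normal draw (sd = 0.15 ×
the branch's 2D extent, truncated at ±2σ) under the spec seed, so builds are
bit-reproducible and the session RNG is left untouched. The layouts were
calibrated once so that the passive polarisation pattern is qualitatively
right — terminals depolarising, dendrites hyperpolarising, the longer ON cell
polarising more than the OFF cell, and the 40%-clinched ON cell matching the
OFF cell's z-extent within 10% — and then frozen. Absolute voltages and
calcium peaks therefore differ from any particular traced cell (our passive
ON terminal depolarisation is ~220 mV against an expected ~160 mV for the
traced geometry); all cross-cell comparisons in the experiments are within
this one generator, which is what makes the orderings meaningful.

`scale_axon()` rescales the *positions* of axonal and terminal compartments
about the soma without touching their electrical properties: membrane area,
capacitance and axial resistances are invariant, so the axon-length sweeps
isolate the purely geometric effect of where the cell sits in the field.

## Experiment harnesses

* **Standard runs** place the cell with its dendritic tip 25 µm above the
  interface, soma centred over the electrode, and report per-region
  max/min polarisation, peak terminal calcium and its decay time.
* **Calcium decay time** is measured from the last stimulus offset until the
  maximum terminal calcium stays within 2% above its pre-stimulus baseline
  (a repo convention; the threshold is a parameter). This is a strict
  criterion: with L-type deactivation essentially instantaneous at rest, the
  ON cell's post-burst calcium decays with the pool constant
  $\tau=1.5$ ms and needs $\approx\tau\ln(\Delta/0.02\,[\mathrm{Ca}]_{res})
  \approx 7\text{–}9$ ms from a 0.5–1 µM peak, while the OFF cell's T-type
  activation gate closes at rest with $\tau_m(-53\ \mathrm{mV})=23$ ms and
  sustains influx for well over 100 ms. Looser thresholds (tens of percent)
  reproduce the few-ms / few-tens-of-ms readings one takes off a plot.
* **Position maps** shift the cell on a 2 µm grid (default 48 × 17 = 816
  positions) and record peak terminal calcium per position.
* **Frequency response** uses a mono-compartment patch (specific
  capacitance + leak + one channel) driven by a sinusoidal *current*
  density, 6 cycles per frequency with the last, settled cycle scored by its
  peak inward channel current; the curve is normalised to its maximum over
  the 19-point log-spaced 1–1000 Hz sweep. The amplitude default,
  3.75 µA/cm², polarises the patch by ~90 mV at low frequency so the
  commanded excursion actually reaches the channels' activation midpoints
  (+9 to +38 mV); a small-signal sweep (e.g. 30 mV) leaves both channels in
  the exponential tail of activation ($m_\infty<10^{-4}$) and the
  normalised curve degenerates into a pure low-pass with no band-pass
  structure. A voltage-command variant is available through
  `run_voltage_clamp()` with a sinusoidal command, but the current-driven
  harness is the one that reproduces the band-pass behaviour of the
  channels, because the membrane time constant
  ($c_m/g_{leak}\approx26$ ms) supplies the high-frequency roll-off while
  inactivation and slow activation supply the low-frequency suppression.
  With these choices the T-type peak sits at 2.2 Hz (grid argmax 2.15 Hz)
  and the L-type peak above it on a near-flat low-frequency plateau —
  T-type band-pass, L-type low-pass, sodium-channel kinetics are *not*
  included (the interface accepts any `cbc_channel`-like parameter set, but
  only the two calcium channels are shipped).

## Problem sizes and runtimes

The shipped defaults are desk-scale: the standard field solve is a
201 × 201 × 71 grid (≈2.9 M unknowns, ~600 CG iterations, tens of seconds on
one core) and is solved once and reused; a 15 ms active cell run at
$\Delta t=0.01$ ms takes ~10 ms, so even the full 816-position maps run in
under a minute per cell. The test suite uses the 10 µm field plus small
half-space oracle grids and completes in well under a minute.

## What the tests do and do not show

The suite verifies the pieces against independent oracles (closed-form disk
potential, exponential gate relaxation, hand-assembled two-compartment
operators, analytic calcium fixed points) and the whole against the
qualitative physiology: ON > OFF terminal depolarisation, OFF > ON calcium
magnitude and persistence, saturation of ON calcium above 1 V, opposite
biphasic phase-order preferences for the two cells, far larger positional
sensitivity of the OFF map, and the T-before-L ordering of the sinusoidal
response peaks. Because the morphologies are synthetic, the tests do *not*
certify absolute voltages or calcium concentrations for any real cell, nor
network-level effects (amacrine/ganglion interactions, synaptic release,
electrode-electrolyte interface chemistry and capacitive waveform
distortion are all outside the model).

## Known limitations

* One-way coupling: membrane currents do not feed back onto the field.
* Single calcium pool per compartment; no buffering or intercompartmental
  diffusion.
* The two published K⁺-blending ratios and the sodium channel of the
  frequency-sweep figure are not recoverable from printed sources; the
  former are package defaults (documented above), the latter is left as a
  pluggable interface.
* Calcium recovery times at a strict 2% threshold are materially longer
  than plot-read "return to rest" times (see above); comparisons across
  cells are unaffected.
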