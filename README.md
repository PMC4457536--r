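# cbcstim

Forward simulation of retinal **cone bipolar cells (CBCs)** under
voltage-controlled **subretinal electric stimulation** — the situation of a
photodiode-array implant sitting beneath a degenerated retina. The package is
for computational neuroscientists and prosthesis engineers who want to ask,
at the level of a single ON or OFF bipolar cell: which stimulus polarities,
amplitudes, pulse shapes and frequencies drive the synaptic terminals hard
enough to raise intracellular calcium — the proxy for synaptic output — and
whether any paradigm separates the ON from the OFF pathway.

## The model

Two one-way coupled stages:

1. **Volume conductor.** The quasi-static extracellular potential obeys
   ∇·(σ∇Vₑ) = 0 in a layered chip (10⁶ Ω cm) / retina (57 Ω cm) /
   tamponade (10⁶ Ω cm) sandwich, driven by a 50 µm disk electrode at the
   chip/retina interface, with the retina's outer lateral boundaries grounded
   (the distant return electrode). Solved by a matrix-free finite-volume /
   conjugate-gradient scheme and validated against the closed-form disk
   potential V(z) = (2V₀/π)·atan(a/z) on a homogeneous half-space.

2. **Multi-compartment cable.** Each cell (94 compartments ON, 78 OFF;
   generated, seeded morphologies) obeys, per compartment n,

   C·dVₙ/dt = −I_ion,ₙ + Σⱼ (Vⱼ−Vₙ)/(Rⱼ/2+Rₙ/2) + Σⱼ (V_e,ⱼ−V_e,ₙ)/(Rⱼ/2+Rₙ/2)

   with V the reduced potential (V = Vᵢ − Vₑ − V_rest), a leak
   (E_leak = −53.08 mV, g_leak = 0.0417 mS/cm²) everywhere and one
   Hodgkin–Huxley-style calcium channel on the synaptic terminals: L-type
   (ḡ = 1.088 mS/cm², m²h) on the ON cell, T-type (ḡ = 0.954 mS/cm², mh) on
   the OFF cell. Terminal [Ca²⁺]ᵢ follows a single-pool balance
   (influx ∝ (s/v)·i_Ca/2F, relaxation to 0.15 µM with τ = 1.5 ms) and feeds
   back on the channels through a dynamic, K⁺-blended reversal potential.
   Integration is operator-split: exact exponential gate/calcium updates and
   a backward-Euler Hines solve of the voltage tree.

Pulse polarity is named after the distant return electrode: a *cathodic*
pulse drives the working electrode positive and is the one that depolarises
the axon terminals in this geometry (see the methods vignette,
`vignettes/cbcstim-methods.Rmd`, for why the sign is unambiguous).

## Worked example

```r
library(cbcstim)

cell  <- build_cell(on_spec())        # seeded ON (type 9) fixture
field <- solve_potential(volume_model(), electrode_spec(),
                         drive = 1, grid_spacing = 10)
res   <- run_standard(cell, field, monophasic(1, 0.5, "cathodic"),
                      t_end = 30)
print(res)
```

```
<cbc_experiment>
 cell_type active channel                         protocol terminal_depol
  ON_type9   TRUE       L monophasic cathodic 1 V / 0.5 ms       206.4952
 dendrite_hyperpol   peak_ca decay_ms
         -272.7544 0.5173663      7.5
```

A 1 V, 0.5 ms cathodic pulse depolarises the ON terminals by ~206 mV while
hyperpolarising the dendrites facing the electrode by ~273 mV; terminal
calcium peaks at 0.52 µM and is back at baseline within ~8 ms, because the
L-type channel deactivates essentially instantly at rest. The same pulse on
the OFF fixture (`off_spec()`) depolarises less (~180 mV) but drives calcium
to 4.2 µM and holds it up for ~180 ms — the slow T-type deactivation
(τ_m ≈ 23 ms at rest) sustains the influx. That asymmetry — the *less*
depolarised cell producing *more* calcium — is the central behaviour of the
model.

Other entry points: `biphasic()` / `burst()` / `sinusoid()` for stimulus
design, `run_voltage_clamp()` for channel-level clamp families,
`axon_length_sweep()`, `position_map()` (2 µm-pitch electrode-position maps
of peak terminal calcium), `channel_swap()` (identical channel complements
on both cells) and `frequency_response()` (mono-compartment sinusoidal
sweep: T-type peaks near 2 Hz, L-type above it, both rolling off well below
100 Hz). `read_swc()`/`write_swc()` import/export morphologies
(SWC type codes: 1 soma, 2 axon, 3 dendrite, 5 terminal);
`read_protocol_yaml()`/`read_morphology_yaml()` load the YAML configs under
`inst/extdata/`. A thin CLI over these functions lives at
`inst/cli/cbcsim.R`.

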