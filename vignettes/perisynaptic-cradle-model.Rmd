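---
title: "The perisynaptic cradle model: ion microdomains and NCX reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The perisynaptic cradle model: ion microdomains and NCX reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscradle)
```

## The model

Most excitatory synapses in the CNS are enwrapped by a thin astrocytic sheet
— the perisynaptic cradle (PsC). The cradle is connected to the astrocyte
soma only through a long (~25 µm), thin (~100 nm) process whose membrane
carries fixed negative charges. Cations moving along the process are trapped
in the potential wells of those charges and escape only by field-assisted
(Poole–Frenkel) hopping, so the cradle is semi-isolated from the soma:
ions imported across the cradle membrane accumulate locally as
*microdomains*. `pscradle` simulates the coupled ion dynamics of a single
synapse and its cradle and shows how sustained neuronal firing produces K⁺,
Na⁺ and — through reversal of the Na⁺/Ca²⁺ exchanger — Ca²⁺ microdomains.

Six compartments are modelled (the cylindrical geometry and all dimensions
are in `psc_geometry()`): the presynaptic terminal ("synapse"), the
perisynaptic extracellular cleft (PsECS), the cradle (PsC), the astrocyte
process and soma, and the global extracellular space (GECS). The soma and
GECS are infinite reservoirs (clamped concentrations); the cradle wraps half
of the synapse, so its areas and volumes carry a factor ½. Five
concentrations are dynamic: [K⁺] and [Na⁺] in the PsC and PsECS, and
[Ca²⁺] in the PsC. The astrocyte membrane potential is fixed at
V_A = −80.7 mV (the cradle is isopotential with the astroglial syncytium);
the neurone is a Hodgkin–Huxley model in the rest-at-zero voltage frame.

### Pathways

All currents use one sign convention: positive = the ion leaves its source
compartment (neurone or cradle) for the PsECS; positive process currents
flow toward the soma; positive leak currents flow from the PsECS to the
GECS.

* **Neurone** (`neuron_currents()`): classic HH voltage-gated Na⁺ (m³h) and
  K⁺ (n⁴) channels, a leak, passive Nernst-driven K⁺/Na⁺ background
  channels, and an Na⁺/K⁺-ATPase (NKA) with Hill kinetics,
  `P = P_max (Na_i/(Na_i+K_Nai))³ (K_o/(K_o+K_KE))²`, exporting 3 Na⁺ per
  2 K⁺. Intraneuronal concentrations are constant.
* **EAAT1/2 glutamate transporter** (`eaat_update()`, `eaat_currents()`):
  each spike releases 1 mM of glutamate which binds instantaneously;
  the transporter flux state `J` then jumps by `J0 = 0.06` M/s and decays
  exponentially (`dJ/dt = −J/τ`), co-transporting 3 Na⁺ into the cradle and
  counter-transporting 1 K⁺ per glutamate. Events stack additively — the
  origin of the frequency-dependent Na⁺ load.
* **NCX** (`ncx_currents()`): exponential-ratio rate law
  `I = Ī[(Na_i/Na_o)³ e^{γFV/RT} − (Ca_i/Ca_o) e^{(γ−1)FV/RT}]·SA`,
  3 Na⁺ : 1 Ca²⁺, with `I_CaNCX = −⅔ I_NaNCX`. Positive current is reverse
  mode: Na⁺ out of the cradle, Ca²⁺ in.
* **Kir and background channels** (`kir_current()`,
  `astro_background_current()`): passive `g(V_A − E)` with valence-free
  Nernst potentials (the model's published convention; a `nernst_valence`
  option restores the z-divided form for sensitivity checks).
* **Astrocytic NKA** (`astro_nka_currents()`): same Hill form as the
  neurone's, driven by cradle Na⁺ and PsECS K⁺.
* **PsECS–GECS leak** (`ecs_leak_current()`): `g_iECS · (RT/F)
  ln([i]_PsECS/[i]_GECS) · SA`, the only pathway maintaining the cleft
  against neuronal and transporter load.
* **Process transport** (`poole_frenkel_current()`): the Poole–Frenkel
  current `K_i (ΔV/l) exp[−Q(φ_w − √(Q|ΔV|/(lπε)))/(k_B T)]·CSA_P` with
  ΔV = −Vr and `Vr = (RT/F) ln([i]_soma/[i]_PsC)`. With φ_w = 0.267 eV the
  zero-field Boltzmann factor is e⁻¹⁰ ≈ 4.5×10⁻⁵: the process passes
  orders of magnitude less current than the membrane, which is precisely
  why microdomains form.

### The five balance equations

`concentration_rhs()` assembles, with volumes in litres so `I/(zF·Vol)` is a
molar rate:

* d[K]PsC/dt = −(I_Kir + I_KNKA + I_KEAAT + I_KB + I_KPF)/(F·Vol_PsC)
* d[Na]PsC/dt = −(I_NaB + I_NaNKA + I_NaEAAT + I_NaNCX + I_NaPF)/(F·Vol_PsC)
* d[Ca]PsC/dt = −(I_CaNCX + I_CaPF)/(2F·Vol_PsC)
* d[K]PsECS/dt = (I_KNeu + I_Km − I_KECSL)/(F·Vol_PsECS)
* d[Na]PsECS/dt = (I_NaNeu + I_Nam − I_NaECSL)/(F·Vol_PsECS)

where I_im is the total astrocyte membrane current of ion *i* and I_iNeu the
total neuronal current. The astrocytic K⁺ background current appears in
both the cradle and PsECS balances (so K⁺ moles are conserved and the
background efflux can restore the cradle after stimulation); a
`k_background_in_psc = FALSE` option reproduces the stricter published
cradle balance that omits it.

## Calibration: making rest an equilibrium

The published parameter tables do not form a consistent resting state: at
the tabulated conductances and pump rates, several per-ion resting fluxes
are far from zero, and the naive one-parameter balances demand negative
conductances. `psc_calibrate()` therefore derives, once, a consistent rest:

* **EAAT decay constant.** τ = 3 mM / J0 = 50 ms, so the full-decay
  integral of one impulse moves exactly 3 mM of Na⁺ out of the PsECS (and,
  by stoichiometry, 1 mM of K⁺ back). The nominal 30 ms transporter cycle
  cannot carry 3 mM at J0 = 0.06 M/s (its ceiling is 1.8 mM), so the full
  integral is the only reading consistent with both numbers.
* **Astrocyte.** The tabulated maximal pump rate (10⁻⁶ mol m⁻² s⁻¹) is kept
  — it sets a resting Na⁺/K⁺ turnover of ~2.6 mM/s, low enough that the
  EAAT flux, not the pump's response to extracellular K⁺, dominates the
  stimulated Na⁺ balance (run the alternative and the cradle Na⁺ *falls*
  during stimulation). The Kir and K⁺ background conductances are scaled
  together (preserving their 8:1 ratio, so Kir remains the dominant K⁺
  channel) until resting channel efflux equals pump import, and the Na⁺
  background conductance is set from the Na⁺ balance.
* **Neurone.** The voltage-gated channels at their V = 0 fixed point leak
  Na⁺ in and K⁺ out; keeping the tabulated Na⁺ background conductance, the
  pump rate follows from the Na⁺ balance and the K⁺ background conductance
  from the K⁺ balance. With every ion-specific pathway closed, the leak
  must carry zero resting current, so its reversal is 0 V in this frame.
  The K⁺ channel reversal is the classic rest-frame −12 mV; the
  absolute-frame value printed in the source tables (−0.12 V) would put
  ~0.44 A/m² of standing K⁺ efflux on the membrane, and the pump and shunt
  needed to balance it abolish repetitive firing altogether.
* **Resting Ca²⁺.** The NCX is the cradle's only Ca²⁺ source and the
  process its only sink, so the resting [Ca²⁺]_PsC solves
  `I_CaNCX + I_CaPF = 0` — numerically 100.1 nM, the published initial
  value of 100 nM rounded. (This is also why V_A ≈ E_NCX at rest: the
  exchanger idles, and a Na⁺ microdomain of a few mM is enough to drive it
  into reverse.)

After calibration every per-ion resting flux is zero to ≈10⁻¹⁷ M/s
(`resting_flux_residuals()`), and an unstimulated simulation is flat to
numerical precision.

### The stimulus

The paper's protocol drives the neurone at 10, 20 and 30 Hz for one minute.
The calibrated HH neurone is a type II oscillator: under constant current
repetitive firing begins near 80 Hz, with depolarisation block close above
rheobase, so sustained 10–30 Hz firing is unreachable with a constant
waveform (the f–I scan is reproduced by
`calibrate_stimulus(p, 10, type = "constant")`, which raises a calibration
error carrying the measured bracket). The default protocol therefore uses a
train of 2 ms current pulses at the target rate; each pulse elicits exactly
one spike (1:1 entrainment), and `calibrate_stimulus()` bisects for the
smallest entraining amplitude and applies a 2× safety margin. Deterministic
spike-train fixtures (`generate_spike_train()`, stimulus type `"fixture"`)
drive the astrocyte without the neurone for tests and for the per-spike
EAAT accounting.

### The PsECS–GECS leak

The leak law is logarithmic in concentration, so a single conductance gives
different *molar* exchange rates for ions with different baselines: with
3.3 S/m² for both, K⁺ (4 mM) exchanges with τ ≈ 0.6 s but Na⁺ (135 mM) with
τ ≈ 19 s — slow enough that the transporter collapses the cleft Na⁺ pool to
~20 mM during stimulation, which blows up the cubic NCX ratio and
destabilises the 30 Hz protocol. The published law subscripts the
conductance per ion; the package keeps the tabulated 3.3 S/m² for K⁺ and
scales the Na⁺ conductance by the baseline-concentration ratio
(g_NaECS = 3.3 × 135/4 ≈ 111 S/m²) so both ions have the same diffusive
exchange coefficient. The cleft Na⁺ then shows the published behaviour: a
transient 10–15% loss at stimulation onset, maintained by the leak.

## Numerics

Forward Euler with a fixed Δt = 10 µs, exactly as in the source model; the
inner loop is compiled (Rcpp) and records states, all named currents, and a
running mole-conservation audit every `record_stride` steps (default 100,
i.e. 1 ms). Halving Δt changes protocol endpoints by ~3×10⁻⁶ relative, and
the endpoint error scales ~linearly in Δt as expected for an order-1
scheme. Glutamate events are applied on the same Euler step on which the
spike is detected (upward crossing of +50 mV above rest with a 2 ms
refractory guard). Concentrations are floored at 10⁻¹² M; any floor event
flags the run as non-physiological (none occur in the shipped protocols).
Identical configurations reproduce bit-identical results; the only random
element anywhere is the optional seeded jitter of fixture spike trains.

A pure-R reference stepper (`euler_step()`, `concentration_rhs()`) mirrors
the compiled loop and the test suite cross-checks the two paths to 10⁻¹⁰
relative, along with brute-force re-evaluations of the NCX rate law and the
consistency of its zero-crossing with the analytic equilibrium potential
`E_NCX = (3E_Na − 2E_Ca)/(3 − 2)`.

The test suite runs scaled-down protocols (2 s settle, 5–6 s stimulation,
up to 60 s recovery at Δt = 10 µs) so the whole suite completes in about a
minute; the full 0.1 min settle + 1 min stimulation + 1 min recovery
protocol at any of the three rates takes a few seconds of wall time and is
what the README example and the CLI run by default.

## What the simulations show — and what they do not

With the default calibration the protocol reproduces the model's headline
behaviour: extracellular K⁺ rises and is cleared into the cradle (K⁺
microdomain); EAAT-driven Na⁺ influx builds a cradle Na⁺ microdomain of
several mM; the NCX flips from its idle resting state into sustained
reverse mode during stimulation, importing Ca²⁺; the restricted process
efflux lets a Ca²⁺ microdomain form; and all three plateaus increase
strictly with stimulation frequency from 10 to 30 Hz.

Known limitations, inherent to the model rather than the implementation:

* There is no Ca²⁺ efflux pathway except the (severely restricted)
  process, so the Ca²⁺ microdomain grows steeply with stimulation rate; a
  plasma-membrane Ca²⁺ pump would be needed to bound it at high rates.
* The K⁺ microdomain decays slowly after stimulation: its clearance is
  rate-limited by the slow PsECS–GECS K⁺ leak, so ~60 s of recovery closes
  only ~84% of the K⁺ excursion (Na⁺ ~97%, Ca²⁺ ~99%). Raising the
  neuronal pump to clear the cleft faster would reabsorb the per-spike K⁺
  dump and abolish the K⁺ microdomain itself, so the slow recovery is a
  genuine property of this parameter set.
* Neuronal and somatic concentrations are clamped; glutamate, H⁺ and Cl⁻
  are not tracked; the EAAT flux does not depend on concentrations or
  voltage; the process is a lumped element, not a spatially resolved
  cable.
* The synthetic stimulation protocol (regular pulse trains, or regular
  fixture spike trains with optional uniform jitter) emulates sustained
  periodic firing only; irregular, bursty input and synaptic failures are
  not represented, so passing tests say nothing about responses to
  naturalistic spike statistics.

## Worked example

```{r example, eval = FALSE}
p <- psc_calibrate(psc_params())
p$protocol$t_settle <- 2
p$protocol$t_stim <- 6
p$protocol$t_post <- 0
sweep <- sweep_rates(p, c(10, 20, 30))
sweep[, c("rate_measured", "K_PsC_plateau", "Na_PsC_plateau",
          "Ca_PsC_plateau", "I_NaNCX_stim_density")]

sim <- run_protocol(p)      # single 10 Hz run
autoplot(sim)               # state time courses, stimulus window shaded
plot_microdomains(sim)      # cradle K+/Na+/Ca2+ only
write_timeseries(sim, "run10hz")
```
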