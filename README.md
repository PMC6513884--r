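# pscradle

Biophysical simulation of ion microdomain formation at the astrocytic
**perisynaptic cradle** (PsC) — the thin glial sheet that enwraps a synapse —
and of the reversal of the Na⁺/Ca²⁺ exchanger (NCX) that turns a sodium
microdomain into a local calcium signal.

## The science

Cations leaving the cradle for the astrocyte soma must travel a ~25 µm thin
process whose membrane carries fixed negative charges. They escape the
resulting potential wells only by field-assisted hopping, with a
Poole–Frenkel current

$$I_{iPF} = K_i \frac{\Delta V}{l}\,
\exp\!\left[-\frac{Q\left(\phi_w - \sqrt{Q\,|\Delta V|/(l\pi\epsilon)}\right)}{k_B T}\right] CSA_P,
\qquad \Delta V = -\frac{RT}{F}\ln\frac{[i]_{soma}}{[i]_{PsC}},$$

which at φ_w = 0.267 eV passes ~4.5 × 10⁻⁵ of the equivalent ohmic current.
The cradle is therefore semi-isolated: ions imported across its membrane
accumulate as **microdomains**. A Hodgkin–Huxley presynaptic neurone fires at
a commanded rate; each spike releases 1 mM glutamate, which the EAAT1/2
transporters absorb with an impulse-decay flux (3 Na⁺ in, 1 K⁺ out per
glutamate; 3 mM Na⁺ per spike). The rising cradle Na⁺ drives the 3:1 NCX

$$I_{NaNCX} = \bar I_{NCX}\left[\left(\frac{[Na]_{PsC}}{[Na]_{PsECS}}\right)^{3}
e^{\gamma F V_A/RT} - \frac{[Ca]_{PsC}}{[Ca]_{PsECS}}\,
e^{(\gamma-1) F V_A/RT}\right] SA_{PsC}$$

past its equilibrium potential $E_{NCX} = (3E_{Na} - 2E_{Ca})/(3-2) \approx
-87\ \mathrm{mV} \approx V_A$, flipping it into reverse mode: Na⁺ is
exported and Ca²⁺ imported, and — because the process also restricts Ca²⁺
efflux — a Ca²⁺ microdomain forms without any ER involvement.

The package is for computational neuroscientists and glial physiologists who
want a tested, deterministic re-implementation of this six-compartment model:
every pathway is an exported, documented R function; the full forward-Euler
integration (Δt = 10 µs) runs in a compiled inner loop; results come back as
tibbles with broom-style `tidy()`/`glance()` and ggplot2 `autoplot()`.

## Worked example

```r
library(pscradle)

p <- psc_calibrate(psc_params())   # derive the consistent resting state
p$protocol$t_settle <- 2           # short protocol: 2 s settle, 6 s stimulus
p$protocol$t_stim <- 6
p$protocol$t_post <- 0

sweep_rates(p, c(10, 20, 30))[, c("rate_measured", "K_PsC_plateau",
                                  "Na_PsC_plateau", "Ca_PsC_plateau",
                                  "I_NaNCX_stim_density")]
#> # A tibble: 3 × 5
#>   rate_measured K_PsC_plateau Na_PsC_plateau Ca_PsC_plateau I_NaNCX_stim_density
#>           <dbl>         <dbl>          <dbl>          <dbl>                <dbl>
#> 1         10.00         0.128         0.0211    0.000000508             0.000135
#> 2         20.0          0.161         0.0268    0.00000251              0.000288
#> 3         30.0          0.199         0.0335    0.0000140               0.000496
```

Reading: driven at 10/20/30 Hz (measured rates in column 1), the cradle K⁺
plateau rises from its 100 mM baseline to 128–199 mM and Na⁺ from 15 mM to
21–34 mM; the Ca²⁺ microdomain grows from the 100 nM resting level to
0.5–14 µM; and the stimulated NCX current density is positive
(reverse mode, Ca²⁺-importing) and grows with rate, versus ~10⁻⁷ A/m² at
rest. All three microdomains increase monotonically with firing frequency.

For one run in full detail:

```r
sim <- run_protocol(p)       # 10 Hz pulse-train stimulus
glance(sim)                  # plateau summary, audits, spike count
autoplot(sim)                # faceted state time courses
write_timeseries(sim, "run10hz")   # run10hz.csv + run10hz.json
```

A command-line interface wrapping the same functions ships in
`inst/cli/pscradle.R` (`run`, `calibrate`, `sweep`, `summarize`
subcommands); model parameters can be supplied as a YAML config whose
defaults file is `inst/extdata/default-config.yaml`.

## Model notes

The published parameter tables do not, by themselves, form a consistent
resting state; `psc_calibrate()` derives background conductances, pump
rates, the EAAT decay constant (τ = 50 ms so one spike moves exactly 3 mM
Na⁺) and the resting Ca²⁺ (the joint NCX–process equilibrium, 100.1 nM)
so that every per-ion resting flux is exactly zero. The methods vignette
(`vignettes/perisynaptic-cradle-model.Rmd`) documents each calibration
choice, the sign conventions, the numerical scheme and the model's known
limitations.
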