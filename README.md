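# epgx

Extended phase graphs for coupled two-compartment spin systems — chemical
exchange (Bloch-McConnell) and pulsed magnetization transfer (MT) — as an R
simulation library for quantitative MRI.

## Who this is for

Single-pool extended phase graphs (EPG) are the workhorse for simulating
multi-pulse MRI sequences, but many tissues are two-compartment systems:
myelin water exchanging with intra/extra-axonal water, or free water coupled
to a semisolid bound pool whose ~10 µs T2 makes it invisible yet strongly
felt through magnetization transfer. `epgx` evolves one phase graph per
compartment and couples them during evolution periods, which makes transient
(non-steady-state) sequences — multi-echo CPMG relaxometry, fingerprinting-
style variable-flip trains, multislice turbo spin echo — simulable with
exchange and MT included. It is aimed at people building relaxometry
pipelines, MT-aware dictionaries, or sequence parameter optimizations.

## The formalism in brief

Intravoxel magnetization is carried by configuration states
F̃ₙ (transverse) and Z̃ₙ (longitudinal) per compartment,
M₊(ψ) = Σₙ F̃ₙ e^{inψ}; the signal is F̃₀. Between pulses, relaxation and
exchange act together through matrix exponentials of

    Λ_T = [ −R₂ₐ−kₐ      k_b          ]      Λ_L = [ −R₁ₐ−kₐ    k_b     ]
          [  kₐ          −R₂_b−k_b−2πiδ_b ]        [  kₐ       −R₁_b−k_b ]

per state pair (exchange couples only equal type and order), with
longitudinal recovery entering the order-0 update only, and k_b = kₐ(1−f)/f
from detailed balance. RF pulses mix (F̃ₙ, F̃₋ₙ*, Z̃ₙ) with the standard 3×3
transition matrix; in the MT variant the bound pool has no transverse states
and every Z̃ₙᵇ is scaled by exp(−π γ² E G(Δ)), where E is the pulse energy
∫B₁²dt and G the absorption lineshape (super-Lorentzian by default).
Brute-force isochromat integration of the same equations is included and
agrees with the phase-graph computation to the double-precision floor once
the ensemble resolves every populated order.

## Worked example

```r
library(epgx)

wm <- tissue_preset("wm_mt")        # white-matter MT model (1.5 T)
wm
#> two-pool magnetization-transfer model
#>   T1a = 779 ms, T1b = 779 ms, T2a = 45 ms
#>   T2b = 12 us (super_lorentzian lineshape)
#>   ka = 4.3 s^-1, f = 0.117, M0 = 1, T1obs = 779 ms

# exchange bias of myelin-water imaging: simulate a 50-echo CPMG train of
# the myelin-water exchange model (true f = 0.2, ka = 2 s^-1) with a 10%
# transmit-field error, then analyze it the classical way
myelin <- tissue_preset("myelin_bm")
ec <- simulate_cpmg(myelin, n_echoes = 50, esp = 5, b1_scale = 1.1)
nnls_t2_spectrum(ec$echoes, ec$echo_times)
#> t2_spectrum: 120 grid points, 2 peak(s), f_hat = 0.1329, t2b_hat = 20 ms
```

The estimated myelin-water fraction is 0.133 against a true 0.2: moderate
exchange alone produces a ~33% underestimate, while the short-component T2
(20 ms) is recovered. With `ka = 0` the analysis returns f̂ = 0.2.

```r
# MT attenuation in multislice TSE: other slices act as off-resonant
# saturation of the bound pool (180-degree protocol, 25 echoes, TR 5 s)
ms1  <- multislice_tse(wm, n_slices = 1)
ms15 <- multislice_tse(wm, n_slices = 15)
100 * (1 - ms15$mean_echo / ms1$mean_echo)
#> 33.8   # percent signal loss for white matter; a CSF-like single-pool
         # model shows exactly none
```

A command-line front end is in `exec/epgx`
(`epgx simulate|steady-state|cpmg|multislice`), driven by YAML configs; see
`vignettes/epgx-methods.Rmd` for the model, operator conventions and design
decisions.

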