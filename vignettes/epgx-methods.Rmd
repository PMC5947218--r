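---
title: "Two-compartment extended phase graphs: models, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment extended phase graphs: models, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgx)
```

## The problem

The extended phase graph (EPG) algorithm represents the intravoxel
magnetization produced by a train of RF and gradient pulses as discrete
Fourier "configuration states": transverse states $\tilde F_n$ and
longitudinal states $\tilde Z_n$, where $n$ indexes the gradient-induced
intravoxel phase $\psi$ accrued per repetition interval,

$$M_+(\psi) = \sum_n \tilde F_n e^{in\psi}, \qquad
  M_z(\psi) = \sum_n \tilde Z_n e^{in\psi},$$

and the measurable signal is the voxel average of $M_+$, i.e. $\tilde F_0$.
Classic EPG assumes a single pool with one $(T_1, T_2)$. Biological tissues
are better described by coupled two-compartment models: a general
Bloch-McConnell (BM) system of two exchanging water pools (e.g. myelin water
and intra/extra-axonal water), or the pulsed magnetization-transfer (MT)
system of a free water pool coupled to a semisolid "bound" pool whose
$T_2 \sim 10\,\mu s$ is too short to support observable transverse
magnetization.

This package evolves one phase graph per compartment and couples them during
the evolution periods. Exchange conserves type and order: $\tilde F_n^a
\leftrightarrow \tilde F_n^b$ and $\tilde Z_n^a \leftrightarrow \tilde
Z_n^b$ only. In the MT variant the bound pool carries only $\tilde Z_n^b$
states, and RF pulses saturate them directly instead of rotating them.

## Operators

**Relaxation and exchange** act simultaneously and do not commute, so they
are exponentiated together. Between pulses the transverse states of a BM
system evolve under

$$\Lambda_T = \begin{pmatrix} -R_{2a}-k_a & k_b \\ k_a & -R_{2b}-k_b-2\pi i
\delta_b \end{pmatrix}$$

per $(\tilde F_n^a, \tilde F_n^b)$ pair (the conjugate pair evolves under the
conjugate matrix), and longitudinal states under the real matrix $\Lambda_L$
with recovery $C = (R_{1a} M_0^a, R_{1b} M_0^b)$ entering only the order-0
update, $Z_0 \mapsto e^{\Lambda_L \Delta t} Z_0 + (e^{\Lambda_L \Delta t} -
I)\Lambda_L^{-1} C$. Every propagator in the package is therefore a 2x2
exponential, which `epgx` computes by the exact closed form
$e^{\mu}(\cosh q\, I + \tfrac{\sinh q}{q}(A - \mu I))$ with $\mu =
\mathrm{tr}(A)/2$, $q^2 = \mu^2 - \det A$ (series expansion of
$\cosh$, $\sinh(q)/q$ for $|q| < 10^{-5}$). Tests check these against an
independent scaling-and-squaring Taylor exponential to $10^{-12}$.

The pool-b frequency offset $\delta_b$ lives inside $\Lambda_T$, not in the
gradient shift: the shift operator stays pure integer bookkeeping
($\tilde F_n \to \tilde F_{n+1}$, with the new $\tilde F_0$ refilled by
conjugation from the $\tilde F_{-1}$ rung). Exchange rates are accepted in
s^-1 — the unit of every published tissue table — and converted exactly once
(`derived_rates()`); all internal times are milliseconds. The reverse rate
follows from detailed balance $k_b = k_a (1-f)/f$, so equilibrium
$(M_0^a, M_0^b) = ((1-f) m_0, f m_0)$ is a fixed point of the longitudinal
update (a property test).

**RF pulses** mix $(\tilde F_n, \tilde F_{-n}^*, \tilde Z_n)$ at every order
with the standard 3x3 transition matrix; in BM mode both pools are rotated
identically (the pulse bandwidth is assumed large compared with $\delta_b$).
In MT mode the bound pool's every $\tilde Z_n^b$ is multiplied by
$e^{-\bar W \tau_{rf}}$, with the mean saturation rate taken in the pulsed-MT
(mean-square-$B_1$) convention

$$\bar W \tau_{rf} = \pi \gamma^2 \left(\int_0^{\tau_{rf}} B_1^2\,dt\right)
G(\Delta),$$

so the applied factor depends only on pulse *energy* (ms uT^2) and the
absorption lineshape at the pulse offset — not on the pulse shape or
duration. $\gamma = 267.5221$ rad s^-1 uT^-1. Applying the factor at every
order (not just order 0) follows from the block form of the transition
matrix, which acts per order.

**Super-Lorentzian lineshape.** $G(\Delta)$ is integrated adaptively over
fiber orientation (relative tolerance $10^{-8}$). The kernel is singular at
zero offset, so values inside an exclusion band are interpolated by a cubic
spline fit through densely sampled points outside it (100 Hz spacing to
10 kHz, 500 Hz to 100 kHz, mirrored). The band half-width matters: with a
1 kHz band the spline reaches $G(0) \approx 17.4\,\mu s$ for
$T_{2b} = 12\,\mu s$, whereas the value used throughout the quantitative-MT
literature for this $T_{2b}$ is $15.1\,\mu s$, which the spline reproduces
with a 1.5 kHz band. The default is therefore `cutoff_hz = 1500` (exposed as
an argument). Computed splines are cached per $(T_{2b},$ cutoff$)$.

## Sequence engines and conventions

`simulate_train()` runs any equidistant train: RF (with saturation in MT
mode), record the demodulated $\tilde F_0$, relax-exchange, shift (0 or more
cycles), optional diffusion. Conventions, chosen once:

* **Observable signal.** BM systems are two *water* pools: the observed
  signal is $\tilde F_0^a + \tilde F_0^b$ (only the total is measurable);
  MT systems observe the free pool only. Per-pool traces are always
  returned, and normalization of MT signals by the visible fraction $(1-f)$
  is an explicit helper (`normalize_signal()`), never silent.
* **Sampling.** SPGR samples immediately after the pulse ($TE \approx 0$),
  with an optional `te` argument that applies the transverse
  relaxation-exchange propagator over the echo time. bSSFP samples at
  $TR/2$.
* **RF spoiling** uses the quadratic schedule $\phi_j = \Phi_0 j(j+1)/2$ and
  receiver demodulation by $e^{-i\phi_j}$. The ideally spoiled steady-state
  solver (`spgr_steady_state()`) is the $\Phi_0$-independent reference;
  transient signals at well-spoiled increments (e.g. 117 degrees) approach
  it but finite-$\Phi_0$ signals need not equal it. `simulate_train()` has a
  `perfect_spoil` mode (transverse zeroed each TR) whose converged value
  matches the solver to better than 0.1%.
* **bSSFP off-resonance.** For a balanced sequence, off-resonance
  precession per TR accumulates exactly like gradient dephasing, so the
  off-resonance profile is obtained by running the train with one
  configuration-order increment per TR and evaluating the Fourier series at
  echo time (`bssfp_profile()`), with the extra half-interval phase
  $e^{i\psi/2}$. The direct solver (`bssfp_steady_state()`) composes the
  two-pulse period map of the order-0 state vector and solves the linear
  fixed point; both routes agree to 0.1% over a 64-point $\psi$ grid for
  all model classes, including the asymmetric profile produced by
  $\delta_b \neq 0$. On resonance the MT solver also matches an
  independently derived real 3-variable closed form
  (`mt_bssfp_analytic()`).
* **CPMG** uses excitation about x, refocusing about y, and the
  transmit-field scale multiplies *all* flips (a transmit error scales the
  whole train). Half-interval relaxation-exchange-shift flanks each
  refocusing pulse; echoes are read at order 0.
* **Diffusion** attenuates each order with the constant-gradient b-factors
  ($b_T \propto (n+\tfrac12)^2 + \tfrac1{12}$, $b_L \propto n^2$), applied
  identically to both compartments with a single shared coefficient. The
  default gradient moment corresponds to one dephasing cycle across a
  1.5 mm voxel; it is a configuration value, not an asserted one.

**Multislice TSE.** From the center slice's point of view, acquisition of
every other slice is a train of pulses with zero flip for the free pool but
full bound-pool saturation at the inter-slice frequency offset. Timing
proved *not* to be negligible: packing all foreign-slice saturation
immediately after the center readout lets the free pool recover over the
long dead time (about 3% attenuation at 15 slices), packing it immediately
before gives about 44%, and a packed odd-even order makes the predicted
attenuation non-monotone in slice count because the center slice's position
in the order flips parity. The engine therefore uses the standard scanner
timing — slice blocks distributed evenly over the TR, each filling a
$TR/n_{slices}$ slot, odd-even interleaved order — which yields a smooth,
monotone attenuation: 34% for the white-matter model at 15 slices (180
degree protocol), weaker for caudate nucleus and for the 120-degree
protocol, and exactly zero for a single-pool (CSF-like) tissue. Three TR
periods suffice to reach the periodic steady state.

**Fingerprinting-style trains.** `mrf_train()` prepends a perfect inversion
of the free pool (bound pool saturated with 433 ms uT^2) to 256 pulses of
12 ms TR whose flips follow sinusoidal lobes repeating every 32 pulses with
16 distinct amplitudes including zero (`sin(pi j / 31)` sampling; the peak
flip, 50 degrees by default, is a free design choice — no analysis here
depends on the exact lobe shape). Readout energies are $54.3\,\alpha^2$
ms uT^2. Zero-flip intervals keep the constant per-TR gradient area, so
states shift and relax through them.

## Relaxometry analyses

**NNLS T2 spectroscopy.** `nnls_t2_spectrum()` solves the nonnegative
exponential fit with the Lawson-Hanson algorithm (`pracma::lsqnonneg`), no
regularization. The T2 grid is 120 points log-spaced over 5 ms - 2 s;
estimates move by less than 0.01 in $\hat f$ between 80 and 200 points
(tested). Peaks are the two largest local maxima, split at the
minimum-amplitude point between them; the small-pool fraction $\hat f$ is
the fractional area of the shorter-T2 peak and $\hat T_{2,b}$ its
amplitude-weighted geometric-mean T2 (the estimator had to be chosen; the
geometric mean respects the log grid). For the myelin-water model with
exchange $k_a = 2$ s^-1 and transmit scale 1.1, the analysis returns
$\hat f = 0.133$ against a true $f = 0.2$ — exchange alone produces a 33%
underestimate of the myelin-water fraction — while $k_a = 0$ recovers
$\hat f = 0.2$. The bias surface (`bias_surface()`) shows $\hat f$ driven
mainly by $k_a$ (and measurably by $\delta_b$), $\hat T_{2,b}$ mainly by
the transmit scale.

**Constrained MT fitting.** `fit_epgx_mt()` fits $(k_a, T_{1a}, T_{1b}, f,
G_0)$ to the magnitudes of two RF-spoiled transients acquired with
different spoiling increments (150 and 117 degrees), with $T_{2a}$,
diffusion and overall scale fixed at measured values. Consistency with a
separately measured inversion-recovery $T_1^{obs}$ is enforced *exactly* by
elimination: the bi-exponential eigenvalue relation is linear in $R_{1a}$,
so $T_{1a}$ is solved in closed form from $(k_a, T_{1b}, f)$ and
$T_1^{obs}$ (`t1a_from_observed()`), and Levenberg-Marquardt runs over the
remaining four parameters from three deterministic starts. A soft penalty
formulation was tried first and abandoned: it left the optimizer in local
minima even on noiseless self-generated data, while elimination recovers
the generating parameters to machine precision. On synthetic data generated
from the two-pool parameter set $(k_a = 6.2$ s^-1, $T_{1a} = 1763$ ms,
$T_{1b} = 363$ ms, $f = 0.100$, $G_0 = 29.4\,\mu s)$ — which implies
$T_1^{obs} = 1283$ ms — the fit is exact, whereas the single-pool control
fit (varying $T_1$ only, `fit_single_pool()`) leaves residuals concentrated
immediately after the inversion, where bi-exponential recovery departs most
from mono-exponential behavior.

Two conventions for the small-pool residence time coexist in the
literature: $\tau_b = f/(k_a(1-f)) = 1/k_b$ and $\tau_b = f/k_a$ (they
differ by $(1-f)$: 125 vs 100 ms for the myelin model). `residence_time()`
reports both; everything else is parameterized by $k_a$ directly.

## Validation strategy

The package's correctness case rests on independent routes agreeing:

1. **Isochromat oracle.** `simulate_isochromats()` integrates the coupled
   equations directly for an ensemble of dephasing angles on a midpoint grid
   over $[-\pi, \pi]$ (midpoints avoid double-counting $\pm\pi$) and
   averages $M_+$. For a train of $P$ pulses and $n_{iso} \ge P$ the
   ensemble mean equals the phase-graph $\tilde F_0$ *exactly* (RMS
   difference at the double-precision floor, $\sim 10^{-16}$ in practice;
   asserted $\le 10^{-12}$), because all populated orders stay below the
   ensemble's aliasing limit; at $n_{iso} = 30$ the deviation is orders of
   magnitude larger.
2. **Steady-state fixed points** against converged transients (above).
3. **Analytic limits**: Ernst formula, classical bSSFP closed form,
   weighted sums of single-pool results for $k_a = 0$, pure $T_2$ decay for
   ideal CPMG, bi-exponential echoes for decoupled pools, and the textbook
   single-pool EPG implementation kept in the test helpers.

## What the synthetic data do and do not show

The synthetic-signal generator (`synth_signal()`) adds complex white
Gaussian noise of a stated SNR (defined relative to the mean signal
magnitude) to an exact forward simulation, deterministically per seed.
Passing tests therefore demonstrate internal consistency of the formalism
and correct recovery when the forward model is true. They do not probe:
slice profiles (pulses are ideal rotations plus lumped saturation),
$B_0$/$B_1$ maps, Rician magnitude bias at low SNR, more than two
compartments, compartment-specific diffusion coefficients (supported as
configuration but physically unvalidated), or CEST-type long-pulse
saturation, which a sequence-level formalism cannot represent.

## Numerical and degenerate-input choices

* State arrays default to one order per pulse (lossless); a smaller
  `order_max` truncates with a warning and a `dropped` counter.
* `relaxation_exchange()` handles a singular $\Lambda_L$ (all rates zero)
  through a series evaluation of the recovery integral instead of a matrix
  inverse.
* $f = 0$ is allowed only with $k_a = 0$ (pool b absent; $k_b$ undefined
  otherwise) and reproduces single-pool operators exactly.
* The conjugate-symmetry invariant $\tilde F_{-0}^* = \overline{\tilde F_0}$
  is maintained by construction and asserted to $10^{-12}$ along entire
  simulations.
* Problem sizes used by the test suite and the acceptance analyses: trains
  of 40-1000 pulses, 50-echo CPMG, 64-point profile grids, three TR periods
  of multislice TSE, 128-257-pulse fitting problems — all chosen as the
  smallest sizes at which the corresponding analyses are converged (e.g.
  transients run to $5\,T_1$, where the per-TR change is below $10^{-8}$).

## Known limitations

Equidistant timing only (variable gradient moments would need the
continuous-Fourier formulation); two compartments; a single shared
diffusion coefficient by default; no fitting of Gaussian lineshapes to data
(the Gaussian is available as a closed-form alternative only); the
multislice engine models saturation, not physical slice cross-talk (which
the CSF invariance check shows is absent by construction).
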