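# Sequence descriptions and engines: SPGR, bSSFP, fingerprinting-style
# variable flip-angle trains, CPMG and multislice TSE.

#' Pulse-train description
#'
#' A sequence of RF pulses with equidistant timing. Per-pulse vectors are
#' recycled from scalars. RF phases may be given explicitly or generated from
#' a quadratic spoiling schedule `phi_j = phi0 j (j + 1) / 2` (`j` counted
#' from 0) via `spoil_increment`.
#'
#' @param flips flip angles (rad).
#' @param phases RF phases (rad); defaults to the quadratic schedule when
#'   `spoil_increment` is given, else 0.
#' @param energies pulse energies `integral(B1^2 dt)` (ms uT^2); drive bound-
#'   pool saturation in MT mode, ignored otherwise.
#' @param durations pulse durations (ms, informational).
#' @param offsets per-pulse irradiation offsets (Hz); 0 = on-resonance.
#' @param tr inter-pulse interval (ms), `> 0`.
#' @param dephasing_cycles integer gradient dephasing per interval in cycles
#'   (0 for balanced sequences, 1 for a standard unbalanced gradient).
#' @param spoil_increment quadratic RF-spoiling increment (rad), optional.
#' @return an object of class `pulse_train`.
#' @export
pulse_train <- function(flips, phases = NULL, energies = 0, durations = 0,
                        offsets = 0, tr, dephasing_cycles = 1,
                        spoil_increment = NULL) {
  n <- length(flips)
  if (n < 1) stop("empty pulse train")
  if (tr <= 0) stop("'tr' must be positive")
  if (is.null(phases)) {
    phases <- if (is.null(spoil_increment)) rep(0, n) else {
      j <- seq_len(n) - 1
      spoil_increment * j * (j + 1) / 2
    }
  }
  energies <- recycle_to(energies, n, "energies")
  if (any(energies < 0)) stop("'energies' must be >= 0")
  structure(
    list(flips = flips, phases = recycle_to(phases, n, "phases"),
         energies = energies, durations = recycle_to(durations, n, "durations"),
         offsets = recycle_to(offsets, n, "offsets"), tr = tr,
         dephasing_cycles = as.integer(dephasing_cycles),
         spoil_increment = spoil_increment),
    class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("pulse_train: %d pulses, TR = %g ms, dephasing %d cycle(s)/TR\n",
              length(x$flips), x$tr, x$dephasing_cycles))
  cat(sprintf("  flips %.3g..%.3g deg, max energy %.3g ms uT^2\n",
              min(x$flips) * 180 / pi, max(x$flips) * 180 / pi,
              max(x$energies)))
  invisible(x)
}

#' RF-spoiled gradient-echo pulse train
#'
#' Constant flip angle with quadratic RF-spoiling phases and one dephasing
#' cycle per TR. Pulse energies, needed for bound-pool saturation in MT mode,
#' default to hard pulses of amplitude `b1_ut`.
#'
#' @param tr repetition time (ms).
#' @param alpha flip angle (rad).
#' @param phi0 quadratic spoiling phase increment (rad).
#' @param n_pulses number of pulses.
#' @param b1_ut hard-pulse amplitude used to derive pulse energies (uT); set
#'   `energies` to override.
#' @param energies per-pulse energies (ms uT^2), overriding `b1_ut`.
#' @return a [pulse_train()].
#' @export
spgr_sequence <- function(tr = 5, alpha = 10 * pi / 180,
                          phi0 = 117 * pi / 180, n_pulses,
                          b1_ut = 13.5, energies = NULL) {
  if (is.null(energies)) energies <- as.numeric(hard_pulse_energy(alpha, b1_ut))
  pulse_train(flips = rep(alpha, n_pulses), energies = energies, tr = tr,
              dephasing_cycles = 1, spoil_increment = phi0)
}

#' Balanced SSFP pulse train
#'
#' Constant flip with alternating 0/pi phases and zero net dephasing per TR.
#'
#' @inheritParams spgr_sequence
#' @return a [pulse_train()].
#' @export
bssfp_sequence <- function(tr = 5, alpha = 10 * pi / 180, n_pulses,
                           b1_ut = 13.5, energies = NULL) {
  if (is.null(energies)) energies <- as.numeric(hard_pulse_energy(alpha, b1_ut))
  pulse_train(flips = rep(alpha, n_pulses),
              phases = rep(c(0, pi), length.out = n_pulses),
              energies = energies, tr = tr, dephasing_cycles = 0)
}

#' Fingerprinting-style variable flip-angle train
#'
#' An adiabatic inversion (modeled as a perfect 180 on the free pool with a
#' large saturation energy on the bound pool) followed by `n_pulses` low
#' flip-angle pulses whose amplitude follows sinusoidal lobes repeating every
#' 32 pulses and taking 16 distinct values including zero; zero-flip
#' intervals allow free recovery but keep the constant per-TR gradient area,
#' so states still shift and relax. Pulse energies scale with the squared
#' flip angle.
#'
#' @param n_pulses number of readout pulses after the inversion.
#' @param tr repetition time (ms).
#' @param flip_max peak flip angle (rad).
#' @param phi0 quadratic spoiling increment for the SPGR variant (rad).
#' @param variant `"spgr"` (quadratic spoiling, unbalanced gradient) or
#'   `"bssfp"` (alternating phase, balanced).
#' @param inversion include the inversion pulse (flip pi, energy
#'   `inv_energy`) as the first entry.
#' @param inv_energy inversion pulse energy (ms uT^2).
#' @param energy_coef readout pulse energy coefficient: energy =
#'   `energy_coef * alpha^2` ms uT^2.
#' @return a [pulse_train()]; the inversion, when present, is pulse 1.
#' @export
mrf_train <- function(n_pulses = 256, tr = 12, flip_max = 50 * pi / 180,
                      phi0 = 150 * pi / 180,
                      variant = c("spgr", "bssfp"), inversion = TRUE,
                      inv_energy = 433, energy_coef = 54.3) {
  variant <- match.arg(variant)
  j <- seq_len(n_pulses) - 1
  # sinusoidal lobes repeating every 32 pulses; sampling sin(pi j / 31)
  # yields exactly 16 distinct amplitudes per lobe, including zero
  flips <- flip_max * sin(pi * (j %% 32) / 31)
  if (variant == "spgr") {
    phases <- phi0 * j * (j + 1) / 2
    deph <- 1L
  } else {
    phases <- rep(c(0, pi), length.out = n_pulses)
    deph <- 0L
  }
  energies <- energy_coef * flips^2
  if (inversion) {
    flips <- c(pi, flips)
    phases <- c(0, phases)
    energies <- c(inv_energy, energies)
  }
  pulse_train(flips = flips, phases = phases, energies = energies, tr = tr,
              dephasing_cycles = deph)
}

# MT saturation exponents for every pulse of a train
train_sat_exponents <- function(model, train) {
  g <- numeric(length(train$offsets))
  on <- train$offsets == 0
  if (any(on)) g[on] <- mt_g0(model)
  if (any(!on)) {
    g[!on] <- lineshape_value(train$offsets[!on], model$t2b_us,
                              kind = model$lineshape)
  }
  saturation_exponent(train$energies, g)
}

#' Simulate a pulse train with EPG-X
#'
#' Runs two coupled phase-graph calculations (one per compartment) through a
#' pulse train: at each pulse the RF transition block is applied (with
#' bound-pool saturation from the pulse energy and offset in MT mode), the
#' demodulated order-0 transverse state is recorded, then the combined
#' relaxation-exchange propagator and the gradient shift act, with optional
#' per-order diffusion attenuation. For Bloch-McConnell models the observable
#' signal is the sum over both water pools; for MT models it is the free
#' pool.
#'
#' @param model an `epgx_model`.
#' @param train a [pulse_train()].
#' @param order_max highest retained configuration order; defaults to
#'   `n_pulses * max(1, dephasing_cycles) + 1` (lossless).
#' @param diffusion optional [diffusion_spec()].
#' @param te optional echo time (ms): recorded signals are decayed from the
#'   pulse by the transverse relaxation-exchange propagator over `te`.
#' @param perfect_spoil if `TRUE`, transverse states are zeroed before every
#'   pulse (ideal spoiling), giving the spoiled steady state exactly.
#' @return an object of class `epgx_signal`: `times` (ms), complex
#'   demodulated `signal`, per-pool `signal_a`/`signal_b`, longitudinal
#'   order-0 traces `z0_a`/`z0_b`, the final `state`, and `state_last_pulse`
#'   (the state immediately after the final RF pulse, used for off-resonance
#'   profile reconstruction).
#' @examples
#' wm <- epgx_mt_model(779, 779, 45, 12, 4.3, 0.117)
#' sig <- simulate_train(wm, spgr_sequence(n_pulses = 200))
#' utils::tail(Mod(sig$signal))
#' @export
simulate_train <- function(model, train, order_max = NULL, diffusion = NULL,
                           te = NULL, perfect_spoil = FALSE) {
  stopifnot(inherits(model, "epgx_model"), inherits(train, "pulse_train"))
  mode <- model_mode(model)
  P <- length(train$flips)
  cyc <- train$dephasing_cycles
  if (is.null(order_max)) order_max <- P * max(1L, cyc) + 1L
  st <- epgx_state(model, order_max)
  prop <- relaxation_exchange(model, train$tr)
  prop_te <- if (!is.null(te)) relaxation_exchange(model, te) else NULL
  wsat <- if (mode == "mt") train_sat_exponents(model, train) else numeric(P)
  do_diff <- !is.null(diffusion) && diffusion$enabled && cyc >= 1
  sig_a <- sig_b <- complex(P)
  z0a <- z0b <- complex(P)
  st_last <- NULL
  for (j in seq_len(P)) {
    if (perfect_spoil) {
      st$fplus_a[] <- 0 + 0i
      st$fminus_a[] <- 0 + 0i
      if (mode == "bm") {
        st$fplus_b[] <- 0 + 0i
        st$fminus_b[] <- 0 + 0i
      }
    }
    st <- state_rf(st, train$flips[j], train$phases[j],
                   zb_scale = exp(-wsat[j]))
    s <- state_signal(st)
    if (!is.null(prop_te)) {
      if (mode == "bm") {
        v <- prop_te$xi_p %*% c(s$a, s$b)
        s$a <- v[1]
        s$b <- v[2]
      } else {
        s$a <- s$a * prop_te$xi_t
      }
    }
    dem <- exp(-1i * train$phases[j])
    sig_a[j] <- s$a * dem
    sig_b[j] <- s$b * dem
    z0a[j] <- st$z_a[1]
    z0b[j] <- if (mode == "single") 0 else st$z_b[1]
    if (j == P) st_last <- st
    if (any(!is.finite(c(Re(st$fplus_a), Re(st$z_a))))) {
      stop(sprintf("non-finite state after pulse %d", j))
    }
    st <- state_relax(st, prop)
    if (do_diff) {
      st <- state_diffuse(st, diffusion$d, diffusion$k1_rad_mm, train$tr, cyc)
    }
    if (cyc >= 1) for (k in seq_len(cyc)) st <- shift_once(st)
  }
  if (st$dropped > 0) {
    warning(sprintf("%d nonzero state(s) truncated beyond order_max = %d",
                    st$dropped, order_max))
  }
  total <- if (mode == "bm") sig_a + sig_b else sig_a
  structure(
    list(times = (seq_len(P) - 1) * train$tr + if (is.null(te)) 0 else te,
         signal = total, signal_a = sig_a,
         signal_b = if (mode == "bm") sig_b else NULL,
         z0_a = z0a, z0_b = if (mode == "single") NULL else z0b,
         state = st, state_last_pulse = st_last, mode = mode, train = train),
    class = "epgx_signal")
}

#' @export
print.epgx_signal <- function(x, ...) {
  cat(sprintf("epgx_signal (%s): %d samples, |signal| %.4g..%.4g\n",
              x$mode, length(x$signal), min(Mod(x$signal)),
              max(Mod(x$signal))))
  invisible(x)
}

#' @export
as.data.frame.epgx_signal <- function(x, ...) {
  data.frame(time_ms = x$times, re = Re(x$signal), im = Im(x$signal),
             mag = Mod(x$signal))
}

#' Normalize an observed signal by the visible pool size
#'
#' For MT models the bound pool is invisible, so comparisons against
#' single-pool signals are sometimes presented normalized by `(1 - f)`. The
#' normalization is explicit, never applied silently.
#'
#' @param series an `epgx_signal`.
#' @param model the model that generated it.
#' @return the series with `signal`, `signal_a` divided by `(1 - f)`.
#' @export
normalize_signal <- function(series, model) {
  stopifnot(inherits(series, "epgx_signal"), inherits(model, "epgx_model"))
  scl <- 1 - model$f
  series$signal <- series$signal / scl
  series$signal_a <- series$signal_a / scl
  series
}

#' CPMG pulse-train description
#'
#' Excitation of `90 * b1_scale` degrees about x followed by `n_echoes`
#' refocusing pulses of `180 * b1_scale` degrees about y (CPMG convention);
#' the transmit-field scale multiplies all flips. Timing uses half-interval
#' relaxation-exchange-shift either side of each refocusing pulse
#' (see [simulate_cpmg()], the engine for this train).
#'
#' @param n_echoes number of echoes, `>= 1`.
#' @param esp echo spacing (ms), `> 0`.
#' @param b1_scale transmit field scale applied to all flips.
#' @return a [pulse_train()] with `tr = esp` and attribute
#'   `timing = "half_interval"`.
#' @export
cpmg_sequence <- function(n_echoes, esp, b1_scale = 1) {
  stopifnot(n_echoes >= 1, esp > 0)
  tr <- pulse_train(flips = b1_scale * c(pi / 2, rep(pi, n_echoes)),
                    phases = c(0, rep(pi / 2, n_echoes)),
                    tr = esp, dephasing_cycles = 1)
  attr(tr, "timing") <- "half_interval"
  tr
}

#' Simulate a CPMG echo train
#'
#' Multi-echo spin-echo simulation: excitation about x, refocusing about y,
#' with relaxation-exchange and one dephasing cycle in each half echo
#' spacing. Echo amplitudes are the order-0 transverse magnitudes at the
#' echo times; for Bloch-McConnell models the observed amplitude is the sum
#' over both pools (only the total is measurable), with per-pool traces also
#' returned.
#'
#' @param model an `epgx_model`.
#' @param n_echoes number of echoes.
#' @param esp echo spacing (ms).
#' @param b1_scale transmit-field scaling applied to all flips.
#' @return object of class `epgx_echoes`: `echo_times` (ms), `echoes`
#'   (observed magnitudes), complex `echoes_a`/`echoes_b`, final `state`.
#' @examples
#' # ideal refocusing of a single pool: pure exponential T2 decay
#' e <- simulate_cpmg(single_pool_model(1000, 100), n_echoes = 10, esp = 5)
#' all.equal(e$echoes, exp(-e$echo_times / 100), tolerance = 1e-10)
#' @export
simulate_cpmg <- function(model, n_echoes = 50, esp = 5, b1_scale = 1) {
  stopifnot(inherits(model, "epgx_model"), n_echoes >= 1, esp > 0)
  mode <- model_mode(model)
  st <- epgx_state(model, 2L * n_echoes + 2L)
  half <- relaxation_exchange(model, esp / 2)
  st <- state_rf(st, b1_scale * pi / 2, 0)
  st <- shift_once(state_relax(st, half))
  ea <- eb <- complex(n_echoes)
  for (e in seq_len(n_echoes)) {
    st <- state_rf(st, b1_scale * pi, pi / 2)
    st <- shift_once(state_relax(st, half))
    s <- state_signal(st)
    ea[e] <- s$a
    eb[e] <- s$b
    if (e < n_echoes) st <- shift_once(state_relax(st, half))
  }
  structure(
    list(echo_times = esp * seq_len(n_echoes),
         echoes = Mod(if (mode == "bm") ea + eb else ea),
         echoes_a = ea, echoes_b = if (mode == "bm") eb else NULL,
         state = st, mode = mode, esp = esp, b1_scale = b1_scale),
    class = "epgx_echoes")
}

#' @export
print.epgx_echoes <- function(x, ...) {
  cat(sprintf("epgx_echoes (%s): %d echoes, esp %g ms, B1 scale %g\n",
              x$mode, length(x$echoes), x$esp, x$b1_scale))
  invisible(x)
}

#' Multislice TSE echo train for the center slice
#'
#' Simulates the echo train of the center slice of a multislice turbo
#' spin-echo acquisition with a magnetization-transfer model. The
#' acquisition of every other slice is seen by the center slice as a train
#' of off-resonant pulses: zero flip angle for the free pool, but direct
#' saturation of the bound pool through the absorption lineshape evaluated
#' at the slice frequency offset (slice-position difference times
#' `slice_offset_hz`). Slices are acquired in odd-even interleaved order and
#' their blocks of `(n_echoes + 1) * esp` are distributed evenly over the TR
#' (each block fills a `TR / n_slices` slot, the standard scanner timing),
#' so saturation events occur throughout the TR cycle. The sequence is run
#' for `n_tr` TR periods and the echo train of the final one is returned (a
#' periodic steady state is reached in about three).
#'
#' @param model an `epgx_model` (MT for tissue; a single-pool model, e.g.
#'   CSF, shows no multislice effect).
#' @param n_slices odd number of slices.
#' @param refocus_deg nominal refocusing flip (deg): 180 or 120; with 120,
#'   the first refocusing pulse is 160 (standard vendor default).
#' @param n_echoes echoes per excitation.
#' @param esp echo spacing (ms).
#' @param tr repetition time (ms).
#' @param energies pulse-energy table as from [pulse_energy_preset()]:
#'   `data.frame` with `role` (`"excitation"`, `"first_refocus"`,
#'   `"refocus"`), `flip_deg`, `energy`.
#' @param slice_offset_hz frequency spacing between adjacent slices (Hz).
#' @param n_tr number of TR periods simulated.
#' @return list with `echo_times`, `echoes` (final-TR magnitudes), `mean_echo`
#'   and the per-TR echo matrix `echoes_by_tr`.
#' @export
multislice_tse <- function(model, n_slices = 1, refocus_deg = 180,
                           n_echoes = 25, esp = 7.7, tr = 5000,
                           energies = NULL, slice_offset_hz = 2780,
                           n_tr = 3) {
  stopifnot(inherits(model, "epgx_model"))
  if (n_slices %% 2 == 0) stop("'n_slices' must be odd")
  mode <- model_mode(model)
  if (is.null(energies)) {
    energies <- pulse_energy_preset(if (refocus_deg == 180) "tse180" else "tse120")
  }
  e_of <- function(role) energies$energy[match(role, energies$role)]
  f_of <- function(role) energies$flip_deg[match(role, energies$role)] * pi / 180
  first_flip <- f_of("first_refocus")
  refoc_flip <- f_of("refocus")
  block <- (n_echoes + 1) * esp
  center <- (n_slices + 1) / 2
  # odd-even interleaved acquisition order; slice blocks are distributed
  # evenly over the TR (the standard scanner behavior), so each block of
  # (n_echoes + 1) * esp is followed by a gap completing its TR/n_slices slot
  acq_order <- if (n_slices == 1) 1 else {
    c(seq(1, n_slices, by = 2), seq(2, n_slices - 1, by = 2))
  }
  slot <- tr / n_slices
  if (slot < block) stop("slice blocks do not fit in TR")
  gap <- relaxation_exchange(model, slot - block)
  g0 <- if (mode == "mt") mt_g0(model) else 0
  half <- relaxation_exchange(model, esp / 2)
  full <- relaxation_exchange(model, esp)
  st <- epgx_state(model, 2L * n_tr * n_slices * (n_echoes + 2L))
  echoes_by_tr <- matrix(NA_real_, n_tr, n_echoes)
  for (t in seq_len(n_tr)) {
    for (s in acq_order) {
      if (s == center) {
        # the slice's own excitation + echo train (on-resonant saturation)
        st <- state_rf(st, pi / 2, 0,
                       zb_scale = exp(-saturation_exponent(e_of("excitation"), g0)))
        st <- shift_once(state_relax(st, half))
        for (e in seq_len(n_echoes)) {
          fl <- if (e == 1) first_flip else refoc_flip
          en <- if (e == 1) e_of("first_refocus") else e_of("refocus")
          st <- state_rf(st, fl, pi / 2,
                         zb_scale = exp(-saturation_exponent(en, g0)))
          st <- shift_once(state_relax(st, half))
          sg <- state_signal(st)
          echoes_by_tr[t, e] <- Mod(if (mode == "bm") sg$a + sg$b else sg$a)
          if (e < n_echoes) st <- shift_once(state_relax(st, half))
        }
        st <- shift_once(state_relax(st, half))
      } else {
        # another slice: zero flip for the free pool, off-resonant
        # saturation of the bound pool
        goff <- if (mode == "mt") {
          lineshape_value(abs(s - center) * slice_offset_hz, model$t2b_us,
                          kind = model$lineshape)
        } else 0
        sat_exc <- exp(-saturation_exponent(e_of("excitation"), goff))
        sat_first <- exp(-saturation_exponent(e_of("first_refocus"), goff))
        sat_ref <- exp(-saturation_exponent(e_of("refocus"), goff))
        st <- state_rf(st, 0, 0, zb_scale = sat_exc)
        st <- shift_once(state_relax(st, full))
        for (e in seq_len(n_echoes)) {
          st <- state_rf(st, 0, 0,
                         zb_scale = if (e == 1) sat_first else sat_ref)
          st <- shift_once(state_relax(st, full))
        }
      }
      st <- shift_once(state_relax(st, gap))
    }
  }
  list(echo_times = esp * seq_len(n_echoes),
       echoes = echoes_by_tr[n_tr, ],
       mean_echo = mean(echoes_by_tr[n_tr, ]),
       echoes_by_tr = echoes_by_tr)
}
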