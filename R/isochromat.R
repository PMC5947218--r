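# Brute-force validation path: direct Bloch-McConnell integration over an
# ensemble of dephasing angles, and Fourier reconstruction of intravoxel
# profiles from configuration states.

# midpoint grid on [-pi, pi]: avoids double-counting the endpoints
iso_psi_grid <- function(n_iso) -pi + (seq_len(n_iso) - 0.5) * 2 * pi / n_iso

#' Isochromat-ensemble simulation of a pulse train
#'
#' Direct integration of the (Bloch-McConnell or MT-modified) equations for
#' `n_iso` isochromats at dephasing angles spaced evenly over `[-pi, pi]`,
#' with the same RF and saturation action as the phase-graph engine. The
#' signal is the ensemble mean of the transverse magnetization. For any
#' train of P pulses and `n_iso >= P` the result equals the EPG-X signal to
#' double precision; for smaller ensembles large deviations appear. This is
#' the validation oracle, not a performance path.
#'
#' @param model an `epgx_model`.
#' @param train a [pulse_train()].
#' @param n_iso number of isochromats, `>= 1`.
#' @param te optional echo-time decay as in [simulate_train()].
#' @return an object of class `epgx_signal` (without state fields).
#' @export
simulate_isochromats <- function(model, train, n_iso, te = NULL) {
  stopifnot(inherits(model, "epgx_model"), inherits(train, "pulse_train"),
            n_iso >= 1)
  mode <- model_mode(model)
  P <- length(train$flips)
  psi <- iso_psi_grid(n_iso) * train$dephasing_cycles
  eph <- exp(1i * psi)
  prop <- relaxation_exchange(model, train$tr)
  prop_te <- if (!is.null(te)) relaxation_exchange(model, te) else NULL
  wsat <- if (mode == "mt") train_sat_exponents(model, train) else numeric(P)
  # per-isochromat magnetization: complex M+ and real Mz per pool
  ma <- complex(n_iso)
  mb <- if (mode == "bm") complex(n_iso) else NULL
  za <- rep((1 - model$f) * model$m0, n_iso)
  zb <- if (mode != "single") rep(model$f * model$m0, n_iso) else NULL
  sig_a <- sig_b <- complex(P)
  z0a <- z0b <- complex(P)
  for (j in seq_len(P)) {
    T3 <- rf_transition(train$flips[j], train$phases[j])
    rot <- function(mp, mz) {
      M <- T3 %*% rbind(mp, Conj(mp), mz)
      list(mp = M[1, ], mz = Re(M[3, ]))
    }
    ra <- rot(ma, za)
    ma <- ra$mp
    za <- ra$mz
    if (mode == "bm") {
      rb <- rot(mb, zb)
      mb <- rb$mp
      zb <- rb$mz
    } else if (mode == "mt") {
      zb <- zb * exp(-wsat[j])
    }
    s_a <- ma
    s_b <- if (mode == "bm") mb else complex(n_iso)
    if (!is.null(prop_te)) {
      if (mode == "bm") {
        TP <- prop_te$xi_p %*% rbind(s_a, s_b)
        s_a <- TP[1, ]
        s_b <- TP[2, ]
      } else {
        s_a <- s_a * prop_te$xi_t
      }
    }
    dem <- exp(-1i * train$phases[j])
    sig_a[j] <- mean(s_a) * dem
    sig_b[j] <- mean(s_b) * dem
    z0a[j] <- mean(za)
    z0b[j] <- if (mode == "single") 0 else mean(zb)
    # free evolution: relaxation-exchange then dephasing by psi
    if (mode == "bm") {
      TP <- prop$xi_p %*% rbind(ma, mb)
      ma <- TP[1, ] * eph
      mb <- TP[2, ] * eph
      ZZ <- prop$xi_l %*% rbind(za, zb)
      za <- ZZ[1, ] + prop$recovery[1]
      zb <- ZZ[2, ] + prop$recovery[2]
    } else if (mode == "mt") {
      ma <- ma * prop$xi_t * eph
      ZZ <- prop$xi_l %*% rbind(za, zb)
      za <- ZZ[1, ] + prop$recovery[1]
      zb <- ZZ[2, ] + prop$recovery[2]
    } else {
      ma <- ma * prop$xi_t * eph
      za <- za * prop$xi_l + prop$recovery
    }
  }
  total <- if (mode == "bm") sig_a + sig_b else sig_a
  structure(
    list(times = (seq_len(P) - 1) * train$tr + if (is.null(te)) 0 else te,
         signal = total, signal_a = sig_a,
         signal_b = if (mode == "bm") sig_b else NULL,
         z0_a = z0a, z0_b = if (mode == "single") NULL else z0b,
         state = NULL, state_last_pulse = NULL, mode = mode, train = train),
    class = "epgx_signal")
}

# highest order with a nonzero entry in any ladder
effective_order <- function(state) {
  nzmax <- function(v) if (is.null(v)) 0L else {
    w <- which(Mod(v) > 0)
    if (length(w)) max(w) - 1L else 0L
  }
  max(nzmax(state$fplus_a), nzmax(state$fminus_a), nzmax(state$z_a),
      nzmax(state$fplus_b), nzmax(state$fminus_b), nzmax(state$z_b))
}

#' Intravoxel magnetization profile from configuration states
#'
#' Evaluates the Fourier sums `M+(psi) = sum_n F_n e^{i n psi}` and
#' `Mz(psi) = sum_n Z_n e^{i n psi}` on a uniform midpoint grid over
#' `[-pi, pi]`, using `F_{-n} = Conj(F_{-n}*)` and `Z_{-n} = Conj(Z_n)`.
#'
#' @param state an `epgx_state`.
#' @param n_grid number of grid points; must be at least `2 k + 1` where `k`
#'   is the highest populated order (otherwise the reconstruction aliases and
#'   an error is raised).
#' @return list with `psi` and per-pool `m_plus_a`, `mz_a` (and `m_plus_b`,
#'   `mz_b` for BM; `mz_b` only for MT), plus `m_plus` (observable total).
#' @export
states_to_profile <- function(state, n_grid) {
  stopifnot(inherits(state, "epgx_state"))
  k <- effective_order(state)
  if (n_grid < 2 * k + 1) {
    stop(sprintf("n_grid = %d aliases states up to order %d (need >= %d)",
                 n_grid, k, 2 * k + 1))
  }
  psi <- iso_psi_grid(n_grid)
  n <- 0:(length(state$fplus_a) - 1L)
  Ep <- exp(1i * outer(psi, n))                  # e^{+i n psi}
  fourier_f <- function(fp, fm) {
    # sum_{n>=0} F_n e^{inpsi} + sum_{n>=1} Conj(F_-n*) e^{-inpsi}
    fneg <- Conj(fm)
    fneg[1] <- 0 + 0i
    as.vector(Ep %*% fp + Conj(Ep) %*% fneg)
  }
  fourier_z <- function(z) {
    zneg <- Conj(z)
    zneg[1] <- 0 + 0i
    as.vector(Ep %*% z + Conj(Ep) %*% zneg)
  }
  out <- list(psi = psi,
              m_plus_a = fourier_f(state$fplus_a, state$fminus_a),
              mz_a = fourier_z(state$z_a))
  if (state$mode == "bm") {
    out$m_plus_b <- fourier_f(state$fplus_b, state$fminus_b)
    out$mz_b <- fourier_z(state$z_b)
    out$m_plus <- out$m_plus_a + out$m_plus_b
  } else {
    if (state$mode == "mt") out$mz_b <- fourier_z(state$z_b)
    out$m_plus <- out$m_plus_a
  }
  out
}

#' Configuration states from an intravoxel profile
#'
#' Inverse of [states_to_profile()]: discrete Fourier analysis of `M+(psi)`
#' and `Mz(psi)` sampled on the uniform midpoint grid, recovering `F_n`,
#' `F_-n*` and `Z_n` for `n = 0..order_max`. Round-trips with
#' [states_to_profile()] to near machine precision when the grid satisfies
#' the sampling requirement.
#'
#' @param profile list as returned by [states_to_profile()].
#' @param order_max highest order to recover.
#' @return list of ladders `fplus_a`, `fminus_a`, `z_a` (and pool-b
#'   counterparts when present in the profile).
#' @export
profile_to_states <- function(profile, order_max) {
  psi <- profile$psi
  K <- length(psi)
  if (K < 2 * order_max + 1) stop("profile grid too coarse for order_max")
  n <- 0:order_max
  Em <- exp(-1i * outer(n, psi))                 # e^{-i n psi} / K
  analyze_f <- function(mp) {
    fp <- as.vector(Em %*% mp) / K               # F_n, n >= 0
    fm <- Conj(as.vector(Conj(Em) %*% mp) / K)   # F_-n* = Conj(F_-n)
    fm[1] <- Conj(fp[1])
    list(fp = fp, fm = fm)
  }
  analyze_z <- function(mz) as.vector(Em %*% mz) / K
  out <- list()
  fa <- analyze_f(profile$m_plus_a)
  out$fplus_a <- fa$fp
  out$fminus_a <- fa$fm
  out$z_a <- analyze_z(profile$mz_a)
  if (!is.null(profile$m_plus_b)) {
    fb <- analyze_f(profile$m_plus_b)
    out$fplus_b <- fb$fp
    out$fminus_b <- fb$fm
  }
  if (!is.null(profile$mz_b)) out$z_b <- analyze_z(profile$mz_b)
  out
}

#' Off-resonance profile of a converged bSSFP sequence
#'
#' Runs the transient phase-graph simulation with the off-resonance
#' precession per TR encoded as one configuration-order increment (for a
#' balanced sequence, off-resonance dephasing accumulates exactly like
#' gradient dephasing, so the state ladder indexes the per-TR phase `psi`),
#' then reconstructs the echo-time intravoxel profile: states after the last
#' pulse are relaxed over `TR/2` and each isochromat accrues the additional
#' phase `psi/2`. The result is directly comparable to
#' [bssfp_steady_state()] evaluated on the same `psi` grid.
#'
#' @param model an `epgx_model`.
#' @param tr,alpha sequence parameters (ms, rad).
#' @param n_pulses train length; default runs to `5 * T1obs`.
#' @param n_psi number of profile points.
#' @param energy MT pulse energy (ms uT^2); default 13.5 uT hard pulse.
#' @return list with `psi`, complex `signal` (demodulated total), and the
#'   underlying `epgx_signal`.
#' @export
bssfp_profile <- function(model, tr, alpha, n_pulses = NULL, n_psi = 64,
                          energy = NULL) {
  stopifnot(inherits(model, "epgx_model"))
  if (is.null(n_pulses)) n_pulses <- ceiling(5 * t1_observed(model) / tr)
  if (is.null(energy)) energy <- as.numeric(hard_pulse_energy(alpha))
  train <- bssfp_sequence(tr = tr, alpha = alpha, n_pulses = n_pulses,
                          energies = energy)
  train$dephasing_cycles <- 1L            # encode psi as configuration order
  sim <- simulate_train(model, train)
  st <- sim$state_last_pulse
  half <- relaxation_exchange(model, tr / 2)
  if (st$mode == "bm") {
    TP <- half$xi_p %*% rbind(st$fplus_a, st$fplus_b)
    TM <- Conj(half$xi_p) %*% rbind(st$fminus_a, st$fminus_b)
    st$fplus_a <- TP[1, ]; st$fplus_b <- TP[2, ]
    st$fminus_a <- TM[1, ]; st$fminus_b <- TM[2, ]
  } else {
    st$fplus_a <- st$fplus_a * half$xi_t
    st$fminus_a <- st$fminus_a * half$xi_t
  }
  psi <- iso_psi_grid(n_psi)
  mp <- eval_m_plus(st, psi)
  dem <- exp(-1i * train$phases[n_pulses])
  sig <- mp * exp(1i * psi / 2) * dem
  list(psi = psi, signal = sig, sim = sim)
}

# evaluate the observable M+(psi) Fourier series at arbitrary psi
# (direct evaluation; no grid/sampling requirement)
eval_m_plus <- function(state, psi) {
  n <- 0:(length(state$fplus_a) - 1L)
  Ep <- exp(1i * outer(psi, n))
  series <- function(fp, fm) {
    fneg <- Conj(fm)
    fneg[1] <- 0 + 0i
    as.vector(Ep %*% fp + Conj(Ep) %*% fneg)
  }
  out <- series(state$fplus_a, state$fminus_a)
  if (state$mode == "bm") out <- out + series(state$fplus_b, state$fminus_b)
  out
}
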