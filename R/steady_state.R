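# Direct (non-iterative) steady-state solutions for ideally spoiled gradient
# echo and balanced SSFP, built from the same relaxation-exchange operators
# as the transient engine. Their correctness is established by transient-
# convergence and analytic-limit tests rather than by transcribing
# literature formulas.

#' Ideally spoiled gradient-echo steady state
#'
#' Solves the longitudinal fixed point `Z = XiL S(alpha) Z + recovery`, where
#' `S(alpha)` is the per-pulse longitudinal action: `cos(alpha)` on rotated
#' pools and the direct-saturation factor `exp(-Wbar tau_rf)` on the bound
#' pool in MT mode. Transverse magnetization is assumed perfectly spoiled
#' every TR, so the result is independent of the RF-spoiling increment; the
#' echo signal is `sin(alpha)` times the pre-pulse longitudinal
#' magnetization of the visible pool(s). In the single-pool limit this is the
#' Ernst formula `sin(a) (1 - E1) / (1 - E1 cos(a))`.
#'
#' @param model an `epgx_model`.
#' @param tr repetition time (ms).
#' @param alpha flip angle (rad), `0 < alpha < pi`.
#' @param energy RF pulse energy (ms uT^2), required for MT models; defaults
#'   to a 13.5 uT hard pulse.
#' @return list of class `epgx_steady_state` with `signal` (magnitude),
#'   `signal_a`, `signal_b`, and pre-pulse longitudinal vector `mz`.
#' @export
spgr_steady_state <- function(model, tr, alpha, energy = NULL) {
  stopifnot(inherits(model, "epgx_model"), alpha > 0, alpha < pi)
  mode <- model_mode(model)
  prop <- relaxation_exchange(model, tr)
  if (mode == "single") {
    e1 <- prop$xi_l
    z <- prop$recovery / (1 - e1 * cos(alpha))
    sa <- sin(alpha) * z
    out <- list(signal = abs(sa), signal_a = sa, signal_b = 0, mz = z)
  } else {
    S <- if (mode == "bm") {
      diag(c(cos(alpha), cos(alpha)))
    } else {
      if (is.null(energy)) energy <- as.numeric(hard_pulse_energy(alpha))
      wsat <- saturation_exponent(energy, mt_g0(model))
      diag(c(cos(alpha), exp(-wsat)))
    }
    A <- diag(2) - prop$xi_l %*% S
    if (abs(det(A)) < 1e-14) stop("singular steady-state system")
    z <- solve(A, prop$recovery)
    sa <- sin(alpha) * z[1]
    sb <- if (mode == "bm") sin(alpha) * z[2] else 0
    out <- list(signal = abs(sa + sb), signal_a = sa, signal_b = sb, mz = z)
  }
  class(out) <- "epgx_steady_state"
  out
}

# one-TR affine map for the order-0 bSSFP state vector:
# x = (F+a, F-a, Za[, F+b, F-b, Zb]) complex; pulse of phase phi, then free
# evolution over TR with voxel dephasing psi (rad)
bssfp_period_map <- function(model, tr, alpha, psi, phi, energy) {
  mode <- model_mode(model)
  prop <- relaxation_exchange(model, tr)
  wsat <- if (mode == "mt") {
    if (is.null(energy)) energy <- as.numeric(hard_pulse_energy(alpha))
    saturation_exponent(energy, mt_g0(model))
  } else 0
  Tb <- rf_transition_block(alpha, phi, mode = mode, wsat_exponent = wsat)
  n <- nrow(Tb)
  evolve <- function(x) {
    if (mode == "bm") {
      fp <- prop$xi_p %*% x[c(1, 4)] * exp(1i * psi)
      fm <- Conj(prop$xi_p) %*% x[c(2, 5)] * exp(-1i * psi)
      zz <- prop$xi_l %*% x[c(3, 6)] + prop$recovery
      c(fp[1], fm[1], zz[1], fp[2], fm[2], zz[2])
    } else if (mode == "mt") {
      zz <- prop$xi_l %*% x[c(3, 4)] + prop$recovery
      c(x[1] * prop$xi_t * exp(1i * psi), x[2] * prop$xi_t * exp(-1i * psi),
        zz[1], zz[2])
    } else {
      c(x[1] * prop$xi_t * exp(1i * psi), x[2] * prop$xi_t * exp(-1i * psi),
        x[3] * prop$xi_l + prop$recovery)
    }
  }
  list(apply = function(x) evolve(as.vector(Tb %*% x)), n = n, Tb = Tb,
       mode = mode)
}

#' Balanced SSFP steady state
#'
#' Direct steady state of the order-0 state vector (transverse and
#' longitudinal, both pools as the model dictates) for an alternating-phase
#' bSSFP sequence at voxel dephasing `psi` per TR. The two-pulse period map
#' `x -> P x + d` is composed from the RF transition block and the
#' relaxation-exchange propagators (with the pool-b offset `delta_b` inside
#' the transverse block), and the fixed point is solved linearly. The signal
#' is evaluated at the echo time `TR/2` after the phase-0 pulse and
#' demodulated.
#'
#' @param model an `epgx_model`.
#' @param tr repetition time (ms).
#' @param alpha flip angle (rad).
#' @param psi off-resonance dephasing per TR (rad), in `[-pi, pi]`.
#' @param energy RF pulse energy for MT saturation (ms uT^2); defaults to a
#'   13.5 uT hard pulse.
#' @return list of class `epgx_steady_state` with complex `signal_cplx`,
#'   `signal` (magnitude), per-pool parts and longitudinal vector `mz`.
#' @export
bssfp_steady_state <- function(model, tr, alpha, psi = 0, energy = NULL) {
  stopifnot(inherits(model, "epgx_model"))
  mode <- model_mode(model)
  m1 <- bssfp_period_map(model, tr, alpha, psi, 0, energy)
  m2 <- bssfp_period_map(model, tr, alpha, psi, pi, energy)
  n <- m1$n
  two_tr <- function(x) m2$apply(m1$apply(x))
  d <- two_tr(complex(n))
  P <- matrix(0 + 0i, n, n)
  for (k in seq_len(n)) {
    ek <- complex(n)
    ek[k] <- 1 + 0i
    P[, k] <- two_tr(ek) - d
  }
  A <- diag(n) - P
  x <- tryCatch(solve(A, d), error = function(e) {
    stop("singular steady-state system (non-physical parameters)")
  })                                     # state just before the phase-0 pulse
  y <- as.vector(m1$Tb %*% x)            # just after it
  half <- relaxation_exchange(model, tr / 2)
  ph <- exp(1i * psi / 2)
  if (mode == "bm") {
    fp <- half$xi_p %*% y[c(1, 4)] * ph
    sa <- fp[1]
    sb <- fp[2]
    mz <- y[c(3, 6)]
  } else {
    sa <- y[1] * half$xi_t * ph
    sb <- 0 + 0i
    mz <- if (mode == "mt") y[c(3, 4)] else y[3]
  }
  s <- sa + sb
  out <- list(signal_cplx = s, signal = abs(s), signal_a = sa, signal_b = sb,
              mz = mz, psi = psi)
  class(out) <- "epgx_steady_state"
  out
}

#' On-resonance bSSFP steady state of an MT system, reduced closed form
#'
#' At `psi = 0` the on-resonance bSSFP steady state of a
#' magnetization-transfer system stays in the y-z plane, so (after absorbing
#' the phase alternation into a per-TR sign flip) it reduces to a real
#' 3-variable linear system in `(My, Za, Zb)`:
#' RF rotation about x of the free pool with bound-pool saturation
#' `exp(-Wbar tau_rf)`, transverse decay `exp(-TR/T2a)`, and the coupled
#' longitudinal relaxation-exchange update. This reduced derivation is
#' independent of the full complex period-map solver and serves as its
#' on-resonance cross-check, matching the analytic two-pool bSSFP signal
#' equation used in steady-state MT imaging.
#'
#' @param model an `epgx_mt` model.
#' @param tr repetition time (ms).
#' @param alpha flip angle (rad).
#' @param energy pulse energy (ms uT^2); default 13.5 uT hard pulse.
#' @return echo-time (`TR/2`) signal magnitude.
#' @export
mt_bssfp_analytic <- function(model, tr, alpha, energy = NULL) {
  stopifnot(inherits(model, "epgx_mt"))
  if (is.null(energy)) energy <- as.numeric(hard_pulse_energy(alpha))
  eps <- exp(-saturation_exponent(energy, mt_g0(model)))
  prop <- relaxation_exchange(model, tr)
  e2 <- prop$xi_t
  XL <- prop$xi_l
  rec <- prop$recovery
  ca <- cos(alpha)
  sa <- sin(alpha)
  # fixed point of: RF about x (+ bound saturation), relax over TR,
  # transverse sign flip from the phase alternation:
  #   My = -e2 (ca My + sa Za)
  #   Za = XL11 (-sa My + ca Za) + XL12 eps Zb + rec1
  #   Zb = XL21 (-sa My + ca Za) + XL22 eps Zb + rec2
  A <- rbind(
    c(1 + e2 * ca,  e2 * sa,           0),
    c(XL[1, 1] * sa, 1 - XL[1, 1] * ca, -XL[1, 2] * eps),
    c(XL[2, 1] * sa, -XL[2, 1] * ca,    1 - XL[2, 2] * eps))
  b <- c(0, rec[1], rec[2])
  x <- solve(A, b)
  my1 <- ca * x[1] + sa * x[2]
  abs(my1) * exp(-(tr / 2) / model$t2a)
}
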