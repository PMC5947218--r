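# Ordered configuration-state container and the core state updates shared by
# all sequence engines.

#' Configuration-state container
#'
#' Creates an EPG-X state at thermal equilibrium: all configuration states
#' zero except the order-0 longitudinal states `Z0a = (1 - f) m0` and
#' `Z0b = f m0`. Transverse ladders `fplus` hold `F_n` for `n = 0..order_max`
#' and `fminus` hold `F_-n*`; the order-0 entries satisfy
#' `fminus[1] = Conj(fplus[1])` throughout any simulation. In MT mode the
#' bound pool has no transverse ladders.
#'
#' @param model an `epgx_model`.
#' @param order_max highest configuration order retained. States shifted
#'   beyond it are truncated and counted in the `dropped` field (a diagnostic
#'   of lossy truncation); engines default to one order per RF pulse, which
#'   is lossless.
#' @return an object of class `epgx_state`.
#' @export
epgx_state <- function(model, order_max) {
  stopifnot(inherits(model, "epgx_model"), order_max >= 1)
  mode <- model_mode(model)
  L <- order_max + 1L
  z <- complex(L)
  st <- list(mode = mode, order_max = as.integer(order_max),
             fplus_a = z, fminus_a = z, z_a = z,
             fplus_b = NULL, fminus_b = NULL, z_b = NULL,
             m0 = model$m0, f = model$f, dropped = 0)
  st$z_a[1] <- (1 - model$f) * model$m0
  if (mode == "bm") {
    st$fplus_b <- z
    st$fminus_b <- z
    st$z_b <- z
    st$z_b[1] <- model$f * model$m0
  } else if (mode == "mt") {
    st$z_b <- z
    st$z_b[1] <- model$f * model$m0
  }
  class(st) <- "epgx_state"
  st
}

# RF pulse action: rotate free (and, for bm, bound) transverse/longitudinal
# triples at every order; in mt mode scale every bound-pool Z by zb_scale.
state_rf <- function(st, alpha, phi, zb_scale = 1) {
  T3 <- rf_transition(alpha, phi)
  Ma <- T3 %*% rbind(st$fplus_a, st$fminus_a, st$z_a)
  st$fplus_a <- Ma[1, ]
  st$fminus_a <- Ma[2, ]
  st$z_a <- Ma[3, ]
  if (st$mode == "bm") {
    Mb <- T3 %*% rbind(st$fplus_b, st$fminus_b, st$z_b)
    st$fplus_b <- Mb[1, ]
    st$fminus_b <- Mb[2, ]
    st$z_b <- Mb[3, ]
  } else if (st$mode == "mt") {
    st$z_b <- st$z_b * zb_scale
  }
  st
}

# relaxation-exchange over one interval (propagator from relaxation_exchange)
state_relax <- function(st, prop) {
  if (st$mode == "bm") {
    TP <- prop$xi_p %*% rbind(st$fplus_a, st$fplus_b)
    TM <- Conj(prop$xi_p) %*% rbind(st$fminus_a, st$fminus_b)
    ZZ <- prop$xi_l %*% rbind(st$z_a, st$z_b)
    st$fplus_a <- TP[1, ]; st$fplus_b <- TP[2, ]
    st$fminus_a <- TM[1, ]; st$fminus_b <- TM[2, ]
    st$z_a <- ZZ[1, ]; st$z_b <- ZZ[2, ]
    st$z_a[1] <- st$z_a[1] + prop$recovery[1]
    st$z_b[1] <- st$z_b[1] + prop$recovery[2]
  } else if (st$mode == "mt") {
    st$fplus_a <- st$fplus_a * prop$xi_t
    st$fminus_a <- st$fminus_a * prop$xi_t
    ZZ <- prop$xi_l %*% rbind(st$z_a, st$z_b)
    st$z_a <- ZZ[1, ]; st$z_b <- ZZ[2, ]
    st$z_a[1] <- st$z_a[1] + prop$recovery[1]
    st$z_b[1] <- st$z_b[1] + prop$recovery[2]
  } else {
    st$fplus_a <- st$fplus_a * prop$xi_t
    st$fminus_a <- st$fminus_a * prop$xi_t
    st$z_a <- st$z_a * prop$xi_l
    st$z_a[1] <- st$z_a[1] + prop$recovery
  }
  st
}

# one unit of gradient dephasing: F_n -> F_{n+1}; the F_-n* ladder shifts
# down and refills the new F_0 by conjugation; Z unchanged.
shift_once <- function(st) {
  L <- length(st$fplus_a)
  shift_pool <- function(fp, fm) {
    if (fp[L] != 0) st$dropped <<- st$dropped + 1
    list(fp = c(Conj(fm[2]), fp[-L]), fm = c(fm[-1], 0 + 0i))
  }
  pa <- shift_pool(st$fplus_a, st$fminus_a)
  st$fplus_a <- pa$fp
  st$fminus_a <- pa$fm
  if (st$mode == "bm") {
    pb <- shift_pool(st$fplus_b, st$fminus_b)
    st$fplus_b <- pb$fp
    st$fminus_b <- pb$fm
  }
  st
}

#' Gradient shift operator
#'
#' Increments the configuration order of all transverse states by `cycles`
#' full dephasing cycles; longitudinal states are unchanged. States pushed
#' beyond `order_max` are truncated with a warning (set a larger `order_max`
#' at state creation for lossless evolution).
#'
#' @param state an `epgx_state`.
#' @param cycles non-negative integer number of dephasing cycles.
#' @return the shifted state.
#' @export
epgx_shift <- function(state, cycles = 1) {
  stopifnot(inherits(state, "epgx_state"), cycles >= 0, cycles == round(cycles))
  before <- state$dropped
  for (i in seq_len(cycles)) state <- shift_once(state)
  if (state$dropped > before) {
    warning(sprintf("%d nonzero state(s) truncated beyond order_max = %d",
                    state$dropped - before, state$order_max))
  }
  state
}

# per-order diffusion attenuation applied over one interval in which the
# configuration order increases by `cycles` (constant-gradient b-factors);
# identical treatment for both compartments.
state_diffuse <- function(st, d_mm2_s, k1_rad_mm, dt_ms, cycles = 1) {
  if (d_mm2_s <= 0 || cycles < 1) return(st)
  n <- 0:(length(st$fplus_a) - 1L)
  # D in mm^2/s, dt in ms -> consistent via 1e-3; k1 in rad/mm per cycle
  bconst <- d_mm2_s * 1e-3 * (k1_rad_mm * cycles)^2 * dt_ms
  at_p <- exp(-bconst * ((n + 0.5)^2 + 1 / 12))
  at_m <- exp(-bconst * (c(0.5, n[-1] - 0.5)^2 + 1 / 12))
  at_l <- exp(-bconst * n^2)
  st$fplus_a <- st$fplus_a * at_p
  st$fminus_a <- st$fminus_a * at_m
  st$z_a <- st$z_a * at_l
  if (st$mode == "bm") {
    st$fplus_b <- st$fplus_b * at_p
    st$fminus_b <- st$fminus_b * at_m
    st$z_b <- st$z_b * at_l
  } else if (st$mode == "mt") {
    st$z_b <- st$z_b * at_l
  }
  st
}

#' Diffusion specification
#'
#' Apparent-diffusion attenuation of configuration states under a constant
#' unbalanced gradient, applied identically to both compartments (single
#' shared diffusion coefficient). `k1_rad_mm` is the dephasing per interval
#' per unit length; the default corresponds to one full cycle across a
#' 1.5 mm voxel.
#'
#' @param d apparent diffusion coefficient (mm^2 s^-1), `>= 0`.
#' @param k1_rad_mm gradient dephasing per interval (rad mm^-1).
#' @param enabled logical flag.
#' @return object of class `diffusion_spec`.
#' @export
diffusion_spec <- function(d, k1_rad_mm = 2 * pi / 1.5, enabled = TRUE) {
  stopifnot(d >= 0)
  structure(list(d = d, k1_rad_mm = k1_rad_mm, enabled = isTRUE(enabled)),
            class = "diffusion_spec")
}

#' Apply diffusion attenuation to a state
#'
#' Attenuates transverse states by `exp(-b_T(n) D)` with
#' `b_T = k1^2 dt ((n + 1/2)^2 + 1/12)` and longitudinal states by
#' `exp(-b_L(n) D)` with `b_L = k1^2 dt n^2` (constant-gradient b-factors
#' for an interval in which the order increments by one cycle). The order-0
#' longitudinal state is unattenuated.
#'
#' @param state an `epgx_state`.
#' @param spec a [diffusion_spec()].
#' @param interval interval duration (ms).
#' @param cycles dephasing cycles in the interval.
#' @return attenuated state.
#' @export
apply_diffusion <- function(state, spec, interval, cycles = 1) {
  stopifnot(inherits(state, "epgx_state"), inherits(spec, "diffusion_spec"))
  if (!spec$enabled) return(state)
  state_diffuse(state, spec$d, spec$k1_rad_mm, interval, cycles)
}

# observable order-0 transverse values
state_signal <- function(st) {
  a <- st$fplus_a[1]
  b <- if (st$mode == "bm") st$fplus_b[1] else 0 + 0i
  list(a = a, b = b, total = if (st$mode == "bm") a + b else a)
}

#' @export
print.epgx_state <- function(x, ...) {
  nz <- function(v) if (is.null(v)) 0L else sum(v != 0)
  cat(sprintf("epgx_state (%s), order_max = %d\n", x$mode, x$order_max))
  cat(sprintf("  nonzero states: F+a %d, F-a %d, Za %d",
              nz(x$fplus_a), nz(x$fminus_a), nz(x$z_a)))
  if (x$mode == "bm") {
    cat(sprintf(", F+b %d, F-b %d, Zb %d", nz(x$fplus_b), nz(x$fminus_b),
                nz(x$z_b)))
  } else if (x$mode == "mt") {
    cat(sprintf(", Zb %d", nz(x$z_b)))
  }
  cat(sprintf("\n  dropped beyond order_max: %d\n", x$dropped))
  invisible(x)
}
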