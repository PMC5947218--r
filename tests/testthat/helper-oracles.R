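# Independent oracles used by the test suite. These deliberately share no
# code with the package internals they check.

# --- Taylor-series matrix exponential (scaling and squaring) ---------------
expm_taylor <- function(A, nterms = 30) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(nterms)) {
    term <- term %*% As / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# --- brute-force RF rotation in Cartesian coordinates ----------------------
# rotation by alpha about an axis in the transverse plane at azimuth phi,
# expressed in the (M+, M-, Mz) basis for comparison with rf_transition().
# MR rotation sense: an on-axis (phi = 0) pulse takes +z to -y.
rf_rotation_cartesian <- function(alpha, phi) {
  # Rz(phi) Rx(alpha) Rz(-phi) acting on (Mx, My, Mz)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0,
                             sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- function(t) matrix(c(1, 0, 0,
                             0, cos(t), -sin(t),
                             0, sin(t), cos(t)), 3, 3, byrow = TRUE)
  R <- Rz(phi) %*% Rx(alpha) %*% Rz(-phi)
  # basis change (Mx,My,Mz) -> (M+, M-, Mz)
  U <- matrix(c(1, 1i, 0,
                1, -1i, 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  U %*% R %*% solve(U)
}

# --- textbook single-pool EPG ---------------------------------------------
# plain implementation of the classic algorithm: state matrix with rows
# (F+, F-*, Z), RF mixing, relaxation E1/E2 with recovery into Z0, integer
# shift. Returns demodulated F0 after each pulse.
epg_single_reference <- function(t1, t2, m0, flips, phases, tr,
                                 dephasing = 1L) {
  P <- length(flips)
  L <- P * max(1L, dephasing) + 2L
  Fp <- complex(L)
  Fm <- complex(L)
  Z <- complex(L)
  Z[1] <- m0
  e1 <- exp(-tr / t1)
  e2 <- exp(-tr / t2)
  out <- complex(P)
  for (j in seq_len(P)) {
    a <- flips[j]
    p <- phases[j]
    T11 <- cos(a / 2)^2
    T12 <- exp(2i * p) * sin(a / 2)^2
    T13 <- -1i * exp(1i * p) * sin(a)
    nFp <- T11 * Fp + T12 * Fm + T13 * Z
    nFm <- Conj(T12) * Fp + T11 * Fm + Conj(T13) * Z
    nZ <- -0.5i * exp(-1i * p) * sin(a) * Fp +
      0.5i * exp(1i * p) * sin(a) * Fm + cos(a) * Z
    Fp <- nFp
    Fm <- nFm
    Z <- nZ
    out[j] <- Fp[1] * exp(-1i * p)
    Fp <- Fp * e2
    Fm <- Fm * e2
    Z <- Z * e1
    Z[1] <- Z[1] + m0 * (1 - e1)
    for (k in seq_len(dephasing)) {
      Fp <- c(Conj(Fm[2]), Fp[-L])
      Fm <- c(Fm[-1], 0 + 0i)
    }
  }
  out
}

# --- small fixtures --------------------------------------------------------
wm_mt_fixture <- function() epgx_mt_model(779, 779, 45, 12, ka = 4.3, f = 0.117)
myelin_fixture <- function(delta_b = 0, ka = 2) {
  epgx_bm_model(1000, 500, 100, 20, ka = ka, f = 0.2, delta_b = delta_b)
}

# random valid two-pool model under a fixed local seed
random_bm_model <- function() {
  epgx_bm_model(t1a = stats::runif(1, 300, 3000),
                t1b = stats::runif(1, 100, 1500),
                t2a = stats::runif(1, 30, 300),
                t2b = stats::runif(1, 5, 50),
                ka = stats::runif(1, 0, 10),
                f = stats::runif(1, 0.02, 0.45),
                delta_b = stats::runif(1, -50, 50))
}
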