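# internal numerical helpers shared across modules

# gyromagnetic ratio of 1H in rad ms^-1 uT^-1 (= 267.5221 rad s^-1 uT^-1)
.GAMMA_RAD_MS_UT <- 0.2675221

#' Exact exponential of a 2x2 matrix
#'
#' Closed form `exp(A) = e^mu (cosh(q) I + (sinh(q)/q) (A - mu I))` with
#' `mu = tr(A)/2` and `q^2 = mu^2 - det(A)`. Exact for any real or complex
#' 2x2 matrix, with a series expansion of `cosh`/`sinh(q)/q` near the
#' degenerate case `q -> 0`. All relaxation-exchange propagators in the
#' package reduce to 2x2 blocks, so this is the only matrix exponential used.
#'
#' @param A a 2x2 numeric or complex matrix.
#' @return the matrix exponential of `A`, real if `A` is real.
#' @keywords internal
#' @noRd
expm2 <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == c(2L, 2L)))
  mu <- (A[1, 1] + A[2, 2]) / 2
  B <- A
  B[1, 1] <- B[1, 1] - mu
  B[2, 2] <- B[2, 2] - mu
  q2 <- B[1, 1]^2 + B[1, 2] * B[2, 1]
  q <- sqrt(as.complex(q2))
  if (Mod(q) < 1e-5) {
    ch <- 1 + q2 / 2 + q2 * q2 / 24
    shq <- 1 + q2 / 6 + q2 * q2 / 120
  } else {
    ch <- cosh(q)
    shq <- sinh(q) / q
  }
  E <- exp(mu) * (ch * diag(2) + shq * B)
  if (is.complex(A)) E else Re(E)
}

# (XiL - I) LamL^{-1} C with a series fallback when LamL is singular
# (the inhomogeneous part of the order-0 longitudinal update)
recovery_term <- function(xi_l, lam_l, C, dt) {
  n <- nrow(lam_l)
  x <- tryCatch(solve(lam_l, C), error = function(e) NULL)
  if (!is.null(x) && all(is.finite(x))) {
    return(as.numeric((xi_l - diag(n)) %*% x))
  }
  # integral form: int_0^dt exp(LamL s) ds %*% C = dt * phi1(LamL dt) %*% C
  Ad <- lam_l * dt
  term <- diag(n)
  acc <- diag(n)
  for (k in 1:40) {
    term <- term %*% Ad / (k + 1)
    acc <- acc + term
    if (max(abs(term)) < 1e-18) break
  }
  as.numeric(dt * acc %*% C)
}

# log-spaced sequence
logseq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# recycle scalar-or-vector to length n with validation
recycle_to <- function(x, n, name) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop(sprintf("'%s' must have length 1 or %d, got %d", name, n, length(x)),
         call. = FALSE)
  }
  x
}
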