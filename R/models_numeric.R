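# Numeric solutions (NS) of the 2-site Bloch-McConnell equations. These are
# the convention-free reference models: the CPMG propagation is an explicit
# (tau - 180 - tau)^n echo train in the 2x2 complex single-coherence basis,
# and R1rho is a single free evolution of the 6-dimensional (x, y, z per
# state) real magnetization vector.

# Closed-form exponential of a 2x2 complex matrix:
# expm(A) = e^mu (cosh(d) I + sinh(d)/d (A - mu I)), mu = tr(A)/2,
# d^2 = det-free discriminant of the traceless part.
expm2x2 <- function(A) {
  mu <- (A[1, 1] + A[2, 2]) / 2
  B <- A
  B[1, 1] <- B[1, 1] - mu
  B[2, 2] <- B[2, 2] - mu
  d2 <- B[1, 1]^2 + B[1, 2] * B[2, 1]  # B^2 = d2 * I for traceless B
  d <- sqrt(as.complex(d2))
  if (abs(d) < 1e-10) {
    ch <- 1 + d2 / 2
    shd <- 1 + d2 / 6
  } else {
    ch <- cosh(d)
    shd <- sinh(d) / d
  }
  exp(mu) * (ch * diag(2) + shd * B)
}

# Integer matrix power by repeated squaring.
mat_pow <- function(A, n) {
  P <- diag(nrow(A))
  while (n > 0) {
    if (n %% 2 == 1) P <- P %*% A
    A <- A %*% A
    n <- n %/% 2
  }
  P
}

#' Bloch-McConnell evolution matrix for single-coherence CPMG
#'
#' The 2x2 complex matrix over the (A, B) coherence basis:
#' `diag(-R2A0 - kAB, -R2B0 - kBA - i dw)` plus off-diagonal exchange
#' `kBA, kAB`, with `kAB = pB kex` and `kBA = pA kex` (detailed balance).
#'
#' @param r20a,r20b State exchange-free rates, 1/s.
#' @param pA Major-state population in `(0.5, 1]`.
#' @param kex Exchange rate, 1/s.
#' @param dw Shift difference in rad/s.
#' @return A 2x2 complex matrix.
#' @export
build_cpmg_matrix <- function(r20a, r20b = r20a, pA, kex, dw) {
  if (pA < 0.5 || pA > 1) stop("pA must lie in [0.5, 1]", call. = FALSE)
  if (kex < 0) stop("kex must be >= 0", call. = FALSE)
  pB <- 1 - pA
  kab <- pB * kex
  kba <- pA * kex
  matrix(c(-r20a - kab + 0i, kab + 0i,
           kba + 0i, -r20b - kba - 1i * dw),
         nrow = 2, ncol = 2)
}

# Real magnetization of state A after a constant-time (tau-180-tau)^n train.
ns_cpmg_magnetization <- function(r20a, r20b, pA, kex, dw, nu_cpmg,
                                  relax_time_T, m0 = c(pA, 1 - pA)) {
  n <- 2 * max(1, round(relax_time_T * nu_cpmg))  # even number of 180s
  if (abs(n - 2 * relax_time_T * nu_cpmg) > 0.01 * n) {
    warning("2*T*nu_cpmg = ", 2 * relax_time_T * nu_cpmg,
            " is not close to an even integer; using n = ", n, call. = FALSE)
  }
  tau <- relax_time_T / (2 * n)  # half echo spacing; total time exactly T
  A <- expm2x2(build_cpmg_matrix(r20a, r20b, pA, kex, dw) * tau)
  # one echo element maps v -> A conj(A v); two elements are the linear map
  # A Conj(A) Conj(A) A, so the train is that pair propagator to the n/2.
  P2 <- A %*% Conj(A) %*% Conj(A) %*% A
  v <- mat_pow(P2, n %/% 2) %*% as.complex(m0)
  Re(v[1])
}

#' Numeric 2-site CPMG model (single quantum)
#'
#' Propagates the Bloch-McConnell equations through the explicit echo train
#' `(tau - 180 - tau)^n` with `tau = tau_cp/2 = 1/(4 nu_cpmg)` and
#' `n = 2 T nu_cpmg` 180-degree pulses (rounded to the nearest even integer;
#' a mismatch above 1 percent is warned about). The 180-degree pulse acts as
#' complex conjugation of the coherence vector; the matrix exponential over
#' one free-evolution segment is exact, so the propagation has no step-size
#' error. Starting magnetization is thermal equilibrium `(pA, pB)` and
#' `R2eff = -ln(Re M_A(T) / pA) / T`.
#'
#' @inheritParams build_cpmg_matrix
#' @param nu_cpmg CPMG frequency in Hz (vectorised).
#' @param relax_time_T Constant relaxation period, s.
#' @param m0 Starting magnetization: `"equilibrium"` (`(pA, pB)`, matching
#'   constant-time preparation; the default) or `"state_a"` (pure state A).
#' @return R2eff in 1/s, one value per `nu_cpmg`.
#' @export
ns_cpmg_2site <- function(r20a, r20b = r20a, pA, kex, dw, nu_cpmg,
                          relax_time_T, m0 = c("equilibrium", "state_a")) {
  m0 <- match.arg(m0)
  start <- if (m0 == "equilibrium") c(pA, 1 - pA) else c(1, 0)
  if (pA == 1 || dw == 0 || kex == 0) return(rep_len(r20a, length(nu_cpmg)))
  vapply(nu_cpmg, function(nu) {
    m <- ns_cpmg_magnetization(r20a, r20b, pA, kex, dw, nu, relax_time_T,
                               m0 = start)
    if (m <= 0) {
      stop("non-positive magnetization: pathological parameters", call. = FALSE)
    }
    -log(m / start[1]) / relax_time_T
  }, numeric(1))
}

#' Numeric 2-site CPMG model for MMQ coherences
#'
#' The SQ branch is identical to [ns_cpmg_2site()]; the ZQ and DQ branches
#' run the same propagation with effective shifts `dw - dwH` and `dw + dwH`;
#' the MQ branch propagates both components and averages their end-point
#' magnetizations before rate extraction.
#'
#' @inheritParams ns_cpmg_2site
#' @param dwH Proton shift difference in rad/s.
#' @param exp_type One of `"CPMG_SQ"`, `"CPMG_ZQ"`, `"CPMG_DQ"`, `"CPMG_MQ"`.
#' @return R2eff in 1/s, one value per `nu_cpmg`.
#' @export
ns_mmq_2site <- function(r20a, r20b = r20a, pA, kex, dw, dwH = NULL,
                         nu_cpmg, relax_time_T, exp_type = "CPMG_SQ") {
  if (exp_type != "CPMG_SQ" && is.null(dwH)) {
    stop("dwH is required for ZQ/DQ/MQ data", call. = FALSE)
  }
  if (is.null(dwH)) dwH <- 0
  dw_eff <- switch(exp_type,
    CPMG_SQ = dw,
    CPMG_ZQ = dw - dwH,
    CPMG_DQ = dw + dwH,
    CPMG_MQ = NULL,
    stop("exp_type must be a CPMG coherence type", call. = FALSE))
  if (!is.null(dw_eff)) {
    return(ns_cpmg_2site(r20a, r20b, pA, kex, abs(dw_eff), nu_cpmg,
                         relax_time_T))
  }
  if (pA == 1 || kex == 0 || (dw == 0 && dwH == 0)) {
    return(rep_len(r20a, length(nu_cpmg)))
  }
  vapply(nu_cpmg, function(nu) {
    mz <- ns_cpmg_magnetization(r20a, r20b, pA, kex, abs(dw - dwH), nu,
                                relax_time_T)
    md <- ns_cpmg_magnetization(r20a, r20b, pA, kex, dw + dwH, nu,
                                relax_time_T)
    m <- 0.5 * (mz + md)
    if (m <= 0) {
      stop("non-positive magnetization: pathological parameters", call. = FALSE)
    }
    -log(m / pA) / relax_time_T
  }, numeric(1))
}

# 6x6 real Bloch-McConnell matrix in the (xA, yA, zA, xB, yB, zB) basis.
build_r1rho_matrix <- function(r1, r20a, r20b, pA, kex, omega1,
                               omega_a, omega_b) {
  pB <- 1 - pA
  kab <- pB * kex
  kba <- pA * kex
  blockX <- function(r2, Omega) {
    matrix(c(-r2, Omega, 0,
             -Omega, -r2, omega1,
             0, -omega1, -r1), nrow = 3, ncol = 3)
  }
  L <- matrix(0, 6, 6)
  L[1:3, 1:3] <- blockX(r20a, omega_a) - kab * diag(3)
  L[4:6, 4:6] <- blockX(r20b, omega_b) - kba * diag(3)
  L[1:3, 4:6] <- kba * diag(3)
  L[4:6, 1:3] <- kab * diag(3)
  L
}

#' Numeric 2-site R1rho model
#'
#' Propagates the 6-dimensional (x, y, z per state) Bloch-McConnell
#' magnetization under the spin lock for the duration `relax_time_T`. The
#' initial condition is equilibrium magnetization tilted onto the state-A
#' effective field (hard alignment) and the rate is the log ratio of the
#' projection onto that axis:
#' `R1rho = -ln((v . M(T)) / (v . M(0))) / T`.
#'
#' @param r1 Longitudinal rate, 1/s.
#' @param r20a,r20b Exchange-free rotating-frame transverse rates, 1/s.
#' @param pA Major-state population.
#' @param kex Exchange rate, 1/s.
#' @param dw Shift difference, rad/s (`Omega_B = Omega_A + dw`).
#' @param omega1 Spin-lock amplitude, rad/s (vectorised with `omega_a`).
#' @param omega_a State-A offset from the carrier, rad/s.
#' @param relax_time_T Spin-lock duration, s.
#' @return R1rho in 1/s, one value per condition.
#' @export
ns_r1rho_2site <- function(r1, r20a, r20b = r20a, pA, kex, dw, omega1,
                           omega_a, relax_time_T) {
  stopifnot(length(omega1) == length(omega_a))
  if (any(omega1 <= 0)) stop("omega1 must be > 0", call. = FALSE)
  if (any(relax_time_T <= 0)) stop("relax_time_T must be > 0", call. = FALSE)
  Tt <- rep_len(relax_time_T, length(omega1))
  vapply(seq_along(omega1), function(i) {
    w1 <- omega1[i]
    oa <- omega_a[i]
    L <- build_r1rho_matrix(r1, r20a, r20b, pA, kex, w1, oa, oa + dw)
    th <- atan2(w1, oa)
    axis <- c(sin(th), 0, cos(th))
    M0 <- c(pA * axis, (1 - pA) * axis)
    MT <- as.matrix(Matrix::expm(L * Tt[i])) %*% M0
    proj <- sum(c(axis, 0, 0, 0) * MT)
    if (proj <= 0) {
      stop("non-positive projection: pathological parameters", call. = FALSE)
    }
    -log(proj / pA) / Tt[i]
  }, numeric(1))
}
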