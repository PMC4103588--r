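# Closed-form R2eff(nu_cpmg) for the analytic 2-site CPMG models.
#
# Conventions: tau_cp is the time between consecutive 180-degree pulses,
# nu_cpmg = 1/(2 tau_cp); dw is the A-B shift difference in rad/s (magnitude;
# the 2-site expressions depend on it only through even powers). All
# functions are vectorised over nu_cpmg and return r20 exactly (not just to
# rounding) when exchange vanishes.

check_cpmg_domain <- function(r20, pA, kex, dw, nu_cpmg) {
  if (any(!is.finite(c(r20, pA, kex, dw, nu_cpmg))))
    stop("non-finite model input", call. = FALSE)
  if (any(r20 <= 0)) stop("r20 must be > 0", call. = FALSE)
  if (pA < 0.5 || pA > 1) stop("pA must lie in [0.5, 1]", call. = FALSE)
  if (kex < 0 || dw < 0) stop("kex and dw must be >= 0", call. = FALSE)
  if (any(nu_cpmg <= 0)) stop("nu_cpmg must be > 0", call. = FALSE)
}

#' No-exchange CPMG baseline
#'
#' @param r20 Exchange-free transverse rate in 1/s at the point's field.
#' @param nu_cpmg CPMG frequency in Hz (ignored; the curve is flat).
#' @return `r20` for every `nu_cpmg`.
#' @export
r2eff_norex <- function(r20, nu_cpmg) {
  if (any(!is.finite(r20)) || any(r20 <= 0)) stop("r20 must be > 0", call. = FALSE)
  rep_len(r20, length(nu_cpmg))
}

#' LM63 fast-exchange CPMG model (2-site form)
#'
#' `R2eff = R20 + (phi_ex/kex) * (1 - (4 nu/kex) * tanh(kex/(4 nu)))`.
#'
#' @param r20 Exchange-free rate, 1/s.
#' @param phi_ex Fast-exchange amplitude `pA*pB*dw^2` in rad^2/s^2 at this
#'   field.
#' @param kex Exchange rate `kAB + kBA`, 1/s.
#' @param nu_cpmg CPMG frequency, Hz.
#' @return R2eff in 1/s; non-increasing in `nu_cpmg`.
#' @export
r2eff_lm63 <- function(r20, phi_ex, kex, nu_cpmg) {
  if (any(!is.finite(c(r20, phi_ex, kex, nu_cpmg))))
    stop("non-finite model input", call. = FALSE)
  if (phi_ex < 0) stop("phi_ex must be >= 0", call. = FALSE)
  if (phi_ex == 0) return(rep_len(r20, length(nu_cpmg)))
  if (kex <= 0) stop("kex must be > 0 when phi_ex > 0", call. = FALSE)
  r20 + (phi_ex / kex) * (1 - (4 * nu_cpmg / kex) * tanh(kex / (4 * nu_cpmg)))
}

#' CR72 Carver-Richards CPMG model
#'
#' The closed-form 2-site solution valid across time scales:
#' `R2eff = (R2A0 + R2B0 + kex)/2 - nu_cpmg * acosh(D+ cosh(eta+) -
#' D- cos(eta-))` with `Psi`, `zeta`, `D+-` and
#' `eta+- = sqrt(+-Psi + sqrt(Psi^2 + zeta^2)) / (2 sqrt(2) nu_cpmg)`.
#' The acosh argument is clamped to `>= 1` against rounding and the large
#' `eta+` branch is evaluated in log space to avoid cosh overflow.
#'
#' @param r20a,r20b State A and B exchange-free rates, 1/s (usually equal).
#' @param pA Major-state population, in `(0.5, 1]`.
#' @param kex Exchange rate, 1/s.
#' @param dw Shift difference in rad/s.
#' @param nu_cpmg CPMG frequency, Hz.
#' @return R2eff in 1/s.
#' @export
r2eff_cr72 <- function(r20a, r20b = r20a, pA, kex, dw, nu_cpmg) {
  check_cpmg_domain(c(r20a, r20b), pA, kex, dw, nu_cpmg)
  if (pA == 1 || dw == 0 || kex == 0) return(rep_len(r20a, length(nu_cpmg)))
  pB <- 1 - pA
  fact <- r20a - r20b + (pB - pA) * kex
  Psi <- fact^2 - dw^2 + 4 * pA * pB * kex^2
  zeta <- 2 * dw * fact
  root <- sqrt(Psi^2 + zeta^2)
  Dpos <- 0.5 * (1 + (Psi + 2 * dw^2) / root)
  Dneg <- 0.5 * (-1 + (Psi + 2 * dw^2) / root)
  eta_pos <- sqrt(pmax(Psi + root, 0) / 2) / (2 * nu_cpmg)
  eta_neg <- sqrt(pmax(-Psi + root, 0) / 2) / (2 * nu_cpmg)
  big <- eta_pos > 30  # cosh(eta) ~ exp(eta)/2; acosh(x) ~ log(2x)
  ac <- numeric(length(nu_cpmg))
  arg <- Dpos * cosh(pmin(eta_pos, 30)) - Dneg * cos(eta_neg)
  ac[!big] <- acosh(pmax(arg[!big], 1))
  if (any(big)) ac[big] <- eta_pos[big] + log(Dpos)
  0.5 * (r20a + r20b + kex) - nu_cpmg * ac
}

#' IT99 population-skewed CPMG model
#'
#' `R2eff = R20 + pA*pB*dw^2*kex / (kex^2 + sqrt(pA^2 dw^4 + 144/tau_cp^4))`
#' with `tau_cp = 1/(2 nu_cpmg)`; the truncated expansion valid for skewed
#' populations (`pA` close to 1).
#'
#' @inheritParams r2eff_cr72
#' @param r20 Exchange-free rate, 1/s.
#' @return R2eff in 1/s.
#' @export
r2eff_it99 <- function(r20, pA, kex, dw, nu_cpmg) {
  check_cpmg_domain(r20, pA, kex, dw, nu_cpmg)
  if (pA == 1 || dw == 0 || kex == 0) return(rep_len(r20, length(nu_cpmg)))
  tau_cp <- 1 / (2 * nu_cpmg)
  if (any(tau_cp == 0)) stop("tau_cp must be > 0", call. = FALSE)
  pB <- 1 - pA
  r20 + pA * pB * dw^2 * kex /
    (kex^2 + sqrt(pA^2 * dw^4 + 144 / tau_cp^4))
}

#' TSMFK01 very-slow-exchange CPMG model
#'
#' `R2eff = R2A0 + kAB - kAB * sin(dw tau_cp)/(dw tau_cp)` with
#' `tau_cp = 1/(2 nu_cpmg)`; the forward rate `kAB` is the only kinetic
#' parameter in the slow-exchange limit. The sinc is evaluated by series for
#' small arguments (removable singularity).
#'
#' @param r20a State-A exchange-free rate, 1/s.
#' @param kab Forward exchange rate A->B, 1/s.
#' @param dw Shift difference, rad/s.
#' @param nu_cpmg CPMG frequency, Hz.
#' @return R2eff in 1/s.
#' @export
r2eff_tsmfk01 <- function(r20a, kab, dw, nu_cpmg) {
  if (any(!is.finite(c(r20a, kab, dw, nu_cpmg))))
    stop("non-finite model input", call. = FALSE)
  if (kab < 0 || dw < 0) stop("kab and dw must be >= 0", call. = FALSE)
  if (kab == 0 || dw == 0) return(rep_len(r20a, length(nu_cpmg)))
  x <- dw / (2 * nu_cpmg)  # dw * tau_cp
  s <- ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  r20a + kab - kab * s
}

#' MMQ extension of CR72 for multiple-quantum CPMG data
#'
#' The CR72 functional form evaluated with the coherence-dependent effective
#' shift: SQ uses `dw`; ZQ uses `dw - dwH`; DQ uses `dw + dwH`; MQ averages
#' the decays of its ZQ- and DQ-like components over the relaxation period
#' `T` (`R = -ln((exp(-R_ZQ T) + exp(-R_DQ T))/2) / T`), matching the
#' component-averaged extraction of the numeric MMQ solution.
#'
#' @inheritParams r2eff_cr72
#' @param dwH Proton shift difference in rad/s (required for ZQ/DQ/MQ).
#' @param relax_time_T Relaxation period in s (used by the MQ branch).
#' @param exp_type One of `"CPMG_SQ"`, `"CPMG_ZQ"`, `"CPMG_DQ"`, `"CPMG_MQ"`.
#' @return R2eff in 1/s.
#' @export
r2eff_mmq_cr72 <- function(r20a, r20b = r20a, pA, kex, dw, dwH = NULL,
                           nu_cpmg, relax_time_T = NULL,
                           exp_type = "CPMG_SQ") {
  if (!exp_type %in% c("CPMG_SQ", "CPMG_ZQ", "CPMG_DQ", "CPMG_MQ")) {
    stop("exp_type must be a CPMG coherence type", call. = FALSE)
  }
  if (exp_type != "CPMG_SQ" && is.null(dwH)) {
    stop("dwH is required for ZQ/DQ/MQ data", call. = FALSE)
  }
  if (is.null(dwH)) dwH <- 0
  switch(exp_type,
    CPMG_SQ = r2eff_cr72(r20a, r20b, pA, kex, dw, nu_cpmg),
    CPMG_ZQ = r2eff_cr72(r20a, r20b, pA, kex, abs(dw - dwH), nu_cpmg),
    CPMG_DQ = r2eff_cr72(r20a, r20b, pA, kex, dw + dwH, nu_cpmg),
    CPMG_MQ = {
      if (is.null(relax_time_T)) {
        stop("relax_time_T is required for MQ data", call. = FALSE)
      }
      rzq <- r2eff_cr72(r20a, r20b, pA, kex, abs(dw - dwH), nu_cpmg)
      rdq <- r2eff_cr72(r20a, r20b, pA, kex, dw + dwH, nu_cpmg)
      rmin <- pmin(rzq, rdq)
      # log-mean-exp relative to the faster-decaying component
      -(log(0.5 * (exp(-(rzq - rmin) * relax_time_T) +
                   exp(-(rdq - rmin) * relax_time_T))) / relax_time_T) + rmin
    })
}
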