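# Closed-form R1rho models for 2-site exchange under a spin lock.
#
# Geometry: Omega_A is the state-A resonance offset from the spin-lock
# carrier (rad/s, signed), Omega_B = Omega_A + dw with dw stored positive,
# Omega_avg = pA*Omega_A + pB*Omega_B, theta = atan2(omega1, Omega_avg),
# omega_eff^2 = Omega_avg^2 + omega1^2. The fast-exchange models (M61,
# DPL94) use the averaged geometry; TP02/MP05 additionally use the
# state-specific effective fields, per their derivations.

#' Spin-lock geometry for one condition
#'
#' @param omega1 Spin-lock amplitude in rad/s (`> 0`).
#' @param omega_a State-A offset from the carrier in rad/s (signed).
#' @param dw Shift difference A-B in rad/s (stored positive;
#'   `Omega_B = Omega_A + dw`).
#' @param pA Major-state population.
#' @return A list with `omega1`, `Omega_A`, `Omega_B`, `Omega_avg`, `theta`
#'   (tilt angle in `(0, pi)`), `omega_eff_sq`, `wA_eff_sq`, `wB_eff_sq`.
#'   All entries are vectorised over the inputs.
#' @export
spin_lock_geometry <- function(omega1, omega_a, dw = 0, pA = 1) {
  if (any(omega1 <= 0)) stop("omega1 must be > 0", call. = FALSE)
  pB <- 1 - pA
  omega_b <- omega_a + dw
  omega_avg <- pA * omega_a + pB * omega_b
  list(omega1 = omega1,
       Omega_A = omega_a,
       Omega_B = omega_b,
       Omega_avg = omega_avg,
       theta = atan2(omega1, omega_avg),
       omega_eff_sq = omega_avg^2 + omega1^2,
       wA_eff_sq = omega_a^2 + omega1^2,
       wB_eff_sq = omega_b^2 + omega1^2)
}

#' Rotating-frame no-exchange baseline
#'
#' `R1rho = R1 cos^2(theta) + R1rho' sin^2(theta)`.
#'
#' @param r1 Longitudinal rate, 1/s.
#' @param r1rho_prime Exchange-free transverse rate in the rotating frame, 1/s.
#' @param theta Effective-field tilt angle, rad.
#' @return R1rho in 1/s.
#' @export
r1rho_norex <- function(r1, r1rho_prime, theta) {
  r1 * cos(theta)^2 + r1rho_prime * sin(theta)^2
}

#' M61 fast-exchange on-resonance R1rho model
#'
#' `R1rho = R1rho' + phi_ex * kex / (kex^2 + omega1^2)`. Intended for
#' on-resonance data; a warning is emitted when `|Omega_avg| / omega1`
#' exceeds `on_resonance_tol`.
#'
#' @param r1rho_prime Exchange-free rotating-frame rate, 1/s.
#' @param phi_ex `pA*pB*dw^2` in rad^2/s^2 at this field.
#' @param kex Exchange rate, 1/s.
#' @param geom Output of [spin_lock_geometry()].
#' @param on_resonance_tol Warning threshold on `|Omega_avg|/omega1`.
#' @return R1rho in 1/s.
#' @export
r1rho_m61 <- function(r1rho_prime, phi_ex, kex, geom, on_resonance_tol = 0.01) {
  if (phi_ex < 0 || kex < 0) stop("phi_ex and kex must be >= 0", call. = FALSE)
  if (any(abs(geom$Omega_avg) / geom$omega1 > on_resonance_tol)) {
    warning("M61 applied to off-resonance data (|Omega_avg|/omega1 > ",
            on_resonance_tol, ")", call. = FALSE)
  }
  if (phi_ex == 0) return(rep_len(r1rho_prime, length(geom$omega1)))
  r1rho_prime + phi_ex * kex / (kex^2 + geom$omega1^2)
}

#' DPL94 fast-exchange off-resonance R1rho model
#'
#' `R1rho = R1 cos^2(theta) + sin^2(theta) * (R1rho' +
#' phi_ex * kex / (kex^2 + omega_eff^2))`; reduces exactly to M61 at
#' `theta = pi/2`.
#'
#' @inheritParams r1rho_m61
#' @param r1 Measured longitudinal rate, 1/s.
#' @return R1rho in 1/s.
#' @export
r1rho_dpl94 <- function(r1, r1rho_prime, phi_ex, kex, geom) {
  if (phi_ex < 0 || kex < 0) stop("phi_ex and kex must be >= 0", call. = FALSE)
  rex <- if (phi_ex == 0) 0 else phi_ex * kex / (kex^2 + geom$omega_eff_sq)
  r1 * cos(geom$theta)^2 + sin(geom$theta)^2 * (r1rho_prime + rex)
}

#' TP02 R1rho model for non-fast exchange
#'
#' `R1rho = R1 cos^2(theta) + R1rho' sin^2(theta) + sin^2(theta) *
#' pA*pB*dw^2*kex / (wA_eff^2 wB_eff^2 / w_eff^2 + kex^2)` with
#' `wX_eff^2 = Omega_X^2 + omega1^2`; valid for skewed populations
#' (`pB` small).
#'
#' @inheritParams r1rho_dpl94
#' @param pA Major-state population.
#' @param dw Shift difference, rad/s.
#' @return R1rho in 1/s.
#' @export
r1rho_tp02 <- function(r1, r1rho_prime, pA, kex, dw, geom) {
  base <- r1rho_norex(r1, r1rho_prime, geom$theta)
  if (pA == 1 || dw == 0 || kex == 0) return(base)
  pB <- 1 - pA
  base + sin(geom$theta)^2 * pA * pB * dw^2 * kex /
    (geom$wA_eff_sq * geom$wB_eff_sq / geom$omega_eff_sq + kex^2)
}

#' MP05 R1rho model for all time scales
#'
#' The TP02 expression with the second-order denominator correction in the
#' populations and state effective fields:
#' `denom = wA_eff^2 wB_eff^2 / w_eff^2 + kex^2 - sin^2(theta) pA pB dw^2 *
#' (1 + 2 kex^2 (pA wA_eff^2 + pB wB_eff^2) /
#' (wA_eff^2 wB_eff^2 + w_eff^2 kex^2))`; reduces to TP02 when the
#' correction is negligible.
#'
#' @inheritParams r1rho_tp02
#' @return R1rho in 1/s.
#' @export
r1rho_mp05 <- function(r1, r1rho_prime, pA, kex, dw, geom) {
  base <- r1rho_norex(r1, r1rho_prime, geom$theta)
  if (pA == 1 || dw == 0 || kex == 0) return(base)
  pB <- 1 - pA
  sin2 <- sin(geom$theta)^2
  waw <- geom$wA_eff_sq * geom$wB_eff_sq
  denom <- waw / geom$omega_eff_sq + kex^2 -
    sin2 * pA * pB * dw^2 *
      (1 + 2 * kex^2 * (pA * geom$wA_eff_sq + pB * geom$wB_eff_sq) /
             (waw + geom$omega_eff_sq * kex^2))
  base + sin2 * pA * pB * dw^2 * kex / denom
}
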