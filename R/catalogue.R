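# The model catalogue: parameter templates, bounds, grids and applicability.
#
# Parameter scopes: "global" parameters (pA, kex, kAB) are shared by every
# spin of a cluster; "spin" parameters (dw, dwH, phi_ex) are one per spin;
# "spin_field" parameters (r20) are one per spin per static field. Shift
# parameters are user-facing: dw and dwH in ppm, phi_ex in ppm^2 (converted
# to rad/s and rad^2/s^2 at each point's field), so that one value describes
# all fields. For rotating-frame models the r20 symbol holds the
# exchange-free R1rho' at each field.

.pA_max <- 1 - 1e-6

.param_row <- function(symbol, scope, lower, upper, grid) {
  data.frame(symbol = symbol, scope = scope, lower = lower, upper = upper,
             grid = grid, stringsAsFactors = FALSE)
}

.r20_row <- .param_row("r20", "spin_field", 0.1, 200, "seed")
.dw_row <- .param_row("dw", "spin", 0, 30, "linear")
.dwH_row <- .param_row("dwH", "spin", 0, 30, "linear")
.phi_row <- .param_row("phi_ex", "spin", 1e-4, 225, "log")
.pA_row <- .param_row("pA", "global", 0.5, .pA_max, "linear")
.kex_row <- .param_row("kex", "global", 1, 1e6, "log")
.kab_row <- .param_row("kAB", "global", 0.01, 1e4, "log")

.cpmg_sq <- "CPMG_SQ"
.cpmg_mmq <- c("CPMG_SQ", "CPMG_ZQ", "CPMG_DQ", "CPMG_MQ")
.r1rho <- "R1RHO"

.catalogue <- list(
  NoRex = list(exp_types = c(.cpmg_mmq, .r1rho), params = .r20_row),
  LM63 = list(exp_types = .cpmg_sq,
              params = rbind(.kex_row, .phi_row, .r20_row)),
  IT99 = list(exp_types = .cpmg_sq,
              params = rbind(.pA_row, .kex_row, .dw_row, .r20_row)),
  TSMFK01 = list(exp_types = .cpmg_sq,
                 params = rbind(.kab_row, .dw_row, .r20_row)),
  CR72 = list(exp_types = .cpmg_sq,
              params = rbind(.pA_row, .kex_row, .dw_row, .r20_row)),
  MMQ_CR72 = list(exp_types = .cpmg_mmq,
                  params = rbind(.pA_row, .kex_row, .dw_row, .dwH_row,
                                 .r20_row)),
  NS_CPMG_2site = list(exp_types = .cpmg_sq,
                       params = rbind(.pA_row, .kex_row, .dw_row, .r20_row)),
  NS_MMQ_2site = list(exp_types = .cpmg_mmq,
                      params = rbind(.pA_row, .kex_row, .dw_row, .dwH_row,
                                     .r20_row)),
  M61 = list(exp_types = .r1rho,
             params = rbind(.kex_row, .phi_row, .r20_row)),
  DPL94 = list(exp_types = .r1rho,
               params = rbind(.kex_row, .phi_row, .r20_row)),
  TP02 = list(exp_types = .r1rho,
              params = rbind(.pA_row, .kex_row, .dw_row, .r20_row)),
  MP05 = list(exp_types = .r1rho,
              params = rbind(.pA_row, .kex_row, .dw_row, .r20_row)),
  NS_R1rho_2site = list(exp_types = .r1rho,
                        params = rbind(.pA_row, .kex_row, .dw_row, .r20_row))
)

#' List the dispersion model catalogue
#'
#' Returns the implemented models in optimisation order (simple to complex,
#' so every warm-start source is fitted before its targets), with the
#' experiment types each supports and its parameter template (symbol, scope,
#' bounds, grid type).
#'
#' @return A named list of model specifications.
#' @export
list_models <- function() .catalogue

model_names <- function() names(.catalogue)

model_spec <- function(model) {
  spec <- .catalogue[[model]]
  if (is.null(spec)) stop("unknown model: ", model, call. = FALSE)
  spec
}

# Is the model applicable to a spin measured under these conditions?
# M61 additionally requires (near) on-resonance spin-lock data.
model_applicable <- function(model, pts, shift_ppm = 0, isotope = "15N") {
  spec <- model_spec(model)
  if (!all(pts$exp_type %in% spec$exp_types)) return(FALSE)
  if (model == "M61") {
    conv <- 2 * pi * pts$field_h1_mhz * gamma_ratio(isotope)
    om_a <- (shift_ppm - pts$offset_ppm) * conv
    if (any(abs(om_a) / (2 * pi * pts$omega1) > 0.01)) return(FALSE)
  }
  if (model %in% c("DPL94", "TP02", "MP05", "NS_R1rho_2site") &&
      any(!is.finite(pts$r1))) {
    return(FALSE)
  }
  TRUE
}

# Back-calculate rates for one spin under a parameter list `p` with entries
# r20 (named by field), pA, kex, dw, dwH, phi_ex, kAB as the model requires.
backcalc_rates <- function(model, p, pts, isotope = "15N", shift_ppm = 0) {
  out <- numeric(nrow(pts))
  conv <- 2 * pi * pts$field_h1_mhz * gamma_ratio(isotope)
  r20_of <- function(i) {
    r <- p$r20[as.character(pts$field_h1_mhz[i])]
    if (any(is.na(r))) stop("missing r20 for field", call. = FALSE)
    unname(r)
  }
  if (model %in% c("NoRex", "LM63", "IT99", "TSMFK01", "CR72", "MMQ_CR72",
                   "NS_CPMG_2site", "NS_MMQ_2site") &&
      any(pts$exp_type == "R1RHO") && model != "NoRex") {
    stop("CPMG model applied to R1RHO data", call. = FALSE)
  }
  is_r1rho <- pts$exp_type == "R1RHO"
  if (any(is_r1rho)) {
    i <- which(is_r1rho)
    w1 <- 2 * pi * pts$omega1[i]
    om_a <- (shift_ppm - pts$offset_ppm[i]) * conv[i]
    dw_rad <- if (is.null(p$dw)) 0 else p$dw * conv[i]
    pA <- if (is.null(p$pA)) 1 else p$pA
    geom <- spin_lock_geometry(w1, om_a, dw_rad, pA)
    r1 <- pts$r1[i]
    rp <- r20_of(i)
    out[i] <- switch(model,
      NoRex = r1rho_norex(ifelse(is.finite(r1), r1, 0), rp,
                          spin_lock_geometry(w1, om_a)$theta),
      M61 = r1rho_m61(rp, p$phi_ex * conv[i]^2, p$kex,
                      spin_lock_geometry(w1, om_a)),
      DPL94 = r1rho_dpl94(r1, rp, p$phi_ex * conv[i]^2, p$kex,
                          spin_lock_geometry(w1, om_a)),
      TP02 = r1rho_tp02(r1, rp, pA, p$kex, dw_rad, geom),
      MP05 = r1rho_mp05(r1, rp, pA, p$kex, dw_rad, geom),
      NS_R1rho_2site = ns_r1rho_2site(r1[1], rp[1], rp[1], pA, p$kex,
                                      dw_rad[1], w1, om_a,
                                      pts$relax_time_T[i]),
      stop("model ", model, " does not apply to R1RHO data", call. = FALSE))
  }
  if (any(!is_r1rho)) {
    # group CPMG points by (field, exp_type, T) so dw converts once per group
    i_all <- which(!is_r1rho)
    key <- paste(pts$field_h1_mhz[i_all], pts$exp_type[i_all],
                 pts$relax_time_T[i_all])
    for (k in unique(key)) {
      i <- i_all[key == k]
      nu <- pts$nu_cpmg[i]
      Tt <- pts$relax_time_T[i[1]]
      et <- pts$exp_type[i[1]]
      cv <- conv[i[1]]
      r20 <- r20_of(i[1])
      out[i] <- switch(model,
        NoRex = r2eff_norex(r20, nu),
        LM63 = r2eff_lm63(r20, p$phi_ex * cv^2, p$kex, nu),
        IT99 = r2eff_it99(r20, p$pA, p$kex, p$dw * cv, nu),
        TSMFK01 = r2eff_tsmfk01(r20, p$kAB, p$dw * cv, nu),
        CR72 = r2eff_cr72(r20, r20, p$pA, p$kex, p$dw * cv, nu),
        MMQ_CR72 = r2eff_mmq_cr72(r20, r20, p$pA, p$kex, p$dw * cv,
                                  p$dwH * 2 * pi * pts$field_h1_mhz[i[1]],
                                  nu, Tt, et),
        NS_CPMG_2site = ns_cpmg_2site(r20, r20, p$pA, p$kex, p$dw * cv, nu,
                                      Tt),
        NS_MMQ_2site = ns_mmq_2site(r20, r20, p$pA, p$kex, p$dw * cv,
                                    p$dwH * 2 * pi * pts$field_h1_mhz[i[1]],
                                    nu, Tt, et),
        stop("model ", model, " does not apply to CPMG data", call. = FALSE))
    }
  }
  out
}
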