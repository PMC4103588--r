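# Precompiled evaluation plans: the chi-squared target is evaluated many
# thousand times per fit, so the (spin, condition-group) structure, unit
# conversions and parameter-index lookups are resolved once into closures
# over plain numeric vectors.

# Index of a parameter row for symbol `sym` of spin `s` (global rows match
# any spin); NA_integer_ when the model has no such symbol.
.pv_idx <- function(pv, sym, s, field = NULL) {
  i <- which(pv$symbol == sym &
               (is.na(pv$spin_id) | pv$spin_id == s) &
               (if (is.null(field)) TRUE else
                  !is.na(pv$field) & pv$field == field))
  if (length(i)) i[1] else NA_integer_
}

# One closure per (spin, field, exp_type, T) group mapping the free-parameter
# vector to back-calculated rates.
.cpmg_group_fun <- function(model, pv, s, field, exp_type, Tt, nu, isotope) {
  conv <- 2 * pi * field * gamma_ratio(isotope)
  convH <- 2 * pi * field
  i_r20 <- .pv_idx(pv, "r20", s, field)
  i_pA <- .pv_idx(pv, "pA", s)
  i_kex <- .pv_idx(pv, "kex", s)
  i_dw <- .pv_idx(pv, "dw", s)
  i_dwH <- .pv_idx(pv, "dwH", s)
  i_phi <- .pv_idx(pv, "phi_ex", s)
  i_kab <- .pv_idx(pv, "kAB", s)
  switch(model,
    NoRex = function(v) rep_len(v[i_r20], length(nu)),
    LM63 = function(v) r2eff_lm63(v[i_r20], v[i_phi] * conv^2, v[i_kex], nu),
    IT99 = function(v) r2eff_it99(v[i_r20], v[i_pA], v[i_kex],
                                  v[i_dw] * conv, nu),
    TSMFK01 = function(v) r2eff_tsmfk01(v[i_r20], v[i_kab],
                                        v[i_dw] * conv, nu),
    CR72 = function(v) r2eff_cr72(v[i_r20], v[i_r20], v[i_pA], v[i_kex],
                                  v[i_dw] * conv, nu),
    MMQ_CR72 = function(v) r2eff_mmq_cr72(v[i_r20], v[i_r20], v[i_pA],
                                          v[i_kex], v[i_dw] * conv,
                                          v[i_dwH] * convH, nu, Tt, exp_type),
    NS_CPMG_2site = function(v) ns_cpmg_2site(v[i_r20], v[i_r20], v[i_pA],
                                              v[i_kex], v[i_dw] * conv, nu,
                                              Tt),
    NS_MMQ_2site = function(v) ns_mmq_2site(v[i_r20], v[i_r20], v[i_pA],
                                            v[i_kex], v[i_dw] * conv,
                                            v[i_dwH] * convH, nu, Tt,
                                            exp_type),
    stop("model ", model, " does not apply to CPMG data", call. = FALSE))
}

.r1rho_group_fun <- function(model, pv, s, field, Tt, w1, oa, r1, isotope) {
  conv <- 2 * pi * field * gamma_ratio(isotope)
  i_r20 <- .pv_idx(pv, "r20", s, field)
  i_pA <- .pv_idx(pv, "pA", s)
  i_kex <- .pv_idx(pv, "kex", s)
  i_dw <- .pv_idx(pv, "dw", s)
  i_phi <- .pv_idx(pv, "phi_ex", s)
  # geometry of the carrier-referenced state-A offset (used where the model
  # carries no dw: NoRex, M61, DPL94)
  theta0 <- atan2(w1, oa)
  cos2 <- cos(theta0)^2
  sin2 <- sin(theta0)^2
  weff2_0 <- oa^2 + w1^2
  r1z <- ifelse(is.finite(r1), r1, 0)
  switch(model,
    NoRex = function(v) r1z * cos2 + v[i_r20] * sin2,
    M61 = function(v) {
      kex <- v[i_kex]
      v[i_r20] + v[i_phi] * conv^2 * kex / (kex^2 + w1^2)
    },
    DPL94 = function(v) {
      kex <- v[i_kex]
      r1 * cos2 + sin2 * (v[i_r20] + v[i_phi] * conv^2 * kex /
                            (kex^2 + weff2_0))
    },
    TP02 = function(v) {
      pA <- v[i_pA]; kex <- v[i_kex]; dw <- v[i_dw] * conv
      g <- spin_lock_geometry(w1, oa, dw, pA)
      r1rho_tp02(r1, v[i_r20], pA, kex, dw, g)
    },
    MP05 = function(v) {
      pA <- v[i_pA]; kex <- v[i_kex]; dw <- v[i_dw] * conv
      g <- spin_lock_geometry(w1, oa, dw, pA)
      r1rho_mp05(r1, v[i_r20], pA, kex, dw, g)
    },
    NS_R1rho_2site = function(v) ns_r1rho_2site(r1[1], v[i_r20], v[i_r20],
                                                v[i_pA], v[i_kex],
                                                v[i_dw] * conv, w1, oa, Tt),
    stop("model ", model, " does not apply to R1RHO data", call. = FALSE))
}

# Compile the full plan: group closures plus observations and weights.
build_plan <- function(model, pv, dataset, spin_ids) {
  groups <- list()
  n <- 0L
  for (s in sort(spin_ids)) {
    srow <- dataset$spins[dataset$spins$spin_id == s, ]
    d <- spin_data(dataset, s)
    if (any(d$error <= 0)) {
      stop("chi2 requires errors > 0 for every point", call. = FALSE)
    }
    n <- n + nrow(d)
    is_rho <- d$exp_type == "R1RHO"
    if (any(!is_rho)) {
      dc <- d[!is_rho, ]
      key <- paste(dc$field_h1_mhz, dc$exp_type, dc$relax_time_T)
      for (k in unique(key)) {
        g <- dc[key == k, ]
        groups[[length(groups) + 1L]] <- list(
          fun = .cpmg_group_fun(model, pv, s, g$field_h1_mhz[1],
                                g$exp_type[1], g$relax_time_T[1],
                                g$nu_cpmg, srow$isotope),
          obs = g$value, winv = 1 / g$error)
      }
    }
    if (any(is_rho)) {
      dr <- d[is_rho, ]
      key <- paste(dr$field_h1_mhz, dr$relax_time_T)
      for (k in unique(key)) {
        g <- dr[key == k, ]
        conv <- 2 * pi * g$field_h1_mhz[1] * gamma_ratio(srow$isotope)
        oa <- (srow$shift_ppm - g$offset_ppm) * conv
        groups[[length(groups) + 1L]] <- list(
          fun = .r1rho_group_fun(model, pv, s, g$field_h1_mhz[1],
                                 g$relax_time_T[1], 2 * pi * g$omega1, oa,
                                 g$r1, srow$isotope),
          obs = g$value, winv = 1 / g$error)
      }
    }
  }
  list(groups = groups, n = n)
}

# Parameter regions where a numeric propagation fails (magnetization decayed
# through zero) score Inf, so optimisers and grids simply avoid them.
chi2_plan <- function(plan, v) {
  tot <- 0
  for (g in plan$groups) {
    calc <- tryCatch(g$fun(v), error = function(e) NULL)
    if (is.null(calc) || anyNA(calc)) return(Inf)
    tot <- tot + sum(((calc - g$obs) * g$winv)^2)
  }
  tot
}
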