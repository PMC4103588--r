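# The dispersion dataset container: spins x measurement conditions -> rates.

.exp_types <- c("CPMG_SQ", "CPMG_MQ", "CPMG_ZQ", "CPMG_DQ", "R1RHO")

#' Construct a table of spin systems
#'
#' @param spin_id Character vector of unique spin identifiers
#'   (residue/atom, e.g. `"R2:N"`).
#' @param isotope Isotope per spin (`"1H"`, `"15N"`, `"13C"`); recycled.
#' @param cluster_id Optional cluster label per spin; spins sharing a label are
#'   constrained to common exchange kinetics (pA, kex) in clustered fits.
#'   `NA` means the spin is analysed on its own.
#' @param shift_ppm Chemical shift of the major state in ppm, used only to
#'   place R1rho resonance offsets relative to the spin-lock carrier.
#' @return A `data.frame` with one row per spin.
#' @export
spin_systems <- function(spin_id, isotope = "15N", cluster_id = NA_character_,
                         shift_ppm = 0) {
  if (anyDuplicated(spin_id)) stop("spin_id values must be unique", call. = FALSE)
  gamma_ratio(unique(isotope))  # validates isotopes
  data.frame(spin_id = as.character(spin_id),
             isotope = rep_len(as.character(isotope), length(spin_id)),
             cluster_id = rep_len(as.character(cluster_id), length(spin_id)),
             shift_ppm = rep_len(as.numeric(shift_ppm), length(spin_id)),
             stringsAsFactors = FALSE)
}

#' Construct a table of experiment points (measurement conditions)
#'
#' Each row is one condition: a CPMG point carries the pulse-train frequency
#' `nu_cpmg` (Hz) and the constant relaxation period `relax_time_T` (s); an
#' R1rho point carries the spin-lock amplitude `omega1` (Hz, as omega1/2pi),
#' the carrier offset (ppm), the spin-lock duration `relax_time_T` and the
#' measured longitudinal rate `r1` (1/s, needed by off-resonance models).
#'
#' @param exp_type One of `r paste(.exp_types, collapse = ", ")`; recycled.
#' @param field_h1_mhz Static field as proton Larmor MHz.
#' @param nu_cpmg CPMG frequency in Hz (`NA` for R1rho rows).
#' @param relax_time_T Relaxation period in s.
#' @param omega1 Spin-lock amplitude in Hz (`NA` for CPMG rows).
#' @param offset_ppm Spin-lock carrier offset in ppm (`NA` for CPMG rows).
#' @param r1 Measured R1 in 1/s (`NA` when unused).
#' @return A `data.frame` with a `point_id` key column.
#' @export
experiment_points <- function(exp_type, field_h1_mhz, nu_cpmg = NA_real_,
                              relax_time_T, omega1 = NA_real_,
                              offset_ppm = NA_real_, r1 = NA_real_) {
  n <- max(length(exp_type), length(field_h1_mhz), length(nu_cpmg),
           length(relax_time_T), length(omega1), length(offset_ppm), length(r1))
  pts <- data.frame(point_id = seq_len(n),
                    exp_type = rep_len(as.character(exp_type), n),
                    field_h1_mhz = rep_len(as.numeric(field_h1_mhz), n),
                    nu_cpmg = rep_len(as.numeric(nu_cpmg), n),
                    relax_time_T = rep_len(as.numeric(relax_time_T), n),
                    omega1 = rep_len(as.numeric(omega1), n),
                    offset_ppm = rep_len(as.numeric(offset_ppm), n),
                    r1 = rep_len(as.numeric(r1), n),
                    stringsAsFactors = FALSE)
  validate_points(pts)
  pts
}

validate_points <- function(pts) {
  if (!all(pts$exp_type %in% .exp_types)) {
    stop("exp_type must be one of: ", paste(.exp_types, collapse = ", "),
         call. = FALSE)
  }
  cpmg <- pts$exp_type != "R1RHO"
  if (any(cpmg & (!is.finite(pts$nu_cpmg) | pts$nu_cpmg <= 0))) {
    stop("CPMG points require nu_cpmg > 0", call. = FALSE)
  }
  if (any(!is.finite(pts$relax_time_T) | pts$relax_time_T <= 0)) {
    stop("relax_time_T must be > 0 for every point", call. = FALSE)
  }
  if (any(!cpmg & (!is.finite(pts$omega1) | pts$omega1 <= 0))) {
    stop("R1RHO points require omega1 > 0", call. = FALSE)
  }
  invisible(pts)
}

#' Assemble a dispersion dataset
#'
#' Binds spins, experiment points and observed rates (R2eff or R1rho, with one
#' standard deviation each) into a validated container. Every value must refer
#' to an existing spin and point, every spin must carry at least one value,
#' and all CPMG points of one (spin, field) combination must share a single
#' constant relaxation period.
#'
#' @param spins Output of [spin_systems()].
#' @param points Output of [experiment_points()].
#' @param values A `data.frame` with columns `spin_id`, `point_id`, `value`,
#'   `error` (rates in 1/s; `error` is one s.d., `>= 0`).
#' @return An object of class `dispersion_dataset`.
#' @export
dispersion_dataset <- function(spins, points, values) {
  validate_points(points)
  stopifnot(all(c("spin_id", "point_id", "value", "error") %in% names(values)))
  values <- data.frame(spin_id = as.character(values$spin_id),
                       point_id = as.integer(values$point_id),
                       value = as.numeric(values$value),
                       error = as.numeric(values$error),
                       stringsAsFactors = FALSE)
  if (!all(values$spin_id %in% spins$spin_id)) {
    stop("value refers to unknown spin_id", call. = FALSE)
  }
  if (!all(values$point_id %in% points$point_id)) {
    stop("value refers to unknown point_id", call. = FALSE)
  }
  if (!all(spins$spin_id %in% values$spin_id)) {
    stop("every spin must have at least one value", call. = FALSE)
  }
  if (any(!is.finite(values$value)) || any(values$error < 0)) {
    stop("values must be finite and errors >= 0", call. = FALSE)
  }
  if (anyDuplicated(values[, c("spin_id", "point_id")])) {
    stop("duplicate (spin_id, point_id) value", call. = FALSE)
  }
  # one constant relaxation period per (spin, field) for CPMG data
  pts <- points[match(values$point_id, points$point_id), ]
  cpmg <- pts$exp_type != "R1RHO"
  if (any(cpmg)) {
    key <- paste(values$spin_id[cpmg], pts$field_h1_mhz[cpmg], pts$exp_type[cpmg])
    nT <- tapply(pts$relax_time_T[cpmg], key, function(x) length(unique(x)))
    if (any(nT > 1)) {
      stop("all CPMG points of one (spin, field) must share one relax_time_T",
           call. = FALSE)
    }
  }
  structure(list(spins = spins, points = points, values = values),
            class = "dispersion_dataset")
}

#' @export
print.dispersion_dataset <- function(x, ...) {
  cat("<dispersion_dataset> ", nrow(x$spins), " spin(s), ",
      nrow(x$points), " condition(s), ", nrow(x$values), " value(s)\n", sep = "")
  cat("  experiment types: ", paste(unique(x$points$exp_type), collapse = ", "),
      "\n  fields (1H MHz): ",
      paste(sort(unique(x$points$field_h1_mhz)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Observed values for one spin, joined with their conditions.
spin_data <- function(dataset, spin_id) {
  v <- dataset$values[dataset$values$spin_id == spin_id, , drop = FALSE]
  p <- dataset$points[match(v$point_id, dataset$points$point_id), , drop = FALSE]
  cbind(v[, c("value", "error")], p)
}

dataset_fields <- function(dataset, spin_id = NULL) {
  if (is.null(spin_id)) return(sort(unique(dataset$points$field_h1_mhz)))
  v <- dataset$values[dataset$values$spin_id == spin_id, ]
  p <- dataset$points[match(v$point_id, dataset$points$point_id), ]
  sort(unique(p$field_h1_mhz))
}
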