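# Synthetic dispersion data with known ground truth.

#' Describe a synthetic dispersion study
#'
#' @param model Generating model name from [list_models()].
#' @param params Named list of true parameters (shared by all spins), or a
#'   named list of such lists keyed by `spin_id` for per-spin truths. Each
#'   list uses the catalogue symbols: `r20` (named by field, or a scalar
#'   recycled over fields), `pA`, `kex`, `dw` (ppm), `dwH` (ppm), `phi_ex`
#'   (ppm^2), `kAB`.
#' @param fields Static fields as proton Larmor MHz.
#' @param nu_cpmg CPMG frequencies in Hz (CPMG designs).
#' @param relax_time_T Relaxation period in s.
#' @param omega1 Spin-lock amplitudes in Hz (R1rho designs).
#' @param offset_ppm Spin-lock carrier offsets in ppm (R1rho designs;
#'   crossed with `omega1`).
#' @param r1 Longitudinal rate in 1/s (R1rho designs).
#' @param sigma Gaussian noise s.d. on the rates, 1/s.
#' @param spins A [spin_systems()] table (default: one 15N spin).
#' @param exp_type Experiment type for CPMG designs (default SQ).
#' @param seed Mandatory seed for reproducibility.
#' @return A `sim_design` list.
#' @export
sim_design <- function(model, params, fields = 600, nu_cpmg = NULL,
                       relax_time_T = 0.04, omega1 = NULL, offset_ppm = 0,
                       r1 = 1.5, sigma = 0.5, spins = spin_systems("S1:N"),
                       exp_type = "CPMG_SQ", seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (!model %in% model_names()) stop("unknown model: ", model, call. = FALSE)
  if (is.null(nu_cpmg) && is.null(omega1)) {
    stop("the condition grid is empty: give nu_cpmg or omega1", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(model = model, params = params, fields = fields,
                 nu_cpmg = nu_cpmg, relax_time_T = relax_time_T,
                 omega1 = omega1, offset_ppm = offset_ppm, r1 = r1,
                 sigma = sigma, spins = spins, exp_type = exp_type,
                 seed = seed),
            class = "sim_design")
}

design_points <- function(design) {
  if (!is.null(design$nu_cpmg)) {
    grid <- expand.grid(nu_cpmg = design$nu_cpmg, field = design$fields)
    experiment_points(design$exp_type, grid$field, grid$nu_cpmg,
                      design$relax_time_T)
  } else {
    grid <- expand.grid(omega1 = design$omega1, offset = design$offset_ppm,
                        field = design$fields)
    experiment_points("R1RHO", grid$field, NA_real_, design$relax_time_T,
                      grid$omega1, grid$offset, design$r1)
  }
}

design_params <- function(design, spin_id) {
  p <- design$params
  if (!is.null(names(p)) && spin_id %in% names(p) && is.list(p[[spin_id]])) {
    p <- p[[spin_id]]
  }
  if (!is.null(p$r20) && is.null(names(p$r20))) {
    p$r20 <- setNames(rep_len(p$r20, length(design$fields)),
                      as.character(design$fields))
  }
  p
}

#' Simulate a dispersion dataset from a known truth
#'
#' Back-calculates the rates of every spin under the design's model and
#' parameters, adds Gaussian noise with standard deviation `sigma`, and
#' stores `sigma` as the per-point error.
#'
#' @param design A [sim_design()].
#' @return A [dispersion_dataset()] with attribute `truth` (the per-spin
#'   parameter lists used).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  points <- design_points(design)
  set.seed(design$seed %% 2147483647L)
  vals <- list()
  truth <- list()
  for (i in seq_len(nrow(design$spins))) {
    s <- design$spins[i, ]
    p <- design_params(design, s$spin_id)
    truth[[s$spin_id]] <- p
    rates <- backcalc_rates(design$model, p, points, s$isotope, s$shift_ppm)
    vals[[i]] <- data.frame(spin_id = s$spin_id, point_id = points$point_id,
                            value = rates + rnorm(nrow(points)) * design$sigma,
                            error = design$sigma, stringsAsFactors = FALSE)
  }
  ds <- dispersion_dataset(design$spins, points, do.call(rbind, vals))
  attr(ds, "truth") <- truth
  ds
}

#' Simulate peak intensities from a known truth
#'
#' `I = I_ref * exp(-R_true * T) + N(0, sigma_i)`, with the reference
#' intensity also drawn with noise `sigma_i`, so that feeding the output
#' through [calc_r2eff_two_point()] and [propagate_r2eff_error()] recovers
#' the true rates within the quoted errors.
#'
#' @param design A [sim_design()].
#' @param i_ref Noiseless reference intensity.
#' @param sigma_i Gaussian intensity noise s.d.
#' @return A `data.frame` with one row per (spin, point): the condition
#'   columns, `i_ref_obs`, `intensity`, `sigma_i` and the true rate.
#' @export
simulate_intensities <- function(design, i_ref = 1e6, sigma_i = 0) {
  stopifnot(inherits(design, "sim_design"))
  if (i_ref <= 0) stop("i_ref must be > 0", call. = FALSE)
  if (sigma_i < 0) stop("sigma_i must be >= 0", call. = FALSE)
  points <- design_points(design)
  set.seed(design$seed %% 2147483647L)
  out <- list()
  for (i in seq_len(nrow(design$spins))) {
    s <- design$spins[i, ]
    p <- design_params(design, s$spin_id)
    rates <- backcalc_rates(design$model, p, points, s$isotope, s$shift_ppm)
    out[[i]] <- data.frame(
      spin_id = s$spin_id, points,
      r2eff_true = rates,
      i_ref_obs = i_ref + rnorm(nrow(points)) * sigma_i,
      intensity = i_ref * exp(-rates * points$relax_time_T) +
        rnorm(nrow(points)) * sigma_i,
      sigma_i = sigma_i, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
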